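## Independent oracles used across the suite. Each is deliberately written
## from a different derivation than the package implementation it checks.

## Stepwise textbook sRGB -> CIELAB (D65/2deg), scalar, no shortcuts.
oracle_srgb_to_lab <- function(rgb) {
  lin <- vapply(rgb, function(v) {
    if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  }, numeric(1))
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  f <- function(t) if (t > 216 / 24389) t^(1 / 3) else (24389 / 27 * t + 16) / 116
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

## Point-to-triangle distance by an independent decomposition: distance to
## the supporting plane when the projection has non-negative barycentric
## coordinates, else the minimum over the three edge segments.
oracle_pt_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

oracle_pt_tri_dist <- function(p, a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n2 <- sum(n * n)
  d <- Inf
  if (n2 > 0) {
    q <- p - sum((p - a) * n) / n2 * n   # projection onto the plane
    ## barycentric coordinates of q
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) d <- sqrt(sum((p - q)^2))
  }
  min(d, oracle_pt_seg_dist(p, a, b), oracle_pt_seg_dist(p, b, c),
      oracle_pt_seg_dist(p, c, a))
}

## Exhaustive per-facet minimum distance from a query point to a mesh.
oracle_mesh_dist <- function(p, pts, facets) {
  min(vapply(seq_len(nrow(facets)), function(i) {
    oracle_pt_tri_dist(p, pts[facets[i, 1], ], pts[facets[i, 2], ],
                       pts[facets[i, 3], ])
  }, numeric(1)))
}

## Ray-casting containment: parity of ray-facet crossings per component,
## union over components. Retries with other directions on near-degenerate
## hits (ray through an edge/vertex).
oracle_raycast_contains <- function(p, pts, facets, component) {
  dirs <- rbind(c(0.57735, 0.211325, 0.788675), c(0.267261, 0.534522, 0.801784),
                c(0.912871, 0.365148, 0.182574), c(0.123091, 0.492366, 0.861641))
  for (di in seq_len(nrow(dirs))) {
    dir <- dirs[di, ]
    res <- rep(0L, max(component))
    degenerate <- FALSE
    for (i in seq_len(nrow(facets))) {
      a <- pts[facets[i, 1], ]; b <- pts[facets[i, 2], ]; c_ <- pts[facets[i, 3], ]
      e1 <- b - a; e2 <- c_ - a
      h <- c(dir[2] * e2[3] - dir[3] * e2[2], dir[3] * e2[1] - dir[1] * e2[3],
             dir[1] * e2[2] - dir[2] * e2[1])
      det <- sum(e1 * h)
      if (abs(det) < 1e-12) next
      s <- p - a
      u <- sum(s * h) / det
      q <- c(s[2] * e1[3] - s[3] * e1[2], s[3] * e1[1] - s[1] * e1[3],
             s[1] * e1[2] - s[2] * e1[1])
      v <- sum(dir * q) / det
      t <- sum(e2 * q) / det
      near <- function(x, lo, hi) x > lo - 1e-9 & x < hi + 1e-9
      if (near(u, 0, 1) && near(v, 0, 1) && near(u + v, 0, 1) && t > -1e-9) {
        ## potential hit; degenerate when it grazes an edge/vertex or the
        ## query point sits on the facet plane
        if (u < 1e-9 || v < 1e-9 || u + v > 1 - 1e-9 || t < 1e-9) {
          degenerate <- TRUE
          break
        }
        res[component[i]] <- res[component[i]] + 1L
      }
    }
    if (!degenerate) return(any(res %% 2L == 1L))
  }
  stop("ray casting degenerate in all directions")
}

## Brute-force convex hull: a triple is a hull facet iff all points lie on
## one side of its plane. Returns facets oriented outward.
oracle_convex_hull <- function(P) {
  n <- nrow(P)
  tri <- t(combn(n, 3))
  facets <- NULL
  for (k in seq_len(nrow(tri))) {
    f <- tri[k, ]
    a <- P[f[1], ]
    nn <- c((P[f[2], ] - a)[2] * (P[f[3], ] - a)[3] -
              (P[f[2], ] - a)[3] * (P[f[3], ] - a)[2],
            (P[f[2], ] - a)[3] * (P[f[3], ] - a)[1] -
              (P[f[2], ] - a)[1] * (P[f[3], ] - a)[3],
            (P[f[2], ] - a)[1] * (P[f[3], ] - a)[2] -
              (P[f[2], ] - a)[2] * (P[f[3], ] - a)[1])
    sd <- sweep(P, 2, a) %*% nn
    if (all(sd <= 1e-9)) {
      facets <- rbind(facets, f)
    } else if (all(sd >= -1e-9)) {
      facets <- rbind(facets, f[c(1, 3, 2)])
    }
  }
  facets
}

## Containment against oracle facets (outward-oriented half-spaces).
oracle_convex_contains <- function(P, facets, Q) {
  ok <- rep(TRUE, nrow(Q))
  for (k in seq_len(nrow(facets))) {
    f <- facets[k, ]
    a <- P[f[1], ]
    u <- P[f[2], ] - a; v <- P[f[3], ] - a
    nn <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    nn <- nn / sqrt(sum(nn^2))
    ok <- ok & (sweep(Q, 2, a) %*% nn <= 1e-9)
  }
  ok
}

oracle_convex_volume <- function(P, facets) {
  ctr <- colMeans(P)
  vol <- 0
  for (k in seq_len(nrow(facets))) {
    a <- P[facets[k, 1], ] - ctr
    b <- P[facets[k, 2], ] - ctr
    c_ <- P[facets[k, 3], ] - ctr
    vol <- vol + abs(det(rbind(a, b, c_))) / 6
  }
  vol
}

## O(n^3) single-linkage clustering with a distance cut.
oracle_single_linkage <- function(xy, cut) {
  n <- nrow(xy)
  g <- seq_len(n)
  d <- as.matrix(dist(xy))
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (g[i] != g[j] && d[i, j] <= cut) {
        g[g == g[j]] <- g[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(g, unique(g))
}

## Brute-force per-pixel voxel binning.
oracle_bin_counts <- function(labmat, binSize) {
  key <- apply(floor(labmat / binSize), 1, paste, collapse = " ")
  table(key)
}

## A tiny random Lab image fixture as an array.
random_srgb_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(round(runif(h * w * 3) * 255) / 255, dim = c(h, w, 3))
}

## ---- vectorized oracle variants (same derivations, batched over facets) --

## Ray casting with Moller-Trumbore evaluated for all facets at once.
oracle_raycast_contains_vec <- function(p, pts, facets, component) {
  A <- pts[facets[, 1], , drop = FALSE]
  B <- pts[facets[, 2], , drop = FALSE]
  C <- pts[facets[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  dirs <- rbind(c(0.57735, 0.211325, 0.788675),
                c(0.267261, 0.534522, 0.801784),
                c(0.912871, 0.365148, 0.182574),
                c(0.123091, 0.492366, 0.861641))
  cross_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  for (di in seq_len(nrow(dirs))) {
    d <- dirs[di, ]
    dm <- matrix(d, nrow(e2), 3, byrow = TRUE)
    h <- cross_rows(dm, e2)
    det <- rowSums(e1 * h)
    s <- sweep(-A, 2, p, "+")
    u <- rowSums(s * h) / det
    q <- cross_rows(s, e1)
    v <- (q %*% d) / det
    t <- rowSums(e2 * q) / det
    ok <- abs(det) > 1e-12
    cand <- ok & u > -1e-9 & v > -1e-9 & u + v < 1 + 1e-9 & t > -1e-9
    grazing <- cand & (u < 1e-9 | v < 1e-9 | u + v > 1 - 1e-9 | t < 1e-9)
    if (any(grazing)) next
    hit <- cand & u >= 0 & v >= 0 & u + v <= 1 & t > 0
    counts <- tabulate(component[hit], nbins = max(component))
    return(any(counts %% 2L == 1L))
  }
  stop("ray casting degenerate in all directions")
}

## Plane-projection/edge-segment distance decomposition, batched over facets.
oracle_mesh_dist_vec <- function(p, pts, facets) {
  A <- pts[facets[, 1], , drop = FALSE]
  B <- pts[facets[, 2], , drop = FALSE]
  C <- pts[facets[, 3], , drop = FALSE]
  v0 <- B - A; v1 <- C - A
  n <- cbind(v0[, 2] * v1[, 3] - v0[, 3] * v1[, 2],
             v0[, 3] * v1[, 1] - v0[, 1] * v1[, 3],
             v0[, 1] * v1[, 2] - v0[, 2] * v1[, 1])
  n2 <- rowSums(n^2)
  q <- sweep(-A, 2, p, "+")              # p - A per facet
  dplane <- rowSums(q * n) / n2
  proj <- q - dplane * n                 # projection of p, relative to A
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(proj * v0); d21 <- rowSums(proj * v1)
  den <- d00 * d11 - d01^2
  vv <- (d11 * d20 - d01 * d21) / den
  ww <- (d00 * d21 - d01 * d20) / den
  inside <- vv >= 0 & ww >= 0 & vv + ww <= 1
  dface <- rep(Inf, nrow(A))
  dface[inside] <- (abs(dplane) * sqrt(n2))[inside]
  segd <- function(P0, P1) {
    ab <- P1 - P0
    w <- sweep(-P0, 2, p, "+")
    t <- rowSums(w * ab) / rowSums(ab * ab)
    t <- pmin(pmax(t, 0), 1)
    sqrt(rowSums((w - t * ab)^2))
  }
  min(pmin(dface, segd(A, B), segd(B, C), segd(C, A)))
}
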