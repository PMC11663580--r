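## Low-level 3D computational geometry: incremental convex hull,
## gift-wrapping Delaunay tetrahedralization, and vectorized
## point-to-triangle distances. Coordinates are CIELAB, so all lengths are
## Delta E units.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Deterministic quasi-random jitter used only inside Delaunay predicates.
## Voxel centres lie on a regular lattice (maximally co-spherical), which is
## the classic degenerate input; a tiny symbolic-style perturbation makes all
## predicates decisive without touching the caller's RNG. Amplitude is
## relative to the cloud diameter, so facet geometry computed from the
## ORIGINAL coordinates is unaffected at any meaningful Delta E scale.
.qjitter <- function(n, scale, amp = 1e-4, phase = 0) {
  i <- seq_len(3L * n) + phase
  u <- (sin(i * 12.9898 + 78.233) * 43758.5453) %% 1
  matrix((u - 0.5) * 2 * amp * scale, n, 3L)
}

## ---- incremental convex hull -------------------------------------------

## Returns list(facets = f x 3 integer matrix, outward-oriented). Errors on
## degenerate input (fewer than 4 affinely independent points).
.chull3d <- function(P) {
  n <- nrow(P)
  diam <- max(apply(P, 2, function(x) diff(range(x))))
  if (n < 4L || diam <= 0)
    stop("degenerate hull: need at least 4 affinely independent vertices")
  eps <- 1e-12 * max(diam, 1)

  ## initial simplex: extreme pair, farthest-from-line, farthest-from-plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  if (i1 == i2) { i1 <- which.min(P[, 3]); i2 <- which.max(P[, 3]) }
  u <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (dline[i3] <= (1e-10 * diam^2)^2)
    stop("degenerate hull: vertices are collinear")
  nrm <- .cross3(u, P[i3, ] - P[i1, ])
  dplane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps * diam)
    stop("degenerate hull: vertices are coplanar")

  F <- matrix(c(i1, i2, i3,
                i1, i2, i4,
                i1, i3, i4,
                i2, i3, i4), ncol = 3, byrow = TRUE)
  inner <- colMeans(P[c(i1, i2, i3, i4), ])
  orient_out <- function(f) {
    a <- P[f[1], ]; nn <- .cross3(P[f[2], ] - a, P[f[3], ] - a)
    if (sum(nn * (inner - a)) > 0) f[c(1, 3, 2)] else f
  }
  F <- t(apply(F, 1, orient_out))

  facet_plane <- function(f) {
    a <- P[f[1], ]; nn <- .cross3(P[f[2], ] - a, P[f[3], ] - a)
    nn <- nn / sqrt(sum(nn^2))
    c(nn, sum(nn * a))
  }
  PL <- t(apply(F, 1, facet_plane))   # f x 4: unit normal, offset

  tol <- 1e-10 * diam
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (ip in rest) {
    p <- P[ip, ]
    sd <- PL[, 1:3, drop = FALSE] %*% p - PL[, 4]
    vis <- sd > tol
    if (!any(vis)) next
    ## horizon: directed edges of visible facets whose undirected twin is
    ## not in the visible set
    vf <- F[vis, , drop = FALSE]
    ed <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newF <- cbind(horizon, ip)
    newF <- t(apply(newF, 1, orient_out))
    F <- rbind(F[!vis, , drop = FALSE], newF)
    PL <- rbind(PL[!vis, , drop = FALSE], t(apply(newF, 1, facet_plane)))
  }
  list(facets = F, planes = PL)
}

## ---- Delaunay tetrahedralization (gift wrapping / DeWall) ---------------

.tri_circumcenter <- function(a, b, c) {
  u <- b - a; v <- c - a
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  det <- uu * vv - uv * uv
  st <- c(vv * uu - uv * vv, uu * vv - uv * uu) / (2 * det)
  a + st[1] * u + st[2] * v
}

## For oriented face (a, b, c) with outward normal nrm, return the index of
## the Delaunay mate among candidate points (rows of P), or 0L if the face
## lies on the convex hull (no point strictly on the outward side). The mate
## minimizes the signed height t of the circumsphere centre along nrm.
.delaunay_mate <- function(P, a, z0, nrm, cand, eps) {
  Q <- sweep(P[cand, , drop = FALSE], 2, a)       # q = p - a
  dn <- Q %*% nrm
  pos <- dn > eps
  if (!any(pos)) return(0L)
  z0a <- z0 - a
  tt <- (rowSums(Q^2) - 2 * (Q %*% z0a)) / (2 * dn)
  tt[!pos] <- Inf
  cand[which.min(tt)]
}

## Full Delaunay tetrahedralization by face-wise gift wrapping. Returns an
## integer matrix t x 4 of tetrahedra. Predicates run on jittered
## coordinates; callers measure edges on the originals. The result is
## self-verified (the tetrahedra must tile the jittered cloud's convex
## hull); on the rare failure the jitter phase and amplitude are re-drawn.
.delaunay3d <- function(P0) {
  for (attempt in 0:2) {
    res <- tryCatch(.delaunay3d_once(P0, amp = 1e-4 * 10^attempt,
                                     phase = attempt * 997),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (grepl("degenerate hull", conditionMessage(res))) stop(res)
  }
  stop(res)
}

.delaunay3d_once <- function(P0, amp = 1e-4, phase = 0) {
  n <- nrow(P0)
  if (n < 4L) stop("degenerate hull: need at least 4 distinct vertices")
  diam <- max(apply(P0, 2, function(x) diff(range(x))))
  if (diam <= 0) stop("degenerate hull: all vertices identical")
  P <- P0 + .qjitter(n, diam, amp = amp, phase = phase)
  eps <- 1e-9 * diam

  ## seed facet: extreme point, its nearest neighbour, then the point giving
  ## the smallest circumcircle
  i1 <- which.min(P[, 1])
  d2 <- rowSums(sweep(P, 2, P[i1, ])^2); d2[i1] <- Inf
  i2 <- which.min(d2)
  best <- 0L; bestr <- Inf
  for (k in seq_len(n)) {
    if (k == i1 || k == i2) next
    cc <- tryCatch(.tri_circumcenter(P[i1, ], P[i2, ], P[k, ]),
                   error = function(e) NULL)
    if (is.null(cc) || any(!is.finite(cc))) next
    r <- sum((cc - P[i1, ])^2)
    if (r < bestr) { bestr <- r; best <- k }
  }
  if (best == 0L) stop("degenerate hull: vertices are collinear")
  i3 <- best

  face_key <- function(f) paste(sort(f), collapse = "-")
  tet_key <- function(tt) paste(sort(tt), collapse = "-")

  tets <- vector("list", 8L * n); ntet <- 0L
  seen_tet <- new.env(hash = TRUE, parent = emptyenv())
  fcount <- new.env(hash = TRUE, parent = emptyenv())
  ## stack of frontier entries: list(face = c(i,j,k), opp = vertex of the
  ## known adjacent tet on the non-frontier side)
  stack <- vector("list", 64L); ns <- 0L
  push <- function(entry) {
    ns <<- ns + 1L
    if (ns > length(stack)) stack <<- c(stack, vector("list", length(stack)))
    stack[[ns]] <<- entry
  }

  add_tet <- function(tt) {
    k <- tet_key(tt)
    if (!is.null(seen_tet[[k]])) return(invisible(FALSE))
    seen_tet[[k]] <- TRUE
    ntet <<- ntet + 1L
    if (ntet > length(tets)) tets <<- c(tets, vector("list", length(tets)))
    tets[[ntet]] <<- tt
    fcs <- rbind(tt[-1], tt[-2], tt[-3], tt[-4])
    for (r in 1:4) {
      f <- fcs[r, ]; fk <- face_key(f)
      cnt <- fcount[[fk]]
      if (is.null(cnt)) cnt <- 0L
      fcount[[fk]] <- cnt + 1L
      if (cnt == 0L) push(list(face = f, opp = setdiff(tt, f)))
    }
    invisible(TRUE)
  }

  ## first tetrahedron: wrap the seed facet from whichever side has a mate
  f0 <- c(i1, i2, i3)
  a <- P[f0[1], ]
  nrm <- .cross3(P[f0[2], ] - a, P[f0[3], ] - a)
  nrm <- nrm / sqrt(sum(nrm^2))
  z0 <- .tri_circumcenter(P[f0[1], ], P[f0[2], ], P[f0[3], ])
  cand <- setdiff(seq_len(n), f0)
  m <- .delaunay_mate(P, a, z0, nrm, cand, eps)
  if (m == 0L) m <- .delaunay_mate(P, a, z0, -nrm, cand, eps)
  if (m == 0L) stop("degenerate hull: vertices are coplanar")
  add_tet(c(f0, m))

  while (ns > 0L) {
    entry <- stack[[ns]]; ns <- ns - 1L
    f <- entry$face
    if (fcount[[face_key(f)]] >= 2L) next
    a <- P[f[1], ]
    nrm <- .cross3(P[f[2], ] - a, P[f[3], ] - a)
    nrm <- nrm / sqrt(sum(nrm^2))
    ## orient away from the known tet's opposite vertex
    if (sum(nrm * (P[entry$opp, ] - a)) > 0) nrm <- -nrm
    z0 <- .tri_circumcenter(P[f[1], ], P[f[2], ], P[f[3], ])
    cand <- setdiff(seq_len(n), f)
    m <- .delaunay_mate(P, a, z0, nrm, cand, eps)
    if (m == 0L) next            # convex-hull face
    add_tet(c(f, m))
  }

  out <- do.call(rbind, tets[seq_len(ntet)])
  ## self-check: the tetrahedra must tile the convex hull of the jittered
  ## cloud (no overlaps, no gaps)
  tv <- sum(abs(vapply(seq_len(nrow(out)), function(r) {
    tt <- out[r, ]
    det(rbind(P[tt[2], ] - P[tt[1], ], P[tt[3], ] - P[tt[1], ],
              P[tt[4], ] - P[tt[1], ])) / 6
  }, numeric(1))))
  ch <- .chull3d(P)
  hv <- .mesh_volume(P, ch$facets)
  if (abs(tv - hv) > 1e-6 * hv)
    stop("tetrahedralization inconsistent (tiled volume ", tv,
         " vs hull volume ", hv, ")")
  out
}

## ---- point-to-triangle distance -----------------------------------------

## Minimum squared distances from each row of Q (m x 3) to each of a set of
## triangles (V1, V2, V3: f x 3 matrices), vectorized over both with the
## Ericson/Eberly region decomposition. Returns the per-point minimum over
## facets. Chunked so temporaries stay below ~tens of MB.
.min_tri_dist2 <- function(Q, V1, V2, V3, chunk = NULL) {
  f <- nrow(V1)
  m <- nrow(Q)
  if (is.null(chunk)) chunk <- max(1L, floor(4e6 / max(f, 1L)))
  E0 <- V2 - V1
  E1 <- V3 - V1
  a00 <- rowSums(E0^2); a01 <- rowSums(E0 * E1); a11 <- rowSums(E1^2)
  detv <- a00 * a11 - a01 * a01
  e0a <- rowSums(E0 * V1); e1a <- rowSums(E1 * V1); aa <- rowSums(V1^2)
  out <- numeric(m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    q <- Q[lo:hi, , drop = FALSE]
    k <- nrow(q)
    A00 <- matrix(a00, k, f, byrow = TRUE)
    A01 <- matrix(a01, k, f, byrow = TRUE)
    A11 <- matrix(a11, k, f, byrow = TRUE)
    DET <- matrix(detv, k, f, byrow = TRUE)
    B0 <- matrix(e0a, k, f, byrow = TRUE) - q %*% t(E0)
    B1 <- matrix(e1a, k, f, byrow = TRUE) - q %*% t(E1)
    DD <- matrix(aa, k, f, byrow = TRUE) - 2 * (q %*% t(V1)) +
      matrix(rowSums(q^2), k, f)
    s <- A01 * B1 - A11 * B0
    t <- A01 * B0 - A00 * B1
    cl <- function(x) pmin(pmax(x, 0), 1)
    interior <- (s + t <= DET)
    ## regions with s+t <= det
    r4 <- interior & s < 0 & t < 0
    r3 <- interior & s < 0 & t >= 0
    r5 <- interior & s >= 0 & t < 0
    r0 <- interior & s >= 0 & t >= 0
    ## regions with s+t > det
    r2 <- !interior & s < 0
    r6 <- !interior & s >= 0 & t < 0
    r1 <- !interior & s >= 0 & t >= 0
    S <- s; T <- t
    if (any(r0)) { S[r0] <- s[r0] / DET[r0]; T[r0] <- t[r0] / DET[r0] }
    if (any(r3)) { S[r3] <- 0; T[r3] <- cl(-B1[r3] / A11[r3]) }
    if (any(r5)) { T[r5] <- 0; S[r5] <- cl(-B0[r5] / A00[r5]) }
    if (any(r4)) {
      useS <- r4 & (B0 < 0)
      S[useS] <- cl(-B0[useS] / A00[useS]); T[useS] <- 0
      useT <- r4 & (B0 >= 0)
      S[useT] <- 0; T[useT] <- cl(-B1[useT] / A11[useT])
    }
    if (any(r2)) {
      tmp0 <- A01 + B0; tmp1 <- A11 + B1
      onEdge <- r2 & (tmp1 > tmp0)
      den <- A00 - 2 * A01 + A11
      S[onEdge] <- cl((tmp1[onEdge] - tmp0[onEdge]) / den[onEdge])
      T[onEdge] <- 1 - S[onEdge]
      off <- r2 & !(tmp1 > tmp0)
      S[off] <- 0; T[off] <- cl(-B1[off] / A11[off])
    }
    if (any(r6)) {
      tmp0 <- A01 + B1; tmp1 <- A00 + B0
      onEdge <- r6 & (tmp1 > tmp0)
      den <- A00 - 2 * A01 + A11
      T[onEdge] <- cl((tmp1[onEdge] - tmp0[onEdge]) / den[onEdge])
      S[onEdge] <- 1 - T[onEdge]
      off <- r6 & !(tmp1 > tmp0)
      T[off] <- 0; S[off] <- cl(-B0[off] / A00[off])
    }
    if (any(r1)) {
      numer <- A11 + B1 - A01 - B0
      den <- A00 - 2 * A01 + A11
      S[r1] <- cl(numer[r1] / den[r1]); T[r1] <- 1 - S[r1]
    }
    d2 <- S * (A00 * S + A01 * T + 2 * B0) +
      T * (A01 * S + A11 * T + 2 * B1) + DD
    d2[d2 < 0] <- 0
    out[lo:hi] <- apply(d2, 1, min)
  }
  out
}

## Signed tetra volume x 6 helper and mesh volume via the divergence theorem
## over outward-oriented facets.
.mesh_volume <- function(points, facets) {
  a <- points[facets[, 1], , drop = FALSE]
  b <- points[facets[, 2], , drop = FALSE]
  c_ <- points[facets[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}
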