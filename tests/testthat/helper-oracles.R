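# Independent geometry oracles, kept deliberately separate from the package
# implementation paths they check.

# Heron's formula triangle area from three vertices
heron_area <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p1)^2))
  b <- sqrt(sum((p3 - p2)^2))
  c <- sqrt(sum((p1 - p3)^2))
  s <- (a + b + c) / 2
  sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
}

# Exhaustive nearest-intersection scan: for every pixel, intersect the ray
# against EVERY triangle (vectorised Moller-Trumbore over triangles) and keep
# the smallest positive ray parameter. Mirrors the package's epsilon
# conventions but shares no code with it.
brute_raycast_ids <- function(mesh, intrinsics, placement, look_at) {
  ext <- place_camera(placement, look_at = look_at)
  W <- intrinsics$width
  H <- intrinsics$height
  fx <- intrinsics$f * intrinsics$sx
  fy <- intrinsics$f * intrinsics$sy
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  o <- ext$C
  s <- sweep(v0, 2, o, "-") * -1  # o - v0
  hit <- matrix(NA_integer_, H, W)
  for (u in seq_len(W) - 1L) {
    for (vv in seq_len(H) - 1L) {
      yc <- (vv - intrinsics$oy) / fy
      xc <- (u - intrinsics$ox - intrinsics$f * intrinsics$skew * yc) / fx
      d <- as.numeric(t(ext$R) %*% c(xc, yc, 1))
      p <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                 d[3] * e2[, 1] - d[1] * e2[, 3],
                 d[1] * e2[, 2] - d[2] * e2[, 1])
      det <- rowSums(e1 * p)
      q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
                 s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
                 s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
      inv <- 1 / det
      bu <- rowSums(s * p) * inv
      bv <- (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) * inv
      tt <- rowSums(e2 * q) * inv
      ok <- abs(det) >= 1e-12 & bu >= -1e-9 & bu <= 1 + 1e-9 &
        bv >= -1e-9 & (bu + bv) <= 1 + 1e-9 & tt > 1e-9
      if (any(ok)) {
        cand <- which(ok)
        tmin <- min(tt[cand])
        ids <- cand[tt[cand] <= tmin + 1e-12]
        hit[vv + 1L, u + 1L] <- mesh$face_ids[min(ids)]
      }
    }
  }
  hit
}

# triangle soup with faces roughly facing the +z camera half-space
random_triangle_soup <- function(n_tri, seed) {
  set.seed(seed)
  ctr <- cbind(stats::runif(n_tri, -3, 3), stats::runif(n_tri, -3, 3),
               stats::runif(n_tri, -3, 3))
  verts <- matrix(NA_real_, 3 * n_tri, 3)
  for (i in seq_len(n_tri)) {
    verts[3 * i - 2:0, ] <- rep(ctr[i, ], each = 3) +
      matrix(stats::runif(9, -1.5, 1.5), 3)
  }
  mesh3t(verts, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}

# a fronto-parallel rectangular plane (two triangles) at depth z covering
# [-half, half]^2 in x/y, in world coordinates for a camera looking down -z
# from (0, 0, dist) at the origin
plane_mesh <- function(half = 30, z = 0) {
  mesh3t(rbind(c(-half, -half, z), c(half, -half, z),
               c(half, half, z), c(-half, half, z)),
         rbind(c(1, 2, 3), c(1, 3, 4)))
}
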