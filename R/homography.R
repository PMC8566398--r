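## Planar homography estimation shared by calibration and marker pose fitting.

# Normalized DLT: maps planar points (x, y) to image points (u, v).
# Returns 3x3 H with H[3,3] scaled to 1 where possible.
homography_dlt <- function(src_xy, dst_uv) {
  src_xy <- matrix(src_xy, ncol = 2)
  dst_uv <- matrix(dst_uv, ncol = 2)
  n <- nrow(src_xy)
  stopifnot(n >= 4, nrow(dst_uv) == n)

  norm_tf <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(T = T, p = sweep(p, 2, ctr) * s)
  }
  ns <- norm_tf(src_xy); nd <- norm_tf(dst_uv)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  zero <- rep(0, n); one <- rep(1, n)
  A <- rbind(cbind(-x, -y, -one, zero, zero, zero, u * x, u * y, u),
             cbind(zero, zero, zero, -x, -y, -one, v * x, v * y, v))
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

apply_homography <- function(H, xy) {
  xy <- matrix(xy, ncol = 2)
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2] / p[, 3]
}

# Decompose a plane-to-normalized-image homography into an initial pose.
# H maps (x, y) on the plane z = 0 (mm) to normalized image coordinates.
homography_to_pose <- function(Hn) {
  h1 <- Hn[, 1]; h2 <- Hn[, 2]; h3 <- Hn[, 3]
  lambda <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  r1 <- lambda * h1; r2 <- lambda * h2; t <- lambda * h3
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R <- cbind(r1, r2, r3)
  # nearest rotation by SVD
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  pose3d(R, t)
}

# Map the conic of a circle (center cxy, radius r, on the source plane)
# through homography H; return the image ellipse center and area.
# The image of a filled disc under a projective map (no line at infinity
# crossing it) is a filled ellipse; the blob centroid equals its center.
projected_circle_ellipse <- function(H, cxy, r) {
  # circle conic C: x^2 + y^2 - 2 cx x - 2 cy y + cx^2 + cy^2 - r^2 = 0
  C <- matrix(c(1, 0, -cxy[1],
                0, 1, -cxy[2],
                -cxy[1], -cxy[2], cxy[1]^2 + cxy[2]^2 - r^2), 3, 3)
  Hi <- solve(H)
  Cp <- t(Hi) %*% C %*% Hi          # image conic
  A <- Cp[1, 1]; B <- 2 * Cp[1, 2]; Cc <- Cp[2, 2]
  D <- 2 * Cp[1, 3]; E <- 2 * Cp[2, 3]; F <- Cp[3, 3]
  den <- 4 * A * Cc - B^2
  ctr <- c((B * E - 2 * Cc * D) / den, (B * D - 2 * A * E) / den)
  # area = pi * |det Q| / det(M)^(3/2) for an ellipse (det M > 0)
  M <- matrix(c(A, B / 2, B / 2, Cc), 2, 2)
  detQ <- det(matrix(c(A, B / 2, D / 2, B / 2, Cc, E / 2,
                       D / 2, E / 2, F), 3, 3))
  area <- pi * abs(detQ) / det(M)^1.5
  list(center = ctr, area = area)
}

# Centroid of the image of an annulus (outer radius ro, inner ri) under H:
# area-weighted difference of the two disc images.
projected_annulus_centroid <- function(H, cxy, ro, ri) {
  eo <- projected_circle_ellipse(H, cxy, ro)
  ei <- projected_circle_ellipse(H, cxy, ri)
  (eo$center * eo$area - ei$center * ei$area) / (eo$area - ei$area)
}
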