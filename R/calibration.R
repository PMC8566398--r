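#' Calibrate endoscope intrinsics from checkerboard views
#'
#' Planar-target calibration: per-view homographies give a closed-form
#' initialization of the intrinsic matrix (Zhang's constraints on the image
#' of the absolute conic), after which all parameters — focal lengths,
#' principal point, distortion (k1, k2, p1, p2) and per-view extrinsics —
#' are refined jointly by Levenberg-Marquardt minimization of the
#' reprojection error.
#'
#' @param corner_sets List with one element per view; each element is a list
#'   with `image` (n x 2 pixel coordinates) and `board` (n x 2 planar board
#'   coordinates in mm, board z = 0). At least 3 views with >= 4
#'   non-collinear corners each.
#' @param image_size c(width, height) in pixels.
#' @param fit_distortion Estimate the distortion coefficients (default TRUE);
#'   with FALSE they are fixed at zero.
#' @return A `camera_model` with attributes `rms_reprojection_px` (root mean
#'   square reprojection error over all corners) and `extrinsics` (list of
#'   per-view `pose3d`).
#' @export
calibrate_intrinsics <- function(corner_sets, image_size,
                                 fit_distortion = TRUE) {
  if (length(corner_sets) < 3)
    stop("insufficient calibration views (need >= 3)")
  for (v in corner_sets) {
    b <- matrix(v$board, ncol = 2)
    if (nrow(b) < 4) stop("insufficient calibration views (need >= 4 corners)")
    # collinearity check: rank of centered coordinates
    s <- svd(sweep(b, 2, colMeans(b)))$d
    if (s[2] < 1e-9 * max(s[1], 1)) stop("corners are collinear")
  }

  Hs <- lapply(corner_sets, function(v)
    homography_dlt(v$board, v$image))

  # Zhang: constraints v12 . b = 0, (v11 - v22) . b = 0 on B = K^-T K^-1
  vrow <- function(H, i, j) {
    h_i <- H[, i]; h_j <- H[, j]
    c(h_i[1] * h_j[1],
      h_i[1] * h_j[2] + h_i[2] * h_j[1],
      h_i[2] * h_j[2],
      h_i[3] * h_j[1] + h_i[1] * h_j[3],
      h_i[3] * h_j[2] + h_i[2] * h_j[3],
      h_i[3] * h_j[3])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vrow(H, 1, 2), vrow(H, 1, 1) - vrow(H, 2, 2))))
  b <- svd(V, nu = 0, nv = 6)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 <= 0) { b <- -b
    B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
    den <- B11 * B22 - B12^2
    v0 <- (B12 * B13 - B11 * B23) / den
    lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  }
  if (lam / B11 <= 0 || lam * B11 / den <= 0)
    stop("insufficient calibration views (degenerate geometry)")
  fx0 <- sqrt(lam / B11)
  fy0 <- sqrt(lam * B11 / den)
  cx0 <- -B13 * fx0^2 / lam
  cy0 <- v0

  K <- matrix(c(fx0, 0, cx0, 0, fy0, cy0, 0, 0, 1), 3, 3, byrow = TRUE)
  Kinv <- solve(K)
  poses0 <- lapply(Hs, function(H) homography_to_pose(Kinv %*% H))

  nview <- length(corner_sets)
  ndist <- if (fit_distortion) 4 else 0
  pack <- function(intr, dist, poses) {
    c(intr,
      if (fit_distortion) dist,
      unlist(lapply(poses, function(p) c(matrix_to_rodrigues(p$R), p$t))))
  }
  unpack <- function(par) {
    intr <- par[1:4]
    dist <- if (fit_distortion) par[5:8] else c(0, 0, 0, 0)
    rest <- par[-(1:(4 + ndist))]
    poses <- lapply(seq_len(nview), function(i) {
      s <- rest[(6 * (i - 1) + 1):(6 * i)]
      list(R = rodrigues_to_matrix(s[1:3]), t = s[4:6])
    })
    list(intr = intr, dist = dist, poses = poses)
  }
  residuals <- function(par) {
    st <- unpack(par)
    cam <- structure(list(fx = abs(st$intr[1]), fy = abs(st$intr[2]),
                          cx = st$intr[3], cy = st$intr[4],
                          image_size = image_size, distortion = st$dist),
                     class = "camera_model")
    unlist(lapply(seq_len(nview), function(i) {
      p3 <- cbind(matrix(corner_sets[[i]]$board, ncol = 2), 0)
      pc <- sweep(p3 %*% t(st$poses[[i]]$R), 2, st$poses[[i]]$t, `+`)
      pc[, 3] <- pmax(pc[, 3], 1e-6)
      proj <- project_points(cam, pc)
      as.numeric(proj - matrix(corner_sets[[i]]$image, ncol = 2))
    }))
  }

  par0 <- pack(c(fx0, fy0, cx0, cy0), rep(0, 4), poses0)
  fit <- minpack.lm::nls.lm(par = par0, fn = residuals,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  st <- unpack(fit$par)
  cam <- camera_model(abs(st$intr[1]), abs(st$intr[2]),
                      st$intr[3], st$intr[4],
                      image_size = image_size, distortion = st$dist)
  res <- residuals(fit$par)
  attr(cam, "rms_reprojection_px") <- sqrt(mean(res^2))
  attr(cam, "extrinsics") <- lapply(st$poses, function(p) {
    s <- svd(p$R)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
    pose3d(R, p$t)
  })
  cam
}
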