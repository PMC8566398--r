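#' Pinhole camera model with radial-tangential distortion
#'
#' Constructs the intrinsic model of the endoscope used throughout tracking:
#' focal lengths and principal point in pixels, a 4-coefficient distortion
#' vector (k1, k2 radial; p1, p2 tangential) and the image size.
#'
#' Image coordinate convention: origin at the top-left pixel corner, x right,
#' y down, both in pixels. Camera frame: x right, y down, z forward (optical
#' axis), in mm.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels, inside the image.
#' @param image_size Integer vector c(width, height) in pixels.
#' @param distortion Numeric vector c(k1, k2, p1, p2); defaults to zero.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, image_size,
                         distortion = c(0, 0, 0, 0)) {
  stopifnot(is.numeric(fx), is.numeric(fy), fx > 0, fy > 0,
            length(image_size) == 2, all(image_size > 0),
            length(distortion) == 4)
  if (cx < 0 || cx >= image_size[1] || cy < 0 || cy >= image_size[2])
    stop("principal point outside image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_size = as.numeric(image_size),
                 distortion = as.numeric(distortion)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %dx%d px, fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
              x$image_size[1], x$image_size[2], x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  distortion k1=%.4g k2=%.4g p1=%.4g p2=%.4g\n",
              x$distortion[1], x$distortion[2],
              x$distortion[3], x$distortion[4]))
  rms <- attr(x, "rms_reprojection_px")
  if (!is.null(rms)) cat(sprintf("  calibration RMS reprojection %.4f px\n", rms))
  invisible(x)
}

#' Rigid pose (rotation + translation)
#'
#' A rigid transform from a local (marker/board) frame to the camera frame:
#' `X_cam = R %*% X_local + t`, translation in mm.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation Length-3 numeric vector, mm.
#' @return An object of class `pose3d`.
#' @export
pose3d <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with det +1")
  structure(list(R = rotation, t = as.numeric(translation)), class = "pose3d")
}

#' @rdname pose3d
#' @param pose A `pose3d`.
#' @param points_local n x 3 matrix of points in the local frame (mm).
#' @export
pose_apply <- function(pose, points_local) {
  p <- matrix(points_local, ncol = 3)
  sweep(p %*% t(pose$R), 2, pose$t, `+`)
}

#' @rdname pose3d
#' @export
pose_inverse <- function(pose) {
  pose3d(t(pose$R), -t(pose$R) %*% pose$t)
}

#' @rdname pose3d
#' @param a,b Poses; returns the pose applying `b` first, then `a`.
#' @export
pose_compose <- function(a, b) {
  pose3d(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Axis-angle (Rodrigues) vector to rotation matrix and back
#'
#' @param rvec Length-3 axis-angle vector (angle = norm, radians).
#' @return `rodrigues_to_matrix`: a 3x3 rotation matrix;
#'   `matrix_to_rodrigues`: a length-3 vector.
#' @keywords internal
rodrigues_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) return(diag(3))
  k <- rvec / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rodrigues_to_matrix
#' @param R 3x3 rotation matrix.
#' @keywords internal
matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    M <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(M), 0))
    # fix signs using off-diagonals
    i <- which.max(k)
    if (i == 1) { k[2] <- M[1, 2] / k[1]; k[3] <- M[1, 3] / k[1] }
    if (i == 2) { k[1] <- M[1, 2] / k[2]; k[3] <- M[2, 3] / k[2] }
    if (i == 3) { k[1] <- M[1, 3] / k[3]; k[2] <- M[2, 3] / k[3] }
    return(th * k / sqrt(sum(k^2)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th * ax / (2 * sin(th))
}

## distortion in normalized image coordinates -------------------------------

distort_normalized <- function(camera, xy) {
  d <- camera$distortion
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  cbind(xd, yd)
}

undistort_normalized <- function(camera, xy, iters = 20) {
  if (all(camera$distortion == 0)) return(xy)
  est <- xy
  for (i in seq_len(iters)) {
    delta <- distort_normalized(camera, est) - est
    est <- xy - delta
  }
  est
}

#' Project 3D camera-frame points to pixels
#'
#' Central projection followed by the camera's distortion model. All points
#' must be in front of the camera (z > 0).
#'
#' @param camera A `camera_model`.
#' @param points_mm n x 3 matrix (or length-3 vector) of camera-frame points, mm.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(camera, points_mm) {
  p <- matrix(points_mm, ncol = 3)
  if (any(p[, 3] <= 0)) stop("behind camera")
  xy <- cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
  xy <- distort_normalized(camera, xy)
  cbind(camera$fx * xy[, 1] + camera$cx,
        camera$fy * xy[, 2] + camera$cy)
}

#' Back-project pixels to unit viewing rays
#'
#' Inverts the distortion model and returns unit direction vectors in the
#' camera frame; scaling a ray by the point's depth recovers the 3D point.
#'
#' @param camera A `camera_model`.
#' @param points_px n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @return n x 3 matrix of unit direction vectors.
#' @export
back_project_ray <- function(camera, points_px) {
  p <- matrix(points_px, ncol = 2)
  xy <- cbind((p[, 1] - camera$cx) / camera$fx,
              (p[, 2] - camera$cy) / camera$fy)
  xy <- undistort_normalized(camera, xy)
  d <- cbind(xy, 1)
  d / sqrt(rowSums(d^2))
}

## camera model JSON I/O ----------------------------------------------------

#' Read / write a camera model as JSON
#'
#' The schema stores focal lengths and principal point in pixels, distortion
#' coefficients (k1, k2, p1, p2, unitless) and image size in pixels.
#'
#' @param camera A `camera_model`.
#' @param path File path.
#' @return `read_camera_json` returns a `camera_model`.
#' @export
write_camera_json <- function(camera, path) {
  obj <- list(units = list(focal = "px", principal_point = "px",
                           image_size = "px"),
              fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
              distortion = camera$distortion,
              image_size = camera$image_size)
  rms <- attr(camera, "rms_reprojection_px")
  if (!is.null(rms)) obj$rms_reprojection_px <- rms
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- camera_model(obj$fx, obj$fy, obj$cx, obj$cy,
                      image_size = obj$image_size,
                      distortion = obj$distortion)
  if (!is.null(obj$rms_reprojection_px))
    attr(cam, "rms_reprojection_px") <- obj$rms_reprojection_px
  cam
}

#' Read checkerboard corner correspondences from CSV
#'
#' Expects columns `view`, `u_px`, `v_px`, `x_mm`, `y_mm`: one row per corner,
#' image points in pixels and planar board points in mm (board z = 0).
#'
#' @param path CSV file path.
#' @return A list of per-view correspondence sets as accepted by
#'   [calibrate_intrinsics()].
#' @export
read_corner_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("view", "u_px", "v_px", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("corner CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$view), function(v)
    list(image = cbind(v$u_px, v$v_px), board = cbind(v$x_mm, v$y_mm)))
}
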