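## Synthetic endoscopic frame renderer.
##
## Markers are rasterized with coverage-based anti-aliasing: each pixel in
## the marker's projected bounding box is subsampled on a regular grid, the
## subsamples are inverse-mapped through the marker-plane homography, and
## the pixel color is alpha-blended with the marker color by the inside
## fraction. This gives edge localisation well below one pixel, matching a
## well-focused video camera.

hsv_mid_rgb <- function(profile) {
  h <- mean(profile$hue)
  s <- 0.9 * max(profile$saturation)
  v <- 0.9 * max(profile$value)
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

#' Default synthetic endoscope camera
#'
#' 960 x 540 px, fx = fy = 700 px (about 69 degrees horizontal field of
#' view), principal point at the image centre, zero distortion.
#'
#' @return A `camera_model`.
#' @export
default_camera <- function() {
  camera_model(700, 700, 480, 270, image_size = c(960, 540))
}

#' Instrument pose facing the camera
#'
#' Convenience constructor: places the instrument frame at `center_mm`
#' (camera frame) with the shaft-marker face turned toward the camera, then
#' applies optional roll (about the instrument x axis), pitch (about y) and
#' yaw (about z), in that order, in degrees.
#'
#' @param center_mm Length-3 position of the instrument origin, mm.
#' @param roll_deg,pitch_deg,yaw_deg Rotations in degrees.
#' @return A `pose3d`.
#' @export
facing_pose <- function(center_mm = c(0, 0, 150), roll_deg = 0,
                        pitch_deg = 0, yaw_deg = 0) {
  d2r <- pi / 180
  Rx <- rodrigues_to_matrix(c(roll_deg * d2r, 0, 0))
  Ry <- rodrigues_to_matrix(c(0, pitch_deg * d2r, 0))
  Rz <- rodrigues_to_matrix(c(0, 0, yaw_deg * d2r))
  base <- diag(c(1, -1, -1))  # marker face normal toward the camera
  pose3d(base %*% Rz %*% Ry %*% Rx, center_mm)
}

#' Render a synthetic frame containing the instrument markers
#'
#' Draws the markers at a known instrument pose over a desaturated gray
#' background and returns the frame together with the exact 3D tip position
#' implied by the pose and the marker tip offsets, so rendered frames serve
#' as ground truth for the tracking pipeline.
#'
#' @param camera A `camera_model` (zero distortion renders fastest; nonzero
#'   distortion is applied per subsample).
#' @param pose A `pose3d`: instrument frame -> camera frame.
#' @param markers List of `marker_spec`; at least one must be fully inside
#'   the field of view.
#' @param noise_px Standard deviation (pixels) of a random in-plane jitter
#'   applied to each marker's projected shape; also adds mild intensity
#'   noise. 0 renders the exact geometry.
#' @param seed Integer seed for the jitter/noise; ignored when `noise_px = 0`.
#' @param background Gray level of the background, 0-1.
#' @param supersample Anti-aliasing subsamples per pixel axis.
#' @return List with `image` (h x w x 3 array in [0, 1]), `tip_mm` (exact
#'   3D tip position, camera frame), `visible` (logical per marker) and
#'   `truth` (per-marker projected corner/ring-centre coordinates, px).
#' @export
render_marker_frame <- function(camera, pose, markers = default_marker_specs(),
                                noise_px = 0, seed = NULL,
                                background = 0.45, supersample = 12L) {
  check_marker_specs(markers)
  stopifnot(noise_px >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- camera$image_size[1]; h <- camera$image_size[2]

  outline_points <- function(spec) {
    g <- marker_geometry(spec)
    if (spec$kind == "rectangle") return(g$corners)
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    ro <- g$ring_radius + g$ring_width / 2
    do.call(rbind, lapply(seq_len(3), function(i)
      cbind(g$centers[i, 1] + ro * cos(th),
            g$centers[i, 2] + ro * sin(th), 0)))
  }

  # marker-local -> camera rigid transforms
  total <- lapply(markers, function(m) {
    L <- marker_local_pose(m)
    list(R = pose$R %*% L$R, t = as.numeric(pose$R %*% L$t) + pose$t)
  })
  cam_pts <- lapply(seq_along(markers), function(i)
    sweep(outline_points(markers[[i]]) %*% t(total[[i]]$R), 2,
          total[[i]]$t, `+`))
  facing <- vapply(seq_along(markers), function(i) {
    n <- total[[i]]$R[, 3]; ctr <- total[[i]]$t
    -sum(n * ctr) / sqrt(sum(ctr^2)) > cos(80 * pi / 180)
  }, logical(1))
  visible <- vapply(seq_along(markers), function(i) {
    p <- cam_pts[[i]]
    if (!facing[i] || any(p[, 3] <= 1)) return(FALSE)
    px <- project_points(camera, p)
    all(px[, 1] >= 0 & px[, 1] <= w & px[, 2] >= 0 & px[, 2] <= h)
  }, logical(1))
  if (!any(visible)) stop("marker not visible")

  img <- array(background, dim = c(h, w, 3))
  has_dist <- any(camera$distortion != 0)

  ss <- as.integer(supersample)
  off <- (seq_len(ss) - 0.5) / ss - 0.5

  truth <- vector("list", length(markers))
  names(truth) <- vapply(markers, `[[`, "", "marker_id")

  for (mi in seq_along(markers)) {
    spec <- markers[[mi]]
    g <- marker_geometry(spec)
    Rt <- total[[mi]]
    to_cam <- function(p_local)
      sweep(matrix(p_local, ncol = 3) %*% t(Rt$R), 2, Rt$t, `+`)
    Hn <- cbind(Rt$R[, 1], Rt$R[, 2], Rt$t)  # local plane -> normalized
    jitter <- if (noise_px > 0) stats::rnorm(2, 0, noise_px) else c(0, 0)

    # exact projected primitives (without jitter) for ground truth
    if (spec$kind == "rectangle") {
      truth[[mi]] <- list(kind = "rectangle",
                          corners_px = if (all(to_cam(g$corners)[, 3] > 0))
                            project_points(camera, to_cam(g$corners)))
    } else {
      truth[[mi]] <- list(kind = "ring_triplet",
                          centers_px = if (all(to_cam(g$centers)[, 3] > 0))
                            project_points(camera, to_cam(g$centers)))
    }
    if (!visible[mi]) next
    Hn_inv <- solve(Hn)

    px <- project_points(camera, cam_pts[[mi]])
    x0 <- max(1L, floor(min(px[, 1])) - 2L)
    x1 <- min(w, ceiling(max(px[, 1])) + 2L)
    y0 <- max(1L, floor(min(px[, 2])) - 2L)
    y1 <- min(h, ceiling(max(px[, 2])) + 2L)
    if (x1 < x0 || y1 < y0) next

    xs <- seq(x0, x1); ys <- seq(y0, y1)
    nx <- length(xs); ny <- length(ys)
    # jittered stratified subsampling: each pixel draws its subsample
    # positions from a deterministic per-pixel hash, so the coverage
    # quantization error is uncorrelated between pixels (an aligned grid
    # biases whole edge runs by the same fraction of a stratum)
    sub <- expand.grid(kx = seq_len(ss) - 1, ky = seq_len(ss) - 1)
    cov <- matrix(0, ny, nx)
    pcx <- rep(xs - 0.5, each = ny) + 0  # column-major: rows vary fastest
    pcy <- rep(ys - 0.5, times = nx)
    hash01 <- function(a, b, k) {
      x <- sin(a * 12.9898 + b * 78.233 + k * 37.719) * 43758.5453
      x - floor(x)
    }
    for (k in seq_len(nrow(sub))) {
      jx <- hash01(pcx, pcy, k)
      jy <- hash01(pcy, pcx, k + 0.5)
      u <- pcx + (sub$kx[k] + jx) / ss - 0.5 - jitter[1]
      v <- pcy + (sub$ky[k] + jy) / ss - 0.5 - jitter[2]
      xyn <- cbind((u - camera$cx) / camera$fx, (v - camera$cy) / camera$fy)
      if (has_dist) xyn <- undistort_normalized(camera, xyn)
      pl <- cbind(xyn, 1) %*% t(Hn_inv)
      X <- pl[, 1] / pl[, 3]; Y <- pl[, 2] / pl[, 3]
      if (spec$kind == "rectangle") {
        wd <- spec$dimensions$width_mm / 2
        ht <- spec$dimensions$height_mm / 2
        inside <- abs(X) <= wd & abs(Y) <= ht
      } else {
        inside <- rep(FALSE, length(X))
        for (ri in seq_len(3)) {
          r <- sqrt((X - g$centers[ri, 1])^2 + (Y - g$centers[ri, 2])^2)
          inside <- inside | abs(r - g$ring_radius) <= g$ring_width / 2
        }
      }
      cov <- cov + matrix(as.numeric(inside), ny, nx)
    }
    cov <- cov / nrow(sub)
    col <- hsv_mid_rgb(spec$color_profile)
    for (ch in 1:3) {
      block <- img[ys, xs, ch]
      img[ys, xs, ch] <- block * (1 - cov) + col[ch] * cov
    }
  }

  if (noise_px > 0) {
    img <- img + array(stats::rnorm(length(img), 0, 0.01 * noise_px), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }

  tips <- vapply(markers, function(m)
    pose_apply(pose, marker_tip_instrument(m)), numeric(3))
  list(image = img,
       tip_mm = as.numeric(tips[, 1]),
       visible = visible,
       truth = truth)
}

#' Write frames to a PNG directory
#'
#' @param frames List of rendered frames (as from [render_marker_frame()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(frames[[i]]$image, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of PNG frames
#'
#' @param dir Directory containing PNG files (read in sorted name order).
#' @return List of h x w x 3 arrays.
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
}
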