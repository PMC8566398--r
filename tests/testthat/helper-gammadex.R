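# Shared fixtures: all synthetic, built in code.

test_camera <- function() default_camera()
test_specs <- function() default_marker_specs()

# Random instrument pose in the documented working range: 12-18 cm from
# the endoscope, tilted so both the shaft rectangle and the housing rings
# face the camera.
random_working_pose <- function() {
  facing_pose(center_mm = c(stats::runif(1, -25, 25),
                            stats::runif(1, -15, 15),
                            stats::runif(1, 120, 180)),
              roll_deg = stats::runif(1, -55, -15),
              pitch_deg = stats::runif(1, -20, 20),
              yaw_deg = stats::runif(1, -20, 20))
}

render_visible <- function(camera, max_tries = 20, ...) {
  for (k in seq_len(max_tries)) {
    pose <- random_working_pose()
    fr <- try(render_marker_frame(camera, pose, ...), silent = TRUE)
    if (!inherits(fr, "try-error") && fr$visible[1])
      return(list(pose = pose, frame = fr))
  }
  stop("no visible pose found")
}

track_one_frame <- function(frame, camera = test_camera(),
                            specs = test_specs(), hint = NULL) {
  seg <- segment_markers(frame, specs)
  dets <- classify_marker(seg, specs)
  estimate_tip_position(dets, camera, specs, hint_tip_cam = hint)
}

# Straight-line constant-velocity trajectory fixture.
line_trajectory <- function(n = 26, v = c(10, 0, 0), origin = c(0, 0, 150),
                            fps = 25) {
  t <- (seq_len(n) - 1) / fps
  trajectory(t, sweep(outer(t, v), 2, origin, `+`), fps = fps)
}

# Uniform circular motion in the xy-plane at fixed z.
circle_trajectory <- function(radius = 50, omega = 1, fps = 50,
                              n = 4 * fps, z = 150) {
  t <- (seq_len(n) - 1) / fps
  trajectory(t, cbind(radius * cos(omega * t), radius * sin(omega * t), z),
             fps = fps)
}

random_rotation <- function() {
  v <- stats::rnorm(3)
  rodrigues_to_matrix_test(v / sqrt(sum(v^2)) * stats::runif(1, 0, pi))
}

# independent Rodrigues implementation for tests
rodrigues_to_matrix_test <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_trajectory <- function(traj, R = diag(3), shift = c(0, 0, 0),
                                 scale = 1) {
  xyz <- as.matrix(traj[, c("x_mm", "y_mm", "z_mm")])
  xyz2 <- sweep(scale * (xyz %*% t(R)), 2, shift, `+`)
  trajectory(traj$t_s, xyz2, traj$valid, traj$source,
             fps = attr(traj, "fps"), trial_id = attr(traj, "trial_id"))
}

# synthetic calibration views from a known camera
synth_calib_views <- function(truth, n_views = 10, noise_px = 0) {
  board <- as.matrix(expand.grid(x = seq(0, 120, 15), y = seq(0, 90, 15)))
  lapply(seq_len(n_views), function(i) {
    R <- rodrigues_to_matrix_test(c(stats::runif(1, -0.4, 0.4),
                                    stats::runif(1, -0.4, 0.4),
                                    stats::runif(1, -0.4, 0.4))) %*%
      diag(c(1, -1, -1))
    t <- c(stats::runif(1, -70, -30), stats::runif(1, -55, -25),
           stats::runif(1, 260, 420))
    P <- sweep(cbind(board, 0) %*% t(R), 2, t, `+`)
    img <- project_points(truth, P)
    if (noise_px > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_px), ncol = 2)
    list(image = img, board = board)
  })
}
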