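test_that("central projection maps the optical axis to the principal point", {
  cam <- camera_model(1000, 1000, 960, 540, c(1920, 1080))
  expect_equal(as.numeric(project_points(cam, c(0, 0, 150))), c(960, 540))
  # similar triangles: 15 mm lateral at 150 mm with fx = 1000 -> 100 px
  expect_equal(as.numeric(project_points(cam, c(15, 0, 150))),
               c(1060, 540))
})

test_that("points behind the camera are rejected", {
  cam <- test_camera()
  expect_error(project_points(cam, c(0, 0, -5)), "behind camera")
  expect_error(project_points(cam, c(0, 0, 0)), "behind camera")
})

test_that("project and back-project are inverse up to depth", {
  cam_nd <- test_camera()
  cam_d <- camera_model(700, 700, 480, 270, c(960, 540),
                        distortion = c(-0.15, 0.04, 0.001, -0.002))
  set.seed(1)
  for (cam in list(cam_nd, cam_d)) {
    tol_mm <- if (all(cam$distortion == 0)) 1e-6 else 1e-3
    pts <- cbind(runif(100, -40, 40), runif(100, -30, 30),
                 runif(100, 100, 250))
    px <- project_points(cam, pts)
    rays <- back_project_ray(cam, px)
    rec <- rays * (pts[, 3] / rays[, 3])
    expect_lt(max(abs(rec - pts)), tol_mm)
  }
})

test_that("undistort inverts distort to sub-microdevice precision", {
  cam <- camera_model(700, 700, 480, 270, c(960, 540),
                      distortion = c(-0.2, 0.05, 0.002, -0.001))
  set.seed(2)
  xy <- cbind(runif(200, -0.5, 0.5), runif(200, -0.4, 0.4))
  rt <- gammadex:::undistort_normalized(cam, gammadex:::distort_normalized(cam, xy))
  # 1e-6 px at fx = 700 is ~1.4e-9 in normalized units
  expect_lt(max(abs(rt - xy)) * cam$fx, 1e-6)
})

test_that("pose composition, inverse and application behave rigidly", {
  set.seed(3)
  R <- rodrigues_to_matrix_test(c(0.3, -0.2, 0.5))
  p <- pose3d(R, c(10, -5, 100))
  q <- pose_compose(p, pose_inverse(p))
  expect_lt(max(abs(q$R - diag(3))), 1e-9)
  expect_lt(max(abs(q$t)), 1e-9)
  x <- matrix(rnorm(30), 10, 3)
  y <- pose_apply(p, x)
  expect_equal(pose_apply(pose_inverse(p), y), x, tolerance = 1e-9)
  expect_error(pose3d(diag(3) * 2, c(0, 0, 0)), "orthonormal")
})

test_that("camera model JSON round-trips with units and rms metadata", {
  cam <- camera_model(712.5, 709.1, 481.25, 268.5, c(960, 540),
                      distortion = c(-0.1, 0.02, 0, 0))
  attr(cam, "rms_reprojection_px") <- 0.37
  path <- tempfile(fileext = ".json")
  write_camera_json(cam, path)
  cam2 <- read_camera_json(path)
  expect_equal(cam2$fx, cam$fx)
  expect_equal(cam2$distortion, cam$distortion)
  expect_equal(attr(cam2, "rms_reprojection_px"), 0.37)
})

test_that("corner CSV reader groups correspondences by view", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(view = rep(1:3, each = 4),
                   u_px = runif(12, 0, 960), v_px = runif(12, 0, 540),
                   x_mm = rep(c(0, 10, 10, 0), 3),
                   y_mm = rep(c(0, 0, 10, 10), 3))
  write.csv(df, path, row.names = FALSE)
  views <- read_corner_csv(path)
  expect_length(views, 3)
  expect_equal(dim(views[[1]]$image), c(4, 2))
})

test_that("calibration recovers intrinsics exactly from noiseless views", {
  set.seed(10)
  truth <- camera_model(760, 755, 470, 265, c(960, 540),
                        distortion = c(-0.12, 0.03, 0.001, -0.0005))
  views <- synth_calib_views(truth, 10)
  cam <- calibrate_intrinsics(views, c(960, 540))
  expect_lt(abs(cam$fx - truth$fx) / truth$fx, 1e-3)
  expect_lt(abs(cam$fy - truth$fy) / truth$fy, 1e-3)
  expect_lt(max(abs(cam$distortion - truth$distortion)), 1e-4)
  expect_lt(attr(cam, "rms_reprojection_px"), 1e-6)
})

test_that("calibration with 0.5 px corner noise stays below 1 px rms", {
  set.seed(11)
  truth <- camera_model(760, 755, 470, 265, c(960, 540))
  views <- synth_calib_views(truth, 10, noise_px = 0.5)
  cam <- calibrate_intrinsics(views, c(960, 540))
  expect_lt(attr(cam, "rms_reprojection_px"), 1)
  expect_lt(abs(cam$fx - truth$fx) / truth$fx, 0.02)
})

test_that("calibration refuses degenerate input", {
  set.seed(12)
  truth <- camera_model(700, 700, 480, 270, c(960, 540))
  views <- synth_calib_views(truth, 2)
  expect_error(calibrate_intrinsics(views, c(960, 540)), "insufficient")
  # collinear corners
  bad <- list(image = cbind(1:5, 1:5), board = cbind(1:5 * 10, 1:5 * 10))
  expect_error(calibrate_intrinsics(list(bad, bad, bad), c(960, 540)),
               "collinear")
})

test_that("calibration is reprojection-consistent and scale-equivariant", {
  set.seed(13)
  truth <- camera_model(720, 715, 475, 272, c(960, 540))
  views <- synth_calib_views(truth, 8, noise_px = 0.3)
  cam <- calibrate_intrinsics(views, c(960, 540))
  # recompute the rms independently from the returned extrinsics
  ex <- attr(cam, "extrinsics")
  res <- unlist(lapply(seq_along(views), function(i) {
    P <- pose_apply(ex[[i]], cbind(views[[i]]$board, 0))
    as.numeric(project_points(cam, P) - views[[i]]$image)
  }))
  expect_equal(sqrt(mean(res^2)), attr(cam, "rms_reprojection_px"),
               tolerance = 1e-8)
  # scaling the board (and implicitly all depths) leaves intrinsics alone
  views_s <- lapply(views, function(v) {
    v$board <- v$board * 2
    v
  })
  cam_s <- calibrate_intrinsics(views_s, c(960, 540), fit_distortion = FALSE)
  cam_1 <- calibrate_intrinsics(views, c(960, 540), fit_distortion = FALSE)
  expect_equal(cam_s$fx, cam_1$fx, tolerance = 1e-6)
  expect_equal(cam_s$cy, cam_1$cy, tolerance = 1e-4)
})
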