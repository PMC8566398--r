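test_that("noiseless single-frame estimates recover the tip to 0.1 mm", {
  cam <- test_camera(); specs <- test_specs()
  set.seed(21)
  for (k in 1:5) {
    rv <- render_visible(cam)
    tp <- track_one_frame(rv$frame$image)
    expect_true(tp$valid)
    expect_lt(sqrt(sum((tp$position_cam - rv$frame$tip_mm)^2)), 0.1)
    expect_gt(tp$position[3], 0)
    # output frame flips y and keeps z as the distance from the camera
    expect_equal(tp$position,
                 c(tp$position_cam[1], -tp$position_cam[2],
                   tp$position_cam[3]))
  }
})

test_that("tip estimate is translation-equivariant at zero noise", {
  cam <- test_camera(); specs <- test_specs()
  set.seed(22)
  base <- facing_pose(c(0, 0, 150), roll_deg = -35)
  delta <- c(8, -5, 12)
  f1 <- render_marker_frame(cam, base)
  f2 <- render_marker_frame(cam, pose3d(base$R, base$t + delta))
  t1 <- track_one_frame(f1$image)
  t2 <- track_one_frame(f2$image)
  expect_equal(t2$position_cam - t1$position_cam, delta, tolerance = 0.02)
})

test_that("doubling the ring spacing in the spec doubles the recovered depth", {
  cam <- test_camera(); specs <- test_specs()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = -45))
  seg <- segment_markers(fr$image, specs)
  dets <- classify_marker(seg, specs)
  rings <- Filter(function(d) d$kind == "ring_triplet", dets)[[1]]
  # zero tip offset: the "tip" is the first ring centre, whose depth obeys
  # the spacing/depth duality exactly
  spec1 <- specs[[2]]; spec1$tip_offset_mm <- c(0, 0, 0)
  spec2 <- spec1
  spec2$dimensions$spacing_mm <- 2 * spec1$dimensions$spacing_mm
  c1 <- gammadex:::fit_ring_pose(rings$primitives, cam, spec1)
  c2 <- gammadex:::fit_ring_pose(rings$primitives, cam, spec2,
                                 depth_range_mm = c(30, 900))
  expect_equal(c2[[1]]$tip_cam[3] / c1[[1]]$tip_cam[3], 2, tolerance = 0.02)
})

test_that("frames without detections produce invalid track points", {
  cam <- test_camera()
  gray <- array(0.45, dim = c(540, 960, 3))
  tp <- track_one_frame(gray)
  expect_false(tp$valid)
  expect_true(all(is.na(tp$position)))
})

test_that("a lone ring triplet without a prior is declared ambiguous", {
  cam <- test_camera(); specs <- test_specs()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = -85))
  expect_false(fr$visible[1])  # rectangle edge-on
  tp <- track_one_frame(fr$image)
  expect_false(tp$valid)
  # with a prior the ambiguity resolves
  tp2 <- track_one_frame(fr$image, hint = fr$tip_mm + c(2, -1, 3))
  expect_true(tp2$valid)
  expect_lt(sqrt(sum((tp2$position_cam - fr$tip_mm)^2)), 1)
})

test_that("a translation sweep tracks with sub-0.2 mm per-axis rms", {
  cam <- test_camera(); specs <- test_specs()
  n <- 100
  frames <- vector("list", n); truth <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u <- (i - 1) / (n - 1)
    pose <- facing_pose(c(-20 + 40 * u, -10 + 15 * u, 135 + 25 * u),
                        roll_deg = -40 + 15 * u, pitch_deg = 8 * u,
                        yaw_deg = -5 + 10 * u)
    fr <- render_marker_frame(cam, pose)
    frames[[i]] <- fr$image
    truth[i, ] <- fr$tip_mm
  }
  traj <- track_sequence(frames, cam, specs, fps = 25)
  expect_true(all(traj$valid))
  est_cam <- cbind(traj$x_mm, -traj$y_mm, traj$z_mm)
  rms <- sqrt(colMeans((est_cam - truth)^2))
  expect_true(all(rms <= 0.2))
  expect_true(all(traj$z_mm > 0))
})

test_that("marker hand-off during a roll sweep leaves no gap over 2 frames", {
  cam <- test_camera(); specs <- test_specs()
  rolls <- seq(-5, -85, length.out = 40)
  frames <- lapply(rolls, function(r)
    render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = r))$image)
  traj <- track_sequence(frames, cam, specs, fps = 25)
  r <- rle(!traj$valid)
  max_gap <- if (any(r$values)) max(r$lengths[r$values]) else 0
  expect_lte(max_gap, 2)
  # both markers supplied estimates somewhere along the sweep
  expect_gt(sum(traj$valid), 30)
})

test_that("mid-sequence invisible frames are invalid, the rest measured", {
  cam <- test_camera(); specs <- test_specs()
  good <- render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = -35))
  gray <- array(0.45, dim = c(540, 960, 3))
  frames <- c(rep(list(good$image), 4), rep(list(gray), 3),
              rep(list(good$image), 3))
  traj <- track_sequence(frames, cam, specs, fps = 25)
  expect_equal(traj$valid, c(rep(TRUE, 4), rep(FALSE, 3), rep(TRUE, 3)))
  expect_true(all(traj$source[traj$valid] == "measured"))
})

test_that("tracking accuracy assessment reports per-axis mean and sd", {
  truth <- matrix(rnorm(60), 20, 3)
  # identical estimates: 0 +/- 0 on each axis
  acc <- assess_tracking_accuracy(truth, truth)
  expect_equal(acc$mean_abs_mm, rep(0, 3))
  expect_equal(acc$sd_abs_mm, rep(0, 3))
  # constant +1 mm x bias: 1 +/- 0 on x
  est <- truth; est[, 1] <- est[, 1] + 1
  acc2 <- assess_tracking_accuracy(truth, est)
  expect_equal(acc2$mean_abs_mm, c(1, 0, 0))
  expect_equal(acc2$sd_abs_mm[1], 0)
  expect_error(assess_tracking_accuracy(truth, est[1:10, ]), "unpaired")
})

test_that("gaussian error of sd 0.5 mm gives half-normal mean near 0.4 mm", {
  set.seed(23)
  truth <- matrix(0, 20000, 3)
  est <- truth + matrix(rnorm(60000, 0, 0.5), ncol = 3)
  acc <- assess_tracking_accuracy(truth, est)
  expect_equal(acc$mean_abs_mm, rep(0.5 * sqrt(2 / pi), 3),
               tolerance = 0.02)
})
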