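test_that("a marker on the optical axis renders centred at the principal point", {
  cam <- test_camera()
  rect_only <- test_specs()[1]
  pose <- facing_pose(c(0, 0, 150))
  fr <- render_marker_frame(cam, pose, rect_only)
  corners <- fr$truth[[1]]$corners_px
  expect_equal(colMeans(corners), c(cam$cx, cam$cy), tolerance = 1e-9)
  # tip ground truth is the pose applied to the tip offset
  expect_equal(fr$tip_mm, as.numeric(pose$R %*% c(35, 0, 0)) + pose$t)
})

test_that("doubling the focal length doubles the projected side lengths", {
  rect_only <- test_specs()[1]
  pose <- facing_pose(c(0, 0, 150))
  c1 <- render_marker_frame(test_camera(), pose, rect_only)$truth[[1]]$corners_px
  cam2 <- camera_model(1400, 1400, 480, 270, c(960, 540))
  c2 <- render_marker_frame(cam2, pose, rect_only)$truth[[1]]$corners_px
  side <- function(cc) sqrt(sum((cc[2, ] - cc[1, ])^2))
  expect_equal(side(c2) / side(c1), 2, tolerance = 1e-9)
})

test_that("invisible poses and empty marker lists are errors", {
  cam <- test_camera()
  expect_error(render_marker_frame(cam, facing_pose(c(0, 0, -150))),
               "not visible")
  expect_error(render_marker_frame(cam, facing_pose(c(500, 0, 150))),
               "not visible")
  expect_error(render_marker_frame(cam, facing_pose(), list()), "empty")
})

test_that("segmentation finds nothing in an all-gray frame", {
  frame <- array(0.45, dim = c(120, 160, 3))
  seg <- segment_markers(frame, test_specs())
  expect_length(seg$classes[[1]]$regions, 0)
  expect_length(seg$classes[[2]]$regions, 0)
})

test_that("a rendered cyan rectangle yields one region matching its bbox", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150)), test_specs()[1])
  seg <- segment_markers(fr$image, test_specs())
  regs <- seg$classes[["shaft_rect"]]$regions
  expect_length(regs, 1)
  tru <- fr$truth[[1]]$corners_px
  bbox <- regs[[1]]$bbox  # cmin, cmax, rmin, rmax in pixel indices
  expect_lt(abs(bbox[1] - min(tru[, 1])), 1.5)
  expect_lt(abs(bbox[2] - max(tru[, 1])), 1.5)
  expect_lt(abs(bbox[3] - min(tru[, 2])), 1.5)
  expect_lt(abs(bbox[4] - max(tru[, 2])), 1.5)
})

test_that("three rendered rings give three regions with collinear centroids", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = -45))
  seg <- segment_markers(fr$image, test_specs())
  regs <- seg$classes[["housing_rings"]]$regions
  expect_length(regs, 3)
  cents <- do.call(rbind, lapply(regs, `[[`, "centroid_px"))
  fit <- gammadex:::tls_line(cents)
  expect_lt(fit$rms, 0.5)
})

test_that("classification detects both marker kinds with ordered primitives", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(5, -3, 150), roll_deg = -35))
  seg <- segment_markers(fr$image, test_specs())
  dets <- classify_marker(seg, test_specs())
  kinds <- vapply(dets, `[[`, "", "kind")
  expect_setequal(kinds, c("rectangle", "ring_triplet"))
  rect <- dets[[which(kinds == "rectangle")]]
  expect_equal(nrow(rect$primitives), 4)
  # corners within 0.5 px of the projected truth
  tru <- gammadex:::order_corners(fr$truth[[1]]$corners_px)
  meas <- gammadex:::order_corners(rect$primitives)
  expect_lt(max(sqrt(rowSums((meas - tru)^2))), 0.5)
  rings <- dets[[which(kinds == "ring_triplet")]]
  expect_equal(nrow(rings$primitives), 3)
  gaps <- sqrt(rowSums(diff(rings$primitives)^2))
  expect_gt(min(gaps / rev(gaps)), 0.8)
})

test_that("a distractor blob does not break the collinear triplet", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150), roll_deg = -45))
  img <- fr$image
  # paint a square yellow distractor away from the ring line
  yc <- grDevices::col2rgb(grDevices::hsv(0.16, 0.9, 0.9)) / 255
  img[60:75, 700:715, 1] <- yc[1]
  img[60:75, 700:715, 2] <- yc[2]
  img[60:75, 700:715, 3] <- yc[3]
  seg <- segment_markers(img, test_specs())
  expect_length(seg$classes[["housing_rings"]]$regions, 4)
  dets <- classify_marker(seg, test_specs())
  rings <- Filter(function(d) d$kind == "ring_triplet", dets)
  expect_length(rings, 1)
  tru <- fr$truth[[2]]$centers_px
  ord <- gammadex:::tls_line(tru)
  # detected centres match the rendered rings, not the distractor
  for (i in 1:3) {
    dmin <- min(sqrt(rowSums(sweep(rings[[1]]$primitives, 2,
                                   tru[i, ])^2)))
    expect_lt(dmin, 1)
  }
})

test_that("a rectangle occluded to three corners is not detected", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150)), test_specs()[1])
  img <- fr$image
  tru <- fr$truth[[1]]$corners_px
  # gray out a full quadrant so only three corners stay visible
  cx0 <- round(min(tru[, 1])) - 3; cx1 <- round(mean(tru[, 1]))
  cy0 <- round(min(tru[, 2])) - 3; cy1 <- round(mean(tru[, 2]))
  img[cy0:cy1, cx0:cx1, ] <- 0.45
  seg <- segment_markers(img, test_specs())
  dets <- classify_marker(seg, test_specs())
  expect_length(Filter(function(d) d$kind == "rectangle", dets), 0)
})

test_that("frames round-trip through a PNG directory", {
  cam <- test_camera()
  fr <- render_marker_frame(cam, facing_pose(c(0, 0, 150)))
  dir <- tempfile()
  write_frames_png(list(fr), dir)
  back <- read_frames_png(dir)
  expect_length(back, 1)
  # 8-bit quantization only
  expect_lt(max(abs(back[[1]] - fr$image)), 1 / 255)
})
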