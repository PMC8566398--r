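test_that("path length and completion time match simple geometry", {
  tr <- line_trajectory(n = 11, v = c(10, 0, 0), fps = 10)  # 1 s, 10 mm
  expect_equal(path_length(tr), 10)
  expect_equal(completion_time(tr), 1)

  # closed square, side 10 mm
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  interp <- do.call(rbind, lapply(1:4, function(i) {
    u <- seq(0, 1, length.out = 11)[-11]
    outer(1 - u, sq[i, ]) + outer(u, sq[i + 1, ])
  }))
  interp <- rbind(interp, sq[5, ])
  tsq <- trajectory((seq_len(nrow(interp)) - 1) / 25,
                    cbind(interp, 150), fps = 25)
  expect_equal(path_length(tsq), 40)
  expect_error(path_length(line_trajectory(n = 1)), ">= 2")
})

test_that("phantom trial path length matches the per-segment script sum", {
  sim <- simulate_phantom_trial(skill = 1, seed = 9)
  seg_sum <- sum(sqrt(rowSums((sim$script$end - sim$script$start)^2)))
  expect_equal(path_length(sim$trajectory), seg_sum, tolerance = 1e-9)
  # with tremor the path can only be longer
  sim2 <- simulate_phantom_trial(skill = 0.5, seed = 9)
  expect_gt(path_length(sim2$trajectory), seg_sum)
})

test_that("kinematics of uniform circular motion match closed forms", {
  tr <- circle_trajectory(radius = 50, omega = 1, fps = 50)
  k <- kinematics(tr)
  ki <- k[k$interior, ]
  expect_equal(median(ki$speed_mms), 50, tolerance = 1e-3)
  expect_equal(median(ki$curvature_per_mm), 1 / 50, tolerance = 1e-3)
  expect_equal(median(ki$accel_mms2), 50, tolerance = 1e-2)
})

test_that("straight constant-velocity motion has zero higher derivatives", {
  tr <- line_trajectory(n = 30, v = c(12, -3, 4))
  k <- kinematics(tr)
  ki <- k[k$interior, ]
  expect_lt(max(ki$accel_mms2), 1e-9)
  expect_lt(max(ki$jerk_mms3), 1e-9)
  expect_lt(max(ki$curvature_per_mm), 1e-9)
  expect_error(kinematics(line_trajectory(n = 3)), ">= 4")
})

test_that("finite-difference jerk matches the cubic's analytic derivative", {
  fps <- 100
  t <- (0:199) / fps
  # cubic path: third derivative is constant (6a3, 6b3, 6c3)
  xyz <- cbind(2 + t - 0.5 * t^2 + 0.8 * t^3,
               1 + 2 * t + 0.3 * t^2 - 0.4 * t^3,
               150 + 0.5 * t + 0.2 * t^3)
  tr <- trajectory(t, xyz, fps = fps)
  k <- kinematics(tr)
  jerk_true <- sqrt(sum((6 * c(0.8, -0.4, 0.2))^2))
  ki <- k[k$interior, ]
  expect_equal(median(ki$jerk_mms3), jerk_true, tolerance = 1e-6)
})

test_that("straightness index spans its [0, 1] range as designed", {
  expect_equal(straightness_index(line_trajectory()), 1)
  loop <- circle_trajectory(fps = 50, n = 315)  # ~ full circle (2*pi s)
  expect_lt(straightness_index(loop), 0.05)
  zero <- trajectory(c(0, 0.04), matrix(1, 2, 3), fps = 25)
  expect_error(straightness_index(zero), "zero path length")
})

test_that("home-target-home-bucket task straightness matches the anchor form", {
  lay <- task_layout()
  sim <- simulate_phantom_trial(lay, "dropin", skill = 1, seed = 2)
  pl <- sum(sqrt(rowSums((sim$script$end - sim$script$start)^2)))
  net <- sqrt(sum((lay$home - lay$home)^2))  # script returns home: net 0
  si <- straightness_index(sim$trajectory)
  expect_equal(si, net / pl, tolerance = 1e-9)
  expect_lt(si, 0.05)
})

test_that("angular dispersion is 1 for aligned, 0 for cancelling steps", {
  expect_equal(angular_dispersion(line_trajectory()), 1)
  # alternate +x / -x steps
  x <- rep(c(0, 1), 20)
  tr <- trajectory((seq_along(x) - 1) / 25, cbind(x, 0, 150), fps = 25)
  expect_lt(angular_dispersion(tr), 0.03)
})

test_that("isotropic random steps give near-zero mean resultant length", {
  set.seed(33)
  n <- 10000
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(0, apply(dirs, 2, cumsum))
  tr <- trajectory((0:n) / 25, sweep(xyz, 2, c(0, 0, 500), `+`), fps = 25)
  expect_lt(angular_dispersion(tr), 0.02)
})

test_that("trial summary agrees with a brute-force recomputation", {
  sim <- simulate_phantom_trial(skill = 0.6, seed = 4)
  tr <- process_trajectory(sim$trajectory)
  f <- summarize_trial(tr)

  # independent recomputation from the raw coordinate columns
  xyz <- as.matrix(tr[, c("x_mm", "y_mm", "z_mm")])
  dt <- 1 / attr(tr, "fps")
  n <- nrow(xyz)
  expect_equal(f$completion_time_s, (n - 1) * dt, tolerance = 1e-9)
  expect_equal(f$path_length_mm,
               sum(sqrt(rowSums(diff(xyz)^2))), tolerance = 1e-9)
  expect_equal(f$straightness_index,
               sqrt(sum((xyz[n, ] - xyz[1, ])^2)) /
                 sum(sqrt(rowSums(diff(xyz)^2))), tolerance = 1e-9)
  steps <- diff(xyz); len <- sqrt(rowSums(steps^2))
  u <- steps[len > 0, ] / len[len > 0]
  expect_equal(f$angular_dispersion,
               sqrt(sum(colSums(u)^2)) / nrow(u), tolerance = 1e-9)
  d1 <- function(m) rbind(m[2, ] - m[1, ],
                          (m[3:n, ] - m[1:(n - 2), ]) / 2,
                          m[n, ] - m[n - 1, ]) / dt
  v <- d1(xyz); a <- d1(v); j <- d1(a)
  interior <- 4:(n - 3)
  expect_equal(f$median_speed_mms,
               median(sqrt(rowSums(v^2))[interior]), tolerance = 1e-9)
  expect_equal(f$median_accel_mms2,
               median(sqrt(rowSums(a^2))[interior]), tolerance = 1e-9)
  expect_equal(f$median_jerk_mms3,
               median(sqrt(rowSums(j^2))[interior]), tolerance = 1e-9)
  cr <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
              v[, 3] * a[, 1] - v[, 1] * a[, 3],
              v[, 1] * a[, 2] - v[, 2] * a[, 1])
  sp <- sqrt(rowSums(v^2))
  curv <- ifelse(sp < 1e-3, 0, sqrt(rowSums(cr^2)) / pmax(sp, 1e-3)^3)
  expect_equal(f$median_curvature_per_mm, median(curv[interior]),
               tolerance = 1e-9)
})

test_that("circular motion summary returns curvature 1/radius", {
  f <- summarize_trial(circle_trajectory(radius = 40, fps = 50))
  expect_equal(f$median_curvature_per_mm, 1 / 40, tolerance = 1e-3)
  expect_lte(f$straightness_index, 1)
  expect_gte(f$path_length_mm,
             sqrt(sum((c(40, 0, 150) - c(40, 0, 150))^2)))
})

test_that("paired comparison matches the closed-form t statistic", {
  a <- data.frame(path_length_mm = c(10, 12, 9, 14, 11))
  b <- data.frame(path_length_mm = c(8, 11, 9, 10, 10))
  res <- paired_comparison(a, b)
  d <- a$path_length_mm - b$path_length_mm
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
})

test_that("degenerate paired differences are handled per contract", {
  a <- data.frame(path_length_mm = c(1, 2, 3))
  expect_warning(res <- paired_comparison(a, a), "zero variance")
  expect_equal(res$t, 0)  # identical samples: t = 0, p = 1
  expect_equal(res$p, 1)
  b <- data.frame(path_length_mm = c(2, 3, 4))  # differences all -1
  expect_warning(res2 <- paired_comparison(a, b), "zero variance")
  expect_equal(res2$p, 0)
  expect_true(is.infinite(res2$t))
})
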