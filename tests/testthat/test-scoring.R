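toy_features <- function(n = 10, seed = 50) {
  set.seed(seed)
  f <- data.frame(trial_id = sprintf("t%02d", 1:n),
                  completion_time_s = runif(n, 20, 60),
                  path_length_mm = runif(n, 300, 900),
                  straightness_index = runif(n, 0.01, 0.2),
                  angular_dispersion = runif(n, 0.5, 0.9),
                  median_speed_mms = runif(n, 10, 40),
                  median_accel_mms2 = runif(n, 1, 10),
                  median_curvature_per_mm = runif(n, 0.01, 0.2),
                  median_jerk_mms3 = runif(n, 50, 500),
                  stringsAsFactors = FALSE)
  f
}

test_that("design matrix is standardized with the distance covariate", {
  f <- toy_features(6)
  oc <- data.frame(trial_id = f$trial_id,
                   success = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  fp <- matrix(runif(18, -20, 20), 6, 3)
  d <- build_design(f, oc, fp, target_mm = c(0, 0, 150))
  expect_equal(dim(d$X), c(6, 9))
  expect_equal(unname(colMeans(d$X)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, 9), tolerance = 1e-12)
  expect_equal(d$y, c(1, 0, 1, 1, 0, 0))
  expect_true("final_target_distance_mm" %in% d$feature_names)
})

test_that("constant columns are dropped and missing outcomes are errors", {
  f <- toy_features(6)
  f$median_jerk_mms3 <- 7
  oc <- data.frame(trial_id = f$trial_id, success = rep(c(TRUE, FALSE), 3))
  expect_warning(d <- build_design(f, oc), "constant")
  expect_false("median_jerk_mms3" %in% d$feature_names)
  expect_error(build_design(toy_features(6),
                            data.frame(trial_id = "x", success = TRUE)),
               "missing outcomes")
})

test_that("design building is invariant to input row order", {
  f <- toy_features(8)
  oc <- data.frame(trial_id = f$trial_id,
                   success = rep(c(TRUE, FALSE), 4))
  d1 <- build_design(f, oc)
  perm <- sample(8)
  d2 <- build_design(f[perm, ], oc)
  expect_equal(d2$X[order(perm), ], d1$X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d2$y[order(perm)], d1$y)
})

test_that("penalized fit separates a separable 1-D toy", {
  x <- c(-3, -2, -1.5, 1.2, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  X <- matrix((x - mean(x)) / sd(x), ncol = 1,
              dimnames = list(NULL, "f"))
  d <- list(X = X, y = y, center = mean(x), scale = sd(x),
            feature_names = "f")
  m <- fit_logistic(d, l2_strength = 1)
  p <- gammadex:::sigmoid(as.numeric(X %*% m$weights) + m$intercept)
  expect_true(all(p[y == 1] > 0.5))
  expect_true(all(p[y == 0] < 0.5))
  # without the penalty, separation is detected and reported
  expect_error(fit_logistic(d, l2_strength = 0), "separation")
})

test_that("logistic optimum matches a brute-force grid search to 1e-3", {
  set.seed(51)
  x <- c(rnorm(10, -1), rnorm(10, 1))
  y <- c(rep(0, 10), rep(1, 10))
  X <- matrix((x - mean(x)) / sd(x), ncol = 1,
              dimnames = list(NULL, "f"))
  d <- list(X = X, y = y, center = mean(x), scale = sd(x),
            feature_names = "f")
  m <- fit_logistic(d, l2_strength = 1)
  obj <- function(b0, w)
    sum(y * (b0 + w * X[, 1]) - log1p(exp(b0 + w * X[, 1]))) - w^2 / 2
  # two-stage grid: coarse sweep, then fine sweep around the best cell
  g1 <- expand.grid(b0 = seq(-5, 5, 0.05), w = seq(-5, 5, 0.05))
  v1 <- mapply(obj, g1$b0, g1$w)
  c1 <- g1[which.max(v1), ]
  g2 <- expand.grid(b0 = seq(c1$b0 - 0.06, c1$b0 + 0.06, 5e-4),
                    w = seq(c1$w - 0.06, c1$w + 0.06, 5e-4))
  v2 <- mapply(obj, g2$b0, g2$w)
  c2 <- g2[which.max(v2), ]
  expect_lt(abs(m$intercept - c2$b0), 1e-3)
  expect_lt(abs(m$weights - c2$w), 1e-3)
})

test_that("unpenalized fit agrees with glm as an independent reference", {
  set.seed(52)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.5 + x1 - 0.8 * x2))
  X <- scale(cbind(a = x1, b = x2))
  d <- list(X = X[, ], y = y, center = attr(X, "scaled:center"),
            scale = attr(X, "scaled:scale"), feature_names = c("a", "b"))
  m <- fit_logistic(d, l2_strength = 1e-10)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(m$weights), unname(coef(ref)[-1]), tolerance = 1e-6)
})

test_that("scores behave like sigmoids: 0.5 at the mean, monotone, ranked", {
  f <- toy_features(10)
  oc <- data.frame(trial_id = f$trial_id,
                   success = rep(c(TRUE, FALSE), 5))
  d <- build_design(f, oc)
  m <- fit_logistic(d, 1)
  # zero weights forced -> every score 0.5
  m0 <- m; m0$weights <- rep(0, length(m$weights)); m0$intercept <- 0
  s0 <- score_and_rank(m0, f)
  expect_true(all(s0$score == 0.5))
  # monotone in a positively weighted feature
  iw <- which.max(abs(m$weights))
  fname <- m$feature_names[iw]
  f2 <- f[1, , drop = FALSE]
  f2[[fname]] <- f2[[fname]] + sign(m$weights[iw]) * sd(f[[fname]])
  s_base <- score_and_rank(m, f[1, , drop = FALSE])$score
  s_up <- score_and_rank(m, f2)$score
  expect_gt(s_up, s_base)
  # ranking is by descending score with deterministic ties
  s <- score_and_rank(m, f)
  expect_equal(s$rank, seq_len(nrow(s)))
  expect_true(all(diff(s$score) <= 1e-12))
})

test_that("scores are invariant to affine rescaling of raw features", {
  f <- toy_features(12)
  oc <- data.frame(trial_id = f$trial_id,
                   success = rep(c(TRUE, FALSE), 6))
  d1 <- build_design(f, oc)
  m1 <- fit_logistic(d1, 1)
  s1 <- score_and_rank(m1, f)
  f2 <- f
  f2$path_length_mm <- f2$path_length_mm * 1000 + 5   # mm -> odd affine units
  f2$median_speed_mms <- f2$median_speed_mms / 60
  d2 <- build_design(f2, oc)
  m2 <- fit_logistic(d2, 1)
  s2 <- score_and_rank(m2, f2)
  expect_equal(s2$score, s1$score, tolerance = 1e-6)
})

test_that("infinite regularization drives all scores to 0.5", {
  f <- toy_features(10)
  oc <- data.frame(trial_id = f$trial_id,
                   success = rep(c(TRUE, FALSE), 5))
  d <- build_design(f, oc)
  m <- fit_logistic(d, l2_strength = 1e8)
  expect_lt(max(abs(m$weights)), 1e-4)
  s <- score_and_rank(m, f)
  expect_equal(s$score, rep(0.5, 10), tolerance = 1e-3)
})

test_that("label permutation yields chance-level leave-one-out accuracy", {
  set.seed(53)
  f <- toy_features(20)
  oc <- data.frame(trial_id = f$trial_id,
                   success = sample(rep(c(TRUE, FALSE), 10)))
  d <- build_design(f, oc)
  acc <- loo_accuracy(d, 1)
  expect_lt(acc, 0.8)  # no signal: accuracy near chance, never near 1
})

test_that("completion rates follow the outcome table", {
  oc <- data.frame(condition = rep(c("palpation", "radioguided"), each = 4),
                   success = c(TRUE, FALSE, FALSE, FALSE,
                               TRUE, TRUE, TRUE, FALSE))
  expect_equal(completion_rate(oc, "palpation"), 25)
  expect_equal(completion_rate(oc, "radioguided"), 75)
  expect_equal(completion_rate(data.frame(condition = "x", success = FALSE),
                               "x"), 0)
  expect_error(completion_rate(oc, "nope"), "no outcomes")
})

test_that("outcome CSV reader validates the time-limit invariant", {
  path <- tempfile(fileext = ".csv")
  ok <- data.frame(trial_id = "a", condition = "radioguided",
                   success = TRUE, time_to_detection_s = 24)
  write_outcomes_csv(ok, path)
  expect_silent(read_outcomes_csv(path))
  bad <- ok; bad$time_to_detection_s <- 55
  write_outcomes_csv(bad, path)
  expect_error(read_outcomes_csv(path), "invalid")
  bad2 <- ok; bad2$success <- FALSE
  write_outcomes_csv(bad2, path)
  expect_error(read_outcomes_csv(path), "invalid")
})

test_that("dexterity model JSON round-trips and scores identically", {
  f <- toy_features(10)
  oc <- data.frame(trial_id = f$trial_id,
                   success = rep(c(TRUE, FALSE), 5))
  m <- fit_logistic(build_design(f, oc), 1)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(score_and_rank(m2, f)$score, score_and_rank(m, f)$score,
               tolerance = 1e-12)
})
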