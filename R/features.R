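## Trial-level kinematic and dexterity metrics.
##
## Eight metrics per trial: completion time, path length, straightness
## index, angular dispersion, and the trial medians of the per-frame speed,
## acceleration, curvature and smoothness (jerk magnitude). Derivatives use
## central differences at the sampling step; the two boundary frames use
## one-sided stencils and are excluded from the medians.

#' Total path length (mm)
#'
#' Sum of Euclidean step lengths along the trajectory.
#' @param traj A processed `trajectory` with >= 2 points.
#' @return Scalar, mm.
#' @export
path_length <- function(traj) {
  xyz <- traj_xyz(traj)
  if (nrow(xyz) < 2) stop("need >= 2 points")
  sum(sqrt(rowSums(diff(xyz)^2)))
}

#' Completion time (s)
#'
#' @param traj A `trajectory` with >= 2 points.
#' @return t_last - t_first, seconds.
#' @export
completion_time <- function(traj) {
  if (nrow(traj) < 2) stop("need >= 2 points")
  traj$t_s[nrow(traj)] - traj$t_s[1]
}

#' Per-frame kinematics
#'
#' Speed, acceleration, curvature and jerk magnitude (smoothness) at every
#' frame by finite differences at the uniform sampling step: central
#' stencils in the interior, one-sided at the two boundary frames.
#' Curvature kappa = |v x a| / |v|^3, set to 0 where |v| < `v_eps`.
#'
#' @param traj A processed `trajectory` with >= 4 points and uniform
#'   timestamps.
#' @param v_eps Speed threshold (mm/s) below which curvature is degenerate.
#' @return data.frame with columns `t_s`, `speed_mms`, `accel_mms2`,
#'   `jerk_mms3`, `curvature_per_mm` and an `interior` flag.
#' @export
kinematics <- function(traj, v_eps = 1e-3) {
  xyz <- traj_xyz(traj)
  n <- nrow(xyz)
  if (n < 4) stop("need >= 4 points")
  dtv <- diff(traj$t_s)
  if (max(abs(dtv - dtv[1])) > 1e-6 * dtv[1]) stop("non-uniform timestamps")
  dt <- dtv[1]

  deriv <- function(m) {
    d <- m
    d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * dt)
    d[1, ] <- (m[2, ] - m[1, ]) / dt
    d[n, ] <- (m[n, ] - m[n - 1, ]) / dt
    d
  }
  v <- deriv(xyz)
  a <- deriv(v)
  j <- deriv(a)

  speed <- sqrt(rowSums(v^2))
  accel <- sqrt(rowSums(a^2))
  jerk <- sqrt(rowSums(j^2))
  cr <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
              v[, 3] * a[, 1] - v[, 1] * a[, 3],
              v[, 1] * a[, 2] - v[, 2] * a[, 1])
  curv <- ifelse(speed < v_eps, 0, sqrt(rowSums(cr^2)) / pmax(speed, v_eps)^3)

  interior <- rep(TRUE, n)
  # the three frames at each end see one-sided first/second/third derivatives
  interior[c(1:3, (n - 2):n)] <- FALSE
  data.frame(t_s = traj$t_s, speed_mms = speed, accel_mms2 = accel,
             jerk_mms3 = jerk, curvature_per_mm = curv, interior = interior)
}

#' Straightness index
#'
#' Net start-to-end displacement divided by total path length: 1 for a
#' straight path, approaching 0 for convoluted paths.
#'
#' @param traj A `trajectory` with positive path length.
#' @return Scalar in [0, 1].
#' @export
straightness_index <- function(traj) {
  L <- path_length(traj)
  if (L <= 0) stop("zero path length")
  xyz <- traj_xyz(traj)
  net <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  min(net / L, 1)
}

#' Angular dispersion of step directions
#'
#' Mean resultant length R = |sum u_i| / n of the unit step-direction
#' vectors in 3D (zero-length steps skipped): 1 when all steps are aligned,
#' 0 for isotropic directions.
#'
#' @param traj A `trajectory` with >= 2 nonzero steps.
#' @return Scalar in [0, 1].
#' @export
angular_dispersion <- function(traj) {
  steps <- diff(traj_xyz(traj))
  len <- sqrt(rowSums(steps^2))
  keep <- len > 0
  if (!any(keep)) stop("all steps zero-length")
  u <- steps[keep, , drop = FALSE] / len[keep]
  min(sqrt(sum(colSums(u)^2)) / nrow(u), 1)
}

#' Summarize a trial into the eight movement metrics
#'
#' Per-frame features are aggregated by their median over interior frames
#' (boundary frames excluded, their one-sided stencils being noisier).
#'
#' @param traj A processed `trajectory`.
#' @param v_eps Curvature degeneracy threshold, mm/s.
#' @return A one-row data.frame of class `motion_features`:
#'   `completion_time_s`, `path_length_mm`, `straightness_index`,
#'   `angular_dispersion`, `median_speed_mms`, `median_accel_mms2`,
#'   `median_curvature_per_mm`, `median_jerk_mms3`.
#' @export
summarize_trial <- function(traj, v_eps = 1e-3) {
  k <- kinematics(traj, v_eps)
  ki <- k[k$interior, ]
  out <- data.frame(
    trial_id = attr(traj, "trial_id"),
    condition = attr(traj, "condition"),
    completion_time_s = completion_time(traj),
    path_length_mm = path_length(traj),
    straightness_index = straightness_index(traj),
    angular_dispersion = angular_dispersion(traj),
    median_speed_mms = stats::median(ki$speed_mms),
    median_accel_mms2 = stats::median(ki$accel_mms2),
    median_curvature_per_mm = stats::median(ki$curvature_per_mm),
    median_jerk_mms3 = stats::median(ki$jerk_mms3),
    stringsAsFactors = FALSE)
  class(out) <- c("motion_features", "data.frame")
  out
}

metric_columns <- function() {
  c("completion_time_s", "path_length_mm", "straightness_index",
    "angular_dispersion", "median_speed_mms", "median_accel_mms2",
    "median_curvature_per_mm", "median_jerk_mms3")
}

#' Paired comparison of two conditions
#'
#' Classical paired-samples t test (df = n - 1, two-sided) on the
#' per-subject differences of each metric, as used to compare the two probe
#' designs on the same operators. No multiple-testing correction is applied
#' across the eight metrics; p-values are reported raw. When the
#' differences have zero variance the t statistic is undefined: p is then
#' reported exactly (0 for a nonzero mean difference, 1 for zero) with a
#' warning.
#'
#' @param features_a,features_b data.frames of per-subject metric rows
#'   (same subject order, equal length, n >= 2) as from [summarize_trial()].
#' @return data.frame: metric, mean_diff, t, df, p.
#' @export
paired_comparison <- function(features_a, features_b) {
  cols <- intersect(metric_columns(), intersect(names(features_a),
                                                names(features_b)))
  n <- nrow(features_a)
  if (n != nrow(features_b)) stop("unequal paired sample sizes")
  if (n < 2) stop("need n >= 2 pairs")
  res <- lapply(cols, function(cl) {
    d <- features_a[[cl]] - features_b[[cl]]
    if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
      warning("zero variance of differences for ", cl,
              "; exact p reported")
      p <- if (abs(mean(d)) > 0) 0 else 1
      data.frame(metric = cl, mean_diff = mean(d),
                 t = if (abs(mean(d)) > 0) Inf * sign(mean(d)) else 0,
                 df = n - 1, p = p)
    } else {
      tt <- stats::t.test(features_a[[cl]], features_b[[cl]], paired = TRUE)
      data.frame(metric = cl, mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  do.call(rbind, res)
}

#' Write per-trial features as CSV
#'
#' One row per trial; metric units are carried in the column names.
#' @param features data.frame of stacked [summarize_trial()] rows.
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
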