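## Trial simulators: phantom pick/identify/collect trajectories and
## radioguided target-search trials with a Poisson counting probe.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

perp_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- unit3(pracma_cross(d, ref))
  n2 <- pracma_cross(d, n1)
  list(n1 = n1, n2 = n2)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Simulate one phantom trial trajectory
#'
#' Generates the instrument-tip path of the pick/identify/collect exercise:
#' the trajectory visits the script's anchors in order, with skill-dependent
#' imperfections on top of the straight transits — an AR(1)-correlated
#' Gaussian tremor perpendicular to the travel direction and a smooth
#' mid-segment detour, both scaled by (1 - skill). At `skill = 1` the path
#' is exactly the straight anchor-to-anchor polyline. `mode = "dropin"`
#' performs all ten movements; `mode = "clickon"` omits the probe-handling
#' movements (no probe pick-up at home, no return-and-drop, no separate
#' second transit to the target) because the detector rides the instrument.
#'
#' @param layout A `task_layout`.
#' @param mode "dropin" or "clickon".
#' @param skill Scalar in [0, 1]; 1 = perfect.
#' @param fps Sampling rate, Hz.
#' @param seed Integer seed (one generator per trial).
#' @param tremor_sd_mm Perpendicular tremor SD at skill 0, mm.
#' @param detour_mm Mid-segment detour amplitude at skill 0, mm.
#' @param trial_id Identifier.
#' @return List with `trajectory` (a `trajectory`, condition = mode) and
#'   `script` (a `trial_script`).
#' @export
simulate_phantom_trial <- function(layout = task_layout(),
                                   mode = c("dropin", "clickon"),
                                   skill = 0.7, fps = 25, seed = 1,
                                   tremor_sd_mm = 1.5, detour_mm = 15,
                                   trial_id = NULL) {
  mode <- match.arg(mode)
  if (skill < 0 || skill > 1) stop("skill must be in [0, 1]")
  stopifnot(fps > 0)
  set.seed(seed)
  # lower skill slows both transits and in-place handling
  script <- trial_script(mode, layout,
                         transit_speed_mms = 40 * (0.55 + 0.45 * skill),
                         dwell_s = 1.5 * (1.8 - 0.8 * skill))
  # snap segment boundaries onto the frame grid so every anchor is hit
  # exactly and the zero-noise path length equals the anchor polyline
  dur <- pmax(round(script$duration_s * fps), 1) / fps
  script$duration_s <- dur
  script$t_end_s <- cumsum(dur)
  script$t_start_s <- script$t_end_s - dur
  total_t <- script$t_end_s[nrow(script)]
  n <- round(total_t * fps) + 1  # durations are exact frame multiples
  t_s <- (seq_len(n) - 1) / fps

  sd_trem <- tremor_sd_mm * (1 - skill)
  amp_det <- detour_mm * (1 - skill)
  xyz <- matrix(0, n, 3)

  seg_of <- findInterval(t_s, script$t_start_s, rightmost.closed = TRUE)
  seg_of[seg_of < 1] <- 1
  for (s in seq_len(nrow(script))) {
    sel <- which(seg_of == s)
    if (length(sel) == 0) next
    u <- (t_s[sel] - script$t_start_s[s]) / script$duration_s[s]
    p0 <- as.numeric(script$start[s, ]); p1 <- as.numeric(script$end[s, ])
    base <- outer(rep(1, length(sel)), p0) + outer(u, p1 - p0)
    d <- p1 - p0
    moving <- sqrt(sum(d^2)) > 1e-9
    pb <- perp_basis(if (moving) unit3(d) else c(0, 0, 1))
    noise <- matrix(0, length(sel), 3)
    if (sd_trem > 0) {
      ar <- function(k) {
        phi <- 0.85
        e <- stats::rnorm(k, 0, sd_trem * sqrt(1 - phi^2))
        as.numeric(stats::filter(e, phi, method = "recursive"))
      }
      noise <- outer(ar(length(sel)), pb$n1) + outer(ar(length(sel)), pb$n2)
    }
    if (moving && amp_det > 0) {
      th <- stats::runif(1, 0, 2 * pi)
      dirv <- cos(th) * pb$n1 + sin(th) * pb$n2
      noise <- noise + outer(amp_det * sin(pi * u), dirv)
    }
    xyz[sel, ] <- base + noise
  }
  if (is.null(trial_id)) trial_id <- sprintf("phantom_%s_seed%d", mode, seed)
  traj <- trajectory(t_s, xyz, fps = fps, trial_id = trial_id,
                     condition = mode, seed = seed)
  list(trajectory = traj, script = script)
}

probe_rate_at <- function(pos, axis, source_pos, probe) {
  dvec <- as.numeric(source_pos) - pos
  d_true <- sqrt(sum(dvec^2))
  d <- max(d_true, 1)              # intensity floored at 1 mm
  cosang <- if (d_true < 1e-9) 1 else
    sum(axis * dvec) / (d_true * sqrt(sum(axis^2)))
  within <- cosang >= cos(probe$acceptance_half_angle_deg * pi / 180)
  probe$background_rate +
    probe$sensitivity * probe$source_activity * (10 / d)^2 * within
}

#' Simulate gamma-probe counts along a trajectory
#'
#' Expected rate at each sample:
#' `background + sensitivity * activity * (10 / d)^2 * angular_response`,
#' with d the tip-source distance in mm floored at 1 mm and angular
#' response 1 inside the collimation cone, 0 outside. Observed counts are
#' Poisson with mean rate * dt.
#'
#' @param tip_positions A `trajectory` or n x 3 matrix of tip positions, mm.
#' @param probe_axis n x 3 (or length-3) unit pointing vector(s) of the
#'   probe.
#' @param source_pos Length-3 source position, mm.
#' @param probe A `probe_model`.
#' @param dt Sampling interval, s (> 0).
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return data.frame with `rate_cps` (expected) and `counts` (Poisson).
#' @export
simulate_probe_counts <- function(tip_positions, probe_axis, source_pos,
                                  probe = probe_model(), dt = 0.04,
                                  seed = NULL) {
  stopifnot(dt > 0, inherits(probe, "probe_model"))
  pos <- if (inherits(tip_positions, "trajectory"))
    traj_xyz(tip_positions) else matrix(tip_positions, ncol = 3)
  n <- nrow(pos)
  ax <- matrix(probe_axis, ncol = 3)
  if (nrow(ax) == 1) ax <- ax[rep(1, n), , drop = FALSE]
  ax <- ax / sqrt(rowSums(ax^2))
  dvec <- sweep(-pos, 2, as.numeric(source_pos), `+`)  # source - tip
  d_true <- sqrt(rowSums(dvec^2))
  d <- pmax(d_true, 1)             # intensity floored at 1 mm
  cosang <- ifelse(d_true < 1e-9, 1, rowSums(ax * dvec) / pmax(d_true, 1e-9))
  within <- cosang >= cos(probe$acceptance_half_angle_deg * pi / 180)
  rate <- probe$background_rate +
    probe$sensitivity * probe$source_activity * (10 / d)^2 * within
  if (!is.null(seed)) set.seed(seed)
  data.frame(rate_cps = rate, counts = stats::rpois(n, rate * dt))
}

#' Simulate one target-search trial under the 40-second rule
#'
#' The operator inspects a sequence of positions at a small standoff below
#' the abdominal-wall plane of the workspace. Unguided (palpation) search
#' is a correlated random walk of inspection points: each step keeps the
#' previous heading with Gaussian turn noise, reflects at the workspace
#' bounds, and pauses for a palpation dwell at every inspection point.
#' Guided (radioguided) search is the same walk informed by the probe:
#' the 0.5-s moving-average count rate is tracked continuously (also
#' during transits, with window-centre attribution), the loudest reading
#' is inverted through the inverse-square law into a remaining-distance
#' estimate, and the next inspection point is drawn at that scale around
#' the loudest position (returning to it first when the walk has strayed).
#' When an inspection implies the source is within the detection radius
#' the operator declares the target identified and holds the probe still.
#' Success is declared when the tip stays within `detection_radius_mm` of
#' the source for `dwell_need_s` before `time_limit_s`; otherwise the
#' trial is a failure.
#'
#' @param guided TRUE for radioguided search, FALSE for palpation.
#' @param source_pos Length-3 source position, mm.
#' @param probe A `probe_model` (used only when guided).
#' @param policy Named list overriding policy parameters: `speed_mms` (35),
#'   `dwell_s` (1.2), `dwell_guided_s` (0.6; listening to the readout is
#'   faster than a palpation press), `step_mm` (c(25, 60) min/max),
#'   `turn_sd` (0.6 rad), `detection_radius_mm` (10), `dwell_need_s` (1),
#'   `window_s` (0.5), `confirm_s` (3; after identification the operator
#'   holds the probe on the target while declaring it — recorded in the
#'   trajectory, not in the detection time).
#' @param time_limit_s Failure cutoff, s (default 40).
#' @param fps Sampling rate, Hz.
#' @param seed Integer seed (one generator per trial).
#' @param workspace 2 x 3 bounds matrix, mm.
#' @param start_pos Length-3 start position; default workspace centre at
#'   the near face.
#' @param trial_id Identifier.
#' @return List with `trajectory` (condition "radioguided"/"palpation") and
#'   `outcome`: `trial_id`, `condition`, `success`,
#'   `time_to_detection_s` (<= time limit, NA on failure), `seed`.
#' @export
simulate_search_trial <- function(guided, source_pos = c(20, 10, 160),
                                  probe = probe_model(), policy = list(),
                                  time_limit_s = 40, fps = 25, seed = 1,
                                  workspace = rbind(c(-70, -50, 120),
                                                    c(70, 50, 165)),
                                  start_pos = NULL, trial_id = NULL) {
  stopifnot(time_limit_s >= 0, fps > 0)
  pol <- utils::modifyList(list(speed_mms = 35, dwell_s = 1.2,
                                dwell_guided_s = 0.6,
                                step_mm = c(25, 60), turn_sd = 0.6,
                                detection_radius_mm = 10, dwell_need_s = 1,
                                window_s = 0.5, confirm_s = 3), policy)
  insp_dwell <- if (guided) pol$dwell_guided_s else pol$dwell_s
  set.seed(seed)
  # the probe hovers with a small standoff below the abdominal-wall plane,
  # keeping an embedded source inside the forward acceptance hemisphere
  wall_z <- workspace[2, 3] - 11
  if (is.null(start_pos))
    start_pos <- c(mean(workspace[, 1]), mean(workspace[, 2]),
                   workspace[1, 3] + 5)
  condition <- if (guided) "radioguided" else "palpation"
  if (is.null(trial_id))
    trial_id <- sprintf("search_%s_seed%d", condition, seed)

  n_max <- floor(time_limit_s * fps)
  dt <- 1 / fps
  empty_outcome <- list(trial_id = trial_id, condition = condition,
                        success = FALSE, time_to_detection_s = NA_real_,
                        seed = seed)
  if (n_max < 1) {
    traj <- trajectory(0, matrix(start_pos, 1), fps = fps,
                       trial_id = trial_id, condition = condition,
                       seed = seed)
    return(list(trajectory = traj, outcome = empty_outcome))
  }

  pos <- matrix(NA_real_, n_max, 3)
  counts <- numeric(n_max)
  rate_sm <- 0
  win_n <- max(1, round(pol$window_s * fps))
  heading <- stats::runif(1, 0, 2 * pi)

  cur <- start_pos
  # inspection bookkeeping (guided)
  prev_insp <- NULL; prev_rate <- NA
  best_pos <- NULL; best_rate <- -Inf
  bg <- probe$background_rate

  clamp_ws <- function(p) pmin(pmax(p, workspace[1, ] + 1),
                               workspace[2, ] - 1)

  i <- 0
  dwell_frames <- 0
  need_frames <- ceiling(pol$dwell_need_s * fps)
  succeeded <- FALSE; t_detect <- NA_real_

  # phase machine: dwell at current point, then transit to the next
  phase <- "dwell"; phase_left <- round(insp_dwell * fps)
  target <- cur
  dwell_rate_acc <- 0; dwell_rate_n <- 0

  while (i < n_max && !succeeded) {
    i <- i + 1
    if (phase == "transit") {
      step <- pol$speed_mms * dt
      delta <- target - cur
      dist <- sqrt(sum(delta^2))
      if (dist <= step) {
        cur <- target
        phase <- "dwell"; phase_left <- round(insp_dwell * fps)
        dwell_rate_acc <- 0; dwell_rate_n <- 0
      } else {
        cur <- cur + delta / dist * step
      }
    }
    pos[i, ] <- cur
    # probe readout (simulated even when unguided; unguided ignores it)
    counts[i] <- stats::rpois(1, probe_rate_at(cur, c(0, 0, 1), source_pos,
                                               probe) * dt)
    lo <- max(1, i - win_n + 1)
    rate_sm <- sum(counts[lo:i]) / ((i - lo + 1) * dt)

    # the surgeon hears the count rate continuously, also while moving:
    # track the loudest reading and where it was heard (window-centre
    # attribution corrects for motion smearing); a gentle decay lets the
    # search escape a single lucky Poisson fluctuation
    if (guided && i > win_n) {
      best_rate <- best_rate * (1 - 0.03 * dt)
      if (rate_sm > best_rate) {
        best_rate <- rate_sm
        best_pos <- pos[max(1, i - round(win_n / 2)), ]
      }
    }

    if (phase == "dwell") {
      dwell_rate_acc <- dwell_rate_acc + rate_sm; dwell_rate_n <- dwell_rate_n + 1
      phase_left <- phase_left - 1
      if (phase_left <= 0) {
        insp_rate <- dwell_rate_acc / max(1, dwell_rate_n)
        # identification hold: when the readout implies the source is at
        # hand (estimated distance within the detection radius), the
        # operator stops searching and holds the probe on the spot
        hold <- FALSE
        if (guided && insp_rate > bg + 3) {
          d_now <- 10 * sqrt(probe$sensitivity * probe$source_activity /
                               (insp_rate - bg))
          hold <- d_now <= 0.8 * pol$detection_radius_mm
        }
        if (hold) {
          phase_left <- round(insp_dwell * fps)
          dwell_rate_acc <- 0; dwell_rate_n <- 0
        } else {
        # choose next inspection point
        heading <- heading + stats::rnorm(1, 0, pol$turn_sd)
        dir2 <- c(cos(heading), sin(heading))
        if (guided && best_rate > bg + 3) {
          # trust-region ascent: invert the inverse-square law so the best
          # rate heard estimates the remaining distance; inspect a new
          # point at that scale around the loudest position, returning to
          # it first when the walk has strayed beyond the trust region
          d_hat <- 10 * sqrt(probe$sensitivity * probe$source_activity /
                               (best_rate - bg))
          L <- min(max(0.8 * d_hat, 3), pol$step_mm[2])
          stray <- sqrt(sum((cur[1:2] - best_pos[1:2])^2))
          nxt <- if (stray > max(1.5 * L, 12))
            best_pos else best_pos + c(L * dir2, 0)
        } else {
          L <- stats::runif(1, pol$step_mm[1], pol$step_mm[2])
          nxt <- cur + c(L * dir2, 0)
        }
        nxt[3] <- wall_z + stats::rnorm(1, 0, 2)
        # reflect at bounds
        for (ax in 1:2) {
          if (nxt[ax] < workspace[1, ax])
            nxt[ax] <- 2 * workspace[1, ax] - nxt[ax]
          if (nxt[ax] > workspace[2, ax])
            nxt[ax] <- 2 * workspace[2, ax] - nxt[ax]
        }
        nxt <- clamp_ws(nxt)
        heading <- atan2(nxt[2] - cur[2], nxt[1] - cur[1])
        prev_insp <- cur; prev_rate <- insp_rate
        target <- nxt
        phase <- "transit"
        }
      }
    }

    if (sqrt(sum((cur - source_pos)^2)) <= pol$detection_radius_mm) {
      dwell_frames <- dwell_frames + 1
      if (dwell_frames >= need_frames) {
        succeeded <- TRUE
        t_detect <- i * dt
      }
    } else dwell_frames <- 0
  }

  n <- i
  xyz <- pos[seq_len(n), , drop = FALSE]
  if (succeeded && pol$confirm_s > 0) {
    # identification confirmed: the probe is held on the target while the
    # find is declared; the detection clock has already stopped
    hold_n <- round(pol$confirm_s * fps)
    xyz <- rbind(xyz, matrix(rep(cur, hold_n), ncol = 3, byrow = TRUE))
    n <- n + hold_n
  }
  traj <- trajectory((seq_len(n) - 1) / fps, xyz,
                     fps = fps, trial_id = trial_id, condition = condition,
                     seed = seed)
  outcome <- list(trial_id = trial_id, condition = condition,
                  success = succeeded,
                  time_to_detection_s = if (succeeded)
                    min(t_detect, time_limit_s) else NA_real_,
                  seed = seed)
  list(trajectory = traj, outcome = outcome)
}
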