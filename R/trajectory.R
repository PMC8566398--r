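#' Instrument-tip trajectory
#'
#' The pipeline's central object: a uniformly sampled track of the
#' instrument tip in mm (track frame: image-plane x/y with centre origin,
#' y up, z = distance from camera). Implemented as a data.frame with
#' columns `frame`, `t_s`, `x_mm`, `y_mm`, `z_mm`, `valid`, `source` and
#' metadata attributes `fps`, `trial_id`, `condition`, `seed`.
#'
#' @param t_s Strictly increasing timestamps at constant step 1/fps.
#' @param xyz n x 3 matrix of positions (mm); NA where invalid.
#' @param valid Logical vector.
#' @param source Character vector: "measured", "interpolated" or "missing".
#' @param fps Sampling rate, Hz.
#' @param trial_id,condition,seed Metadata.
#' @return An object of classes `trajectory` and `data.frame`.
#' @export
trajectory <- function(t_s, xyz, valid = rep(TRUE, length(t_s)),
                       source = rep("measured", length(t_s)),
                       fps, trial_id = "trial", condition = NA_character_,
                       seed = NA_integer_) {
  xyz <- matrix(xyz, ncol = 3)
  n <- length(t_s)
  stopifnot(nrow(xyz) == n, length(valid) == n, length(source) == n, fps > 0)
  if (n > 1) {
    dt <- diff(t_s)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / fps)) > 1e-6 / fps)
      stop("timestamps must be uniform at 1/fps")
  }
  df <- data.frame(frame = seq_len(n), t_s = as.numeric(t_s),
                   x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
                   valid = as.logical(valid), source = as.character(source),
                   stringsAsFactors = FALSE)
  structure(df, fps = fps, trial_id = trial_id, condition = condition,
            seed = seed, class = c("trajectory", "data.frame"))
}

traj_xyz <- function(traj) as.matrix(traj[, c("x_mm", "y_mm", "z_mm")])

traj_meta <- function(traj)
  list(fps = attr(traj, "fps"), trial_id = attr(traj, "trial_id"),
       condition = attr(traj, "condition"), seed = attr(traj, "seed"))

rebuild_trajectory <- function(traj, xyz = traj_xyz(traj),
                               valid = traj$valid, source = traj$source) {
  m <- traj_meta(traj)
  out <- trajectory(traj$t_s, xyz, valid, source, fps = m$fps,
                    trial_id = m$trial_id, condition = m$condition,
                    seed = m$seed)
  out$frame <- traj$frame
  for (a in c("gaps", "processing_log"))
    attr(out, a) <- attr(traj, a)
  out
}

#' @export
print.trajectory <- function(x, ...) {
  m <- traj_meta(x)
  cat(sprintf("trajectory '%s': %d points @ %g fps (%.2f s), %d valid\n",
              m$trial_id, nrow(x), m$fps,
              if (nrow(x) > 1) x$t_s[nrow(x)] - x$t_s[1] else 0,
              sum(x$valid)))
  if (!is.na(m$condition)) cat("  condition:", m$condition, "\n")
  invisible(x)
}

#' Trajectory CSV I/O
#'
#' Columns: trial_id, frame, t_s, x_mm, y_mm, z_mm, valid, source.
#' Coordinates are in the track frame (image-plane axes, centre origin,
#' y up, z = distance from camera, mm); a comment header records this and
#' the metadata.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  m <- traj_meta(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gammadex trajectory: track frame = image-plane x/y, centre origin, y up, z = distance from camera, mm",
    sprintf("# fps=%g condition=%s seed=%s", m$fps,
            m$condition, m$seed)), con)
  df <- data.frame(trial_id = m$trial_id, traj, stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  meta_line <- grep("^# fps=", hdr, value = TRUE)
  fps <- 25; condition <- NA_character_; seed <- NA_integer_
  if (length(meta_line) == 1) {
    kv <- strsplit(sub("^# ", "", meta_line), " ")[[1]]
    get <- function(k) sub(paste0(k, "="), "", grep(paste0("^", k, "="),
                                                    kv, value = TRUE))
    fps <- as.numeric(get("fps"))
    condition <- get("condition"); if (condition == "NA") condition <- NA
    seed <- suppressWarnings(as.integer(get("seed")))
  }
  df <- utils::read.csv(path, comment.char = "#")
  trajectory(df$t_s, cbind(df$x_mm, df$y_mm, df$z_mm), df$valid, df$source,
             fps = fps, trial_id = df$trial_id[1], condition = condition,
             seed = seed)
}

## --- processing: gaps, interpolation, filtering ---------------------------

#' Annotate out-of-view gaps in a raw trajectory
#'
#' Finds maximal runs of invalid points (movements out of the detection
#' range of the laparoscope) and annotates them as interior gaps or, when
#' they touch the first or last frame, as untrackable leading/trailing
#' gaps, which cannot be interpolated.
#'
#' @param traj A raw `trajectory`.
#' @return The trajectory with a `gaps` attribute: data.frame with columns
#'   `start`, `end`, `length`, `boundary`.
#' @export
flag_out_of_view <- function(traj) {
  if (nrow(traj) == 0) stop("empty trajectory")
  if (!any(traj$valid)) stop("no measured points")
  r <- rle(!traj$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gi <- which(r$values)
  gaps <- data.frame(start = starts[gi], end = ends[gi],
                     length = r$lengths[gi])
  gaps$boundary <- gaps$start == 1 | gaps$end == nrow(traj)
  attr(traj, "gaps") <- gaps
  traj
}

#' Fill interior gaps by linear interpolation
#'
#' Interior gaps no longer than `max_gap_s` are filled per axis by linear
#' interpolation between the flanking measured points and marked
#' `source = "interpolated"`. Leading/trailing gaps are trimmed. Longer
#' interior gaps split the trajectory into sub-tracks.
#'
#' @param traj A `trajectory` with gaps annotated (see [flag_out_of_view()];
#'   called automatically if missing).
#' @param max_gap_s Longest interpolatable gap, seconds.
#' @return A single processed `trajectory`, or a list of sub-track
#'   trajectories when an oversized gap forces a split. The processing log
#'   (attribute `processing_log`) records gaps filled, trimmed and split.
#' @export
interpolate_gaps <- function(traj, max_gap_s = 1.0) {
  if (is.null(attr(traj, "gaps"))) traj <- flag_out_of_view(traj)
  gaps <- attr(traj, "gaps")
  fps <- attr(traj, "fps")
  n <- nrow(traj)
  log <- list(max_gap_s = max_gap_s, filled = 0L, trimmed = 0L, splits = 0L)

  # trim leading/trailing gaps
  keep <- range(which(traj$valid))
  log$trimmed <- n - (keep[2] - keep[1] + 1)
  idx <- keep[1]:keep[2]

  xyz <- traj_xyz(traj)[idx, , drop = FALSE]
  valid <- traj$valid[idx]
  source <- traj$source[idx]
  t_s <- traj$t_s[idx]

  r <- rle(!valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  gi <- which(r$values)
  split_after <- integer(0)
  for (g in gi) {
    len_s <- r$lengths[g] / fps
    a <- starts[g] - 1; b <- ends[g] + 1
    if (len_s <= max_gap_s) {
      w <- (seq(starts[g], ends[g]) - a) / (b - a)
      for (ax in 1:3)
        xyz[starts[g]:ends[g], ax] <- xyz[a, ax] + w * (xyz[b, ax] - xyz[a, ax])
      valid[starts[g]:ends[g]] <- TRUE
      source[starts[g]:ends[g]] <- "interpolated"
      log$filled <- log$filled + 1L
    } else {
      split_after <- c(split_after, g)
    }
  }

  m <- traj_meta(traj)
  mk <- function(sel, k) {
    tr <- trajectory(t_s[sel], xyz[sel, , drop = FALSE], valid[sel],
                     source[sel], fps = m$fps,
                     trial_id = if (k == 0) m$trial_id else
                       paste0(m$trial_id, "_part", k),
                     condition = m$condition, seed = m$seed)
    attr(tr, "processing_log") <- log
    tr
  }
  if (length(split_after) == 0) return(mk(seq_along(t_s), 0))

  log$splits <- length(split_after)
  rv <- rle(valid)
  vend <- cumsum(rv$lengths); vstart <- vend - rv$lengths + 1
  runs <- which(rv$values)
  subs <- list()
  for (g in runs) {
    sel <- vstart[g]:vend[g]
    if (length(sel) >= 2) subs[[length(subs) + 1]] <- mk(sel, length(subs) + 1)
  }
  subs
}

#' Median-filter a trajectory
#'
#' Per-axis running median with an odd window, shrinking symmetrically at
#' the edges; timestamps are untouched. Removes isolated tracking spikes
#' while leaving monotone segments intact.
#'
#' @param traj A processed `trajectory` (every point valid).
#' @param window_frames Odd window length >= 3.
#' @return The filtered `trajectory`.
#' @export
median_filter_track <- function(traj, window_frames = 5) {
  if (window_frames %% 2 == 0 || window_frames < 3)
    stop("window must be odd and >= 3")
  xyz <- traj_xyz(traj)
  n <- nrow(xyz)
  half <- (window_frames - 1) / 2
  out <- xyz
  for (i in seq_len(n)) {
    k <- min(half, i - 1, n - i)   # shrink symmetrically at edges
    sel <- (i - k):(i + k)
    for (ax in 1:3) out[i, ax] <- stats::median(xyz[sel, ax])
  }
  rebuild_trajectory(traj, xyz = out)
}

#' Standard preprocessing: flag, interpolate, filter
#'
#' Gap filling runs before median filtering. When an oversized gap splits
#' the track, the longest sub-track is kept and the choice logged.
#'
#' @param traj Raw `trajectory`.
#' @param max_gap_s Longest interpolatable gap, seconds.
#' @param window_frames Median filter window (odd).
#' @return A processed `trajectory` with a `processing_log` attribute.
#' @export
process_trajectory <- function(traj, max_gap_s = 1.0, window_frames = 5) {
  tr <- interpolate_gaps(flag_out_of_view(traj), max_gap_s)
  picked_longest <- FALSE
  if (is.list(tr) && !inherits(tr, "trajectory")) {
    lens <- vapply(tr, nrow, 0L)
    tr <- tr[[which.max(lens)]]
    picked_longest <- TRUE
  }
  out <- median_filter_track(tr, window_frames)
  log <- attr(tr, "processing_log")
  log$window_frames <- window_frames
  log$picked_longest_subtrack <- picked_longest
  attr(out, "processing_log") <- log
  out
}

#' Write the processing log as JSON
#' @param traj A processed `trajectory`.
#' @param path File path.
#' @export
write_processing_log <- function(traj, path) {
  log <- attr(traj, "processing_log")
  if (is.null(log)) log <- list()
  log$trial_id <- attr(traj, "trial_id")
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
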