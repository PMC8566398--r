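## Monocular tip pose estimation from marker detections.

sph_dir <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

#' Convert camera-frame points to the track output frame
#'
#' The tracking output uses image-plane axes with the origin on the optical
#' axis and y pointing up, z the distance from the camera; the internal
#' camera frame has y pointing down. Applied once, at output.
#'
#' @param p n x 3 matrix or length-3 vector, camera frame (mm).
#' @return Same shape, track frame (mm).
#' @export
camera_to_track_frame <- function(p) {
  m <- matrix(p, ncol = 3)
  out <- cbind(m[, 1], -m[, 2], m[, 3])
  if (is.null(dim(p))) as.numeric(out) else out
}

# Mirror the plane normal of a planar pose about the line of sight: the
# classic two-fold tilt ambiguity of planar targets. Used as a second
# initialization so Levenberg-Marquardt visits both basins.
flip_planar_pose <- function(R, t) {
  v <- t / sqrt(sum(t^2))
  n <- R[, 3]
  n2 <- 2 * sum(n * v) * v - n
  ax <- pracma_cross(n, n2)
  s <- sqrt(sum(ax^2))
  if (s < 1e-9) return(NULL)
  ang <- atan2(s, sum(n * n2))
  M <- rodrigues_to_matrix(ax / s * ang)
  list(R = M %*% R, t = t)
}

# Fit a rectangle marker pose from 4 measured corners. Both the 180-degree
# correspondence ambiguity and the planar tilt ambiguity are kept as
# explicit candidates, sorted by residual.
fit_rectangle_pose <- function(corners_px, camera, spec) {
  g <- marker_geometry(spec)
  model <- g$corners[, 1:2]
  meas <- order_corners(corners_px)

  # normalized undistorted coordinates of the measured corners
  norm_meas <- {
    xy <- cbind((meas[, 1] - camera$cx) / camera$fx,
                (meas[, 2] - camera$cy) / camera$fy)
    undistort_normalized(camera, xy)
  }
  assignments <- c(lapply(0:3, function(s) ((0:3 + s) %% 4) + 1),
                   lapply(0:3, function(s) ((3:0 + s) %% 4) + 1))
  scored <- lapply(assignments, function(idx) {
    H <- homography_dlt(model, norm_meas[idx, ])
    r1 <- H[, 1]; r2 <- H[, 2]
    n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2))
    s <- abs(n1 - n2) / (n1 + n2) + abs(sum(r1 * r2)) / (n1 * n2)
    list(idx = idx, H = H, score = s)
  })
  scored <- scored[order(vapply(scored, `[[`, 0, "score"))]
  # every assignment whose homography is metrically plausible is refined:
  # the correct correspondence, its 180-degree twin and the two mirrored
  # windings all tie near score 0, and only downstream consistency can
  # tell their poses apart
  plaus <- scored[vapply(scored, `[[`, 0, "score") <
                    vapply(scored, `[[`, 0, "score")[1] + 0.2]
  cands <- list()
  for (sc in plaus) {
    pose0 <- homography_to_pose(sc$H)
    target <- as.numeric(meas[sc$idx, ])
    fn <- function(par) {
      R <- rodrigues_to_matrix(par[1:3])
      pc <- sweep(g$corners %*% t(R), 2, par[4:6], `+`)
      if (any(pc[, 3] <= 0)) return(rep(1e3, 8))
      as.numeric(project_points(camera, pc)) - target
    }
    inits <- list(list(R = pose0$R, t = pose0$t))
    fl <- flip_planar_pose(pose0$R, pose0$t)
    if (!is.null(fl)) inits <- c(inits, list(fl))
    for (ini in inits) {
      par0 <- c(matrix_to_rodrigues(ini$R), ini$t)
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = par0, fn = fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 100, ftol = 1e-14, ptol = 1e-14)))
      R <- rodrigues_to_matrix(fit$par[1:3]); t <- fit$par[4:6]
      tip <- as.numeric(R %*% spec$tip_offset_mm) + t
      cands[[length(cands) + 1]] <-
        list(tip_cam = tip, residual_px = sqrt(mean(fn(fit$par)^2)),
             xdir_u = R[1, 1], kind = "rectangle", R = R, t = t)
    }
  }
  # dedupe converged duplicates, keep the lower residual
  keep <- list()
  for (cc in cands[order(vapply(cands, `[[`, 0, "residual_px"))]) {
    dup <- any(vapply(keep, function(k)
      sqrt(sum((k$tip_cam - cc$tip_cam)^2)) < 0.5, TRUE))
    if (!dup) keep[[length(keep) + 1]] <- cc
  }
  keep
}

# Fit the ring-triplet axis (3D line through the equally spaced ring
# centres) from measured centroids; tip = first centre + axial offset.
#
# Solved globally by a 1-D scan over the first centre's depth: given
# lambda1, the second centre's depth follows from |P2 - P1| = spacing
# (quadratic, two branches), the third centre is determined by the equal
# spacing (P3 = 2 P2 - P1), and the misfit is P3's reprojection distance
# from the third measured centre. Local minima are polished by
# Levenberg-Marquardt on the full 5-parameter line. The reversed centre
# order gives the direction-ambiguous twin. Candidates sorted by residual.
fit_ring_pose <- function(centers_px, camera, spec,
                          depth_range_mm = c(30, 500)) {
  s <- spec$dimensions$spacing_mm
  a <- spec$tip_offset_mm[1]
  cands <- list()
  for (o in list(1:3, 3:1)) {
    cp <- centers_px[o, , drop = FALSE]
    rays <- back_project_ray(camera, cp)
    target <- as.numeric(cp)

    branch_P <- function(lam1, sign) {
      P1 <- rays[1, ] * lam1
      b <- sum(rays[2, ] * P1)
      disc <- b^2 - sum(P1^2) + s^2
      if (disc < 0) return(NULL)
      lam2 <- b + sign * sqrt(disc)
      if (lam2 <= 0) return(NULL)
      P2 <- rays[2, ] * lam2
      P3 <- 2 * P2 - P1
      if (P3[3] <= 0) return(NULL)
      rbind(P1, P2, P3)
    }
    mis <- function(lam1, sign) {
      P <- branch_P(lam1, sign)
      if (is.null(P)) return(NA_real_)
      sqrt(sum((project_points(camera, P[3, , drop = FALSE]) - cp[3, ])^2))
    }
    lam_grid <- seq(depth_range_mm[1], depth_range_mm[2], by = 1)
    for (sgn in c(-1, 1)) {
      e <- vapply(lam_grid, mis, 0, sign = sgn)
      ok <- which(is.finite(e))
      if (length(ok) < 3) next
      # local minima of the scan
      locmin <- ok[which(diff(sign(diff(e[ok]))) > 0) + 1]
      if (length(locmin) == 0) locmin <- ok[which.min(e[ok])]
      for (im in locmin) {
        if (!is.finite(e[im]) || e[im] > 20) next
        lo <- lam_grid[max(1, im - 1)]; hi <- lam_grid[min(length(lam_grid),
                                                           im + 1)]
        opt <- stats::optimize(function(l) {
          v <- mis(l, sgn); if (is.na(v)) 1e6 else v
        }, c(lo, hi))
        P <- branch_P(opt$minimum, sgn)
        if (is.null(P)) next
        d0 <- (P[3, ] - P[1, ]) / sqrt(sum((P[3, ] - P[1, ])^2))
        par0 <- c(P[1, ], acos(max(-1, min(1, d0[3]))), atan2(d0[2], d0[1]))
        fn <- function(par) {
          d <- sph_dir(par[4], par[5])
          Pm <- rbind(par[1:3], par[1:3] + s * d, par[1:3] + 2 * s * d)
          if (any(Pm[, 3] <= 0)) return(rep(1e3, 6))
          as.numeric(project_points(camera, Pm)) - target
        }
        fit <- suppressWarnings(minpack.lm::nls.lm(
          par = par0, fn = fn,
          control = minpack.lm::nls.lm.control(
            maxiter = 100, ftol = 1e-14, ptol = 1e-14)))
        d <- sph_dir(fit$par[4], fit$par[5])
        cands[[length(cands) + 1]] <-
          list(tip_cam = fit$par[1:3] + a * d,
               residual_px = sqrt(mean(fn(fit$par)^2)),
               xdir_u = d[1], kind = "ring_triplet")
      }
    }
  }
  keep <- list()
  for (cc in cands[order(vapply(cands, `[[`, 0, "residual_px"))]) {
    dup <- any(vapply(keep, function(k)
      sqrt(sum((k$tip_cam - cc$tip_cam)^2)) < 0.5, TRUE))
    if (!dup) keep[[length(keep) + 1]] <- cc
  }
  keep
}

invalid_track_point <- function(t_s = NA_real_, frame_index = NA_integer_) {
  structure(list(t_s = t_s, frame_index = frame_index,
                 position = c(NA_real_, NA_real_, NA_real_),
                 position_cam = c(NA_real_, NA_real_, NA_real_),
                 valid = FALSE, source = "none",
                 quality = 0, residual_px = NA_real_,
                 marker_id = NA_character_),
            class = "track_point")
}

#' Estimate the 3D instrument-tip position from marker detections
#'
#' Solves each detected marker's pose from its 2D-3D correspondences (4
#' rectangle corners; 3 collinear ring centres plus the known spacing for
#' depth), applies the tip offset, and reports the tip in the track output
#' frame (image-plane axes, centre origin, y up, z = distance from camera,
#' mm). Both marker types carry a two-fold pose ambiguity from their
#' symmetry; it is resolved by mutual consistency when both markers are
#' detected, by proximity to `hint_tip_cam` (e.g. the previous frame's tip)
#' otherwise. A lone ring triplet with no hint is unresolvable and yields an
#' invalid point rather than a guess. When both markers resolve, the one
#' with the lower reprojection residual wins.
#'
#' @param detections List of `marker_detection` (from [classify_marker()]).
#' @param camera A `camera_model`.
#' @param specs List of `marker_spec`.
#' @param hint_tip_cam Optional camera-frame tip position (mm) used as an
#'   ambiguity prior.
#' @param t_s,frame_index Timestamp (s) and frame index recorded on the
#'   output.
#' @return A `track_point`: `position` (track frame), `position_cam`,
#'   `valid`, `source`, `quality`, `residual_px`, `marker_id`.
#' @export
estimate_tip_position <- function(detections, camera, specs,
                                  hint_tip_cam = NULL,
                                  t_s = NA_real_, frame_index = NA_integer_) {
  if (length(detections) == 0) return(invalid_track_point(t_s, frame_index))
  spec_by_id <- stats::setNames(specs, vapply(specs, `[[`, "", "marker_id"))

  per_marker <- list()
  for (det in detections) {
    spec <- spec_by_id[[det$marker_id]]
    if (is.null(spec)) next
    cands <- tryCatch({
      if (det$kind == "rectangle")
        fit_rectangle_pose(det$primitives, camera, spec)
      else fit_ring_pose(det$primitives, camera, spec)
    }, error = function(e) NULL)
    if (is.null(cands) || length(cands) == 0) next
    # a candidate whose own reprojection residual is far above the
    # marker's best fit is refuted; drop it before any pairing
    rs <- vapply(cands, `[[`, 0, "residual_px")
    cands <- cands[rs <= max(3 * min(rs), 0.1)]
    per_marker[[length(per_marker) + 1]] <-
      list(det = det, cands = cands)
  }
  if (length(per_marker) == 0) return(invalid_track_point(t_s, frame_index))

  pick <- NULL
  kinds <- vapply(per_marker, function(m) m$det$kind, "")
  if (length(unique(kinds)) >= 2) {
    # cross-marker consistency: a rectangle pose candidate determines the
    # full instrument frame, hence predicts where the ring centres must
    # appear; the 180-degree twin misplaces them by the tip-offset scale
    # (hundreds of px), so the measured ring centroids resolve the
    # ambiguity decisively
    i <- which(kinds == "rectangle")[1]
    j <- which(kinds == "ring_triplet")[1]
    rect_spec <- spec_by_id[[per_marker[[i]]$det$marker_id]]
    ring_spec <- spec_by_id[[per_marker[[j]]$det$marker_id]]
    meas_centers <- per_marker[[j]]$det$primitives
    Lr <- marker_local_pose(rect_spec)
    Lg <- marker_local_pose(ring_spec)
    gloc <- marker_geometry(ring_spec)$centers
    consist <- vapply(per_marker[[i]]$cands, function(cc) {
      R_instr <- cc$R %*% t(Lr$R)
      t_instr <- cc$t - as.numeric(R_instr %*% Lr$t)
      Rg <- R_instr %*% Lg$R
      tg <- as.numeric(R_instr %*% Lg$t) + t_instr
      pc <- sweep(gloc %*% t(Rg), 2, tg, `+`)
      if (any(pc[, 3] <= 0)) return(Inf)
      pred <- project_points(camera, pc)
      min(mean(sqrt(rowSums((pred - meas_centers)^2))),
          mean(sqrt(rowSums((pred - meas_centers[3:1, ])^2))))
    }, 0)
    rect_pick <- per_marker[[i]]$cands[[which.min(consist)]]
    ring_cands <- per_marker[[j]]$cands
    dtips <- vapply(ring_cands, function(cc)
      sqrt(sum((cc$tip_cam - rect_pick$tip_cam)^2)), 0)
    ring_pick <- ring_cands[[which.min(dtips)]]
    # winner by reprojection residual, floored at the expected sub-pixel
    # measurement noise so a near-exactly-determined fit (3 ring centres,
    # 5 line parameters) cannot win on an artificially tiny residual;
    # a ring twin inconsistent with the rectangle falls back to it
    floor_px <- 0.05
    best <- list(rect_pick, ring_pick)
    resid <- pmax(vapply(best, `[[`, 0, "residual_px"), floor_px)
    if (min(dtips) > 25) resid[2] <- Inf
    ord <- order(resid, c(1, 2))
    pick <- best[[ord[1]]]
    qual <- max(vapply(per_marker, function(m) m$det$quality, 0))
    mid <- per_marker[[if (pick$kind == "rectangle") i else j]]$det$marker_id
  } else if (!is.null(hint_tip_cam)) {
    all_c <- do.call(c, lapply(per_marker, `[[`, "cands"))
    dists <- vapply(all_c, function(cc)
      sqrt(sum((cc$tip_cam - hint_tip_cam)^2)), 0)
    pick <- all_c[[which.min(dists)]]
    src <- which(vapply(seq_along(per_marker), function(k)
      any(vapply(per_marker[[k]]$cands, identical, TRUE, pick)), TRUE))[1]
    qual <- per_marker[[src]]$det$quality
    mid <- per_marker[[src]]$det$marker_id
  } else if (kinds[1] == "rectangle") {
    # no prior: documented convention, marker +x axis points image-right
    cands <- per_marker[[1]]$cands
    us <- vapply(cands, `[[`, 0, "xdir_u")
    pick <- cands[[which.max(us)]]
    qual <- per_marker[[1]]$det$quality
    mid <- per_marker[[1]]$det$marker_id
  } else {
    # lone ring triplet without prior: ambiguous by construction
    return(invalid_track_point(t_s, frame_index))
  }
  if (!is.finite(pick$tip_cam[3]) || pick$tip_cam[3] <= 0)
    return(invalid_track_point(t_s, frame_index))
  structure(list(t_s = t_s, frame_index = frame_index,
                 position = camera_to_track_frame(pick$tip_cam),
                 position_cam = pick$tip_cam,
                 valid = TRUE, source = "measured",
                 quality = qual, residual_px = pick$residual_px,
                 marker_id = mid),
            class = "track_point")
}

#' Track the instrument tip through an image sequence
#'
#' Runs segmentation, classification and tip estimation on every frame and
#' assembles a raw trajectory: one point per frame, invalid where no marker
#' resolves. The previous valid tip serves as the ambiguity prior, which
#' also gives the smooth hand-off between the rectangle and ring markers
#' when the instrument rolls: each frame simply takes whichever marker fits
#' with the lower reprojection residual. Unreadable frames yield an invalid
#' point with a warning, never an abort.
#'
#' @param frames List of h x w x 3 arrays, or a directory of PNG frames.
#' @param camera A `camera_model`.
#' @param specs List of `marker_spec`.
#' @param fps Frame rate, Hz.
#' @param min_area Minimum segment area in pixels.
#' @param trial_id Identifier stored in the trajectory metadata.
#' @return A raw `trajectory` (see [trajectory()]).
#' @export
track_sequence <- function(frames, camera, specs, fps = 25, min_area = 30,
                           trial_id = "track") {
  if (is.character(frames)) frames <- read_frames_png(frames)
  n <- length(frames)
  pts <- vector("list", n)
  hint <- NULL
  for (i in seq_len(n)) {
    tp <- tryCatch({
      seg <- segment_markers(frames[[i]], specs, min_area = min_area)
      dets <- classify_marker(seg, specs, frame_index = i)
      estimate_tip_position(dets, camera, specs, hint_tip_cam = hint,
                            t_s = (i - 1) / fps, frame_index = i)
    }, error = function(e) {
      warning("frame ", i, ": ", conditionMessage(e))
      invalid_track_point((i - 1) / fps, i)
    })
    if (tp$valid) hint <- tp$position_cam
    pts[[i]] <- tp
  }
  trajectory(
    t_s = vapply(pts, `[[`, 0, "t_s"),
    xyz = do.call(rbind, lapply(pts, `[[`, "position")),
    valid = vapply(pts, `[[`, TRUE, "valid"),
    source = ifelse(vapply(pts, `[[`, TRUE, "valid"),
                    "measured", "missing"),
    fps = fps, trial_id = trial_id)
}

#' Per-axis tracking accuracy against ground truth
#'
#' Mean and standard deviation of the absolute per-axis deviations between
#' paired ground-truth and tracked positions, the standard reporting format
#' for phantom accuracy protocols.
#'
#' @param truth,estimate n x 3 matrices of paired positions (mm), n >= 2.
#' @return data.frame with rows x, y, z and columns `mean_abs_mm`, `sd_abs_mm`.
#' @export
assess_tracking_accuracy <- function(truth, estimate) {
  truth <- matrix(truth, ncol = 3); estimate <- matrix(estimate, ncol = 3)
  if (nrow(truth) != nrow(estimate)) stop("unpaired truth/estimate lengths")
  if (nrow(truth) < 2) stop("need >= 2 pairs per axis")
  err <- abs(estimate - truth)
  data.frame(axis = c("x", "y", "z"),
             mean_abs_mm = colMeans(err),
             sd_abs_mm = apply(err, 2, stats::sd))
}
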