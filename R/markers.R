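#' Fiducial marker specification
#'
#' Describes one of the two marker types carried by the instrument: a cyan
#' rectangle mounted on the instrument shaft, or a triplet of equally spaced
#' yellow rings around the probe housing whose projected spacing encodes
#' depth. Geometry is expressed in a common instrument frame: the rectangle
#' lies in the plane z = 0 centred at `offset_mm`; the ring triplet is laid
#' out along the +x axis starting at `offset_mm`.
#'
#' @param marker_id Label, e.g. "shaft_rect".
#' @param kind "rectangle" or "ring_triplet".
#' @param color_profile List with `hue`, `saturation`, `value` ranges, each a
#'   length-2 vector on the 0-1 scale.
#' @param dimensions For a rectangle: list(width_mm, height_mm). For a ring
#'   triplet: list(spacing_mm, ring_width_mm, ring_radius_mm) — spacing is the
#'   centre-to-centre distance of adjacent rings.
#' @param tip_offset_mm Rigid offset (length 3, mm) from the marker frame
#'   origin to the instrument tip. For ring triplets only an axial offset
#'   (y = z = 0) can be resolved from a single view; non-axial components
#'   make the 3-point pose ambiguous and are rejected.
#' @param offset_mm Position of the marker's local origin in the shared
#'   instrument frame (length 3, mm). Default origin.
#' @param orientation 3x3 rotation mapping the marker-local frame (marker
#'   face in the local z = 0 plane) into the instrument frame. Defaults to
#'   identity; mounting the two markers on different faces of the shaft
#'   (e.g. rings rotated 90 degrees about x) is what makes one of them
#'   visible at any roll angle.
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(marker_id, kind, color_profile, dimensions,
                        tip_offset_mm, offset_mm = c(0, 0, 0),
                        orientation = diag(3)) {
  orientation <- as.matrix(orientation)
  if (any(dim(orientation) != c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      abs(det(orientation) - 1) > 1e-6)
    stop("orientation must be a rotation matrix")
  kind <- match.arg(kind, c("rectangle", "ring_triplet"))
  stopifnot(length(tip_offset_mm) == 3, length(offset_mm) == 3)
  for (ch in c("hue", "saturation", "value")) {
    r <- color_profile[[ch]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop("color_profile$", ch, " must be an increasing range in [0, 1]")
  }
  if (kind == "rectangle") {
    if (is.null(dimensions$width_mm) || is.null(dimensions$height_mm) ||
        dimensions$width_mm <= 0 || dimensions$height_mm <= 0)
      stop("rectangle needs positive width_mm and height_mm")
  } else {
    if (is.null(dimensions$spacing_mm) || dimensions$spacing_mm <= 0 ||
        is.null(dimensions$ring_width_mm) || dimensions$ring_width_mm <= 0 ||
        is.null(dimensions$ring_radius_mm) || dimensions$ring_radius_mm <= 0)
      stop("ring_triplet needs positive spacing_mm, ring_width_mm, ring_radius_mm")
    if (any(abs(tip_offset_mm[2:3]) > 1e-9))
      stop("ring_triplet tip_offset_mm must be axial (y = z = 0)")
  }
  structure(list(marker_id = marker_id, kind = kind,
                 color_profile = color_profile,
                 dimensions = dimensions,
                 tip_offset_mm = as.numeric(tip_offset_mm),
                 offset_mm = as.numeric(offset_mm),
                 orientation = orientation),
            class = "marker_spec")
}

#' Default instrument marker set
#'
#' A cyan 20 x 10 mm rectangle on the shaft and a yellow three-ring pattern
#' (8 mm ring spacing, 3 mm ring width, 4 mm ring radius) further down the
#' housing. Physical marker dimensions on a real instrument vary; these
#' defaults are working values for the synthetic pipeline and must be
#' adjusted to the instrument at hand. The two hue ranges do not overlap
#' (cyan 0.45-0.55, yellow 0.12-0.20).
#'
#' @return List of two `marker_spec` objects.
#' @export
default_marker_specs <- function() {
  list(
    marker_spec("shaft_rect", "rectangle",
                color_profile = list(hue = c(0.45, 0.55),
                                     saturation = c(0.5, 1),
                                     value = c(0.3, 1)),
                dimensions = list(width_mm = 20, height_mm = 10),
                tip_offset_mm = c(35, 0, 0),
                offset_mm = c(0, 0, 0)),
    marker_spec("housing_rings", "ring_triplet",
                color_profile = list(hue = c(0.12, 0.20),
                                     saturation = c(0.5, 1),
                                     value = c(0.3, 1)),
                dimensions = list(spacing_mm = 8, ring_width_mm = 1.6,
                                  ring_radius_mm = 2),
                tip_offset_mm = c(80, 0, 0),
                offset_mm = c(-45, 0, 0),
                orientation = matrix(c(1, 0, 0,
                                       0, 0, -1,
                                       0, 1, 0), 3, 3, byrow = TRUE))
  )
}

check_marker_specs <- function(specs) {
  if (length(specs) == 0) stop("empty marker list")
  hues <- lapply(specs, function(s) s$color_profile$hue)
  if (length(specs) > 1) {
    for (i in seq_along(specs)[-1]) for (j in seq_len(i - 1)) {
      a <- hues[[i]]; b <- hues[[j]]
      if (a[1] < b[2] && b[1] < a[2])
        stop("marker color profiles overlap in hue: ",
             specs[[i]]$marker_id, " / ", specs[[j]]$marker_id)
    }
  }
  invisible(specs)
}

# Geometry of a marker in its local frame (marker face in the plane z = 0).
marker_geometry <- function(spec) {
  if (spec$kind == "rectangle") {
    w <- spec$dimensions$width_mm / 2
    h <- spec$dimensions$height_mm / 2
    list(corners = cbind(c(-w, w, w, -w), c(-h, -h, h, h), 0))
  } else {
    s <- spec$dimensions$spacing_mm
    list(centers = cbind(c(0, s, 2 * s), 0, 0),
         ring_radius = spec$dimensions$ring_radius_mm,
         ring_width = spec$dimensions$ring_width_mm)
  }
}

# Rigid transform marker-local -> instrument frame.
marker_local_pose <- function(spec) pose3d(spec$orientation, spec$offset_mm)

# tip position in the instrument frame
marker_tip_instrument <- function(spec)
  spec$offset_mm + as.numeric(spec$orientation %*% spec$tip_offset_mm)

#' Marker specs YAML I/O
#'
#' @param specs List of `marker_spec`.
#' @param path File path.
#' @export
write_marker_yaml <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(s) {
    s <- unclass(s)
    s$orientation <- as.numeric(s$orientation)  # column-major 9-vector
    s
  }), path)
  invisible(path)
}

#' @rdname write_marker_yaml
#' @export
read_marker_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s)
    marker_spec(s$marker_id, s$kind,
                lapply(s$color_profile, as.numeric),
                s$dimensions, as.numeric(s$tip_offset_mm),
                as.numeric(s$offset_mm),
                matrix(as.numeric(s$orientation), 3, 3)))
}

#' Phantom task layout
#'
#' Named anchor points of the pick/identify/collect exercise: the home
#' recess where the tethered probe is picked up and dropped, the radioactive
#' target, and the collection bucket, together with the workspace bounds.
#' All coordinates in mm (camera frame).
#'
#' @param home,target_source,collection_bucket Length-3 anchor points, mm.
#' @param workspace 2 x 3 matrix: rows are lower/upper bounds per axis, mm.
#' @return An object of class `task_layout`.
#' @export
task_layout <- function(home = c(-40, -20, 130),
                        target_source = c(40, 10, 160),
                        collection_bucket = c(-20, 30, 150),
                        workspace = rbind(c(-60, -40, 110),
                                          c(60, 40, 190))) {
  anchors <- list(home = as.numeric(home),
                  target_source = as.numeric(target_source),
                  collection_bucket = as.numeric(collection_bucket))
  stopifnot(all(vapply(anchors, length, 1L) == 3),
            all(dim(workspace) == c(2, 3)))
  for (nm in names(anchors)) {
    a <- anchors[[nm]]
    if (any(a < workspace[1, ]) || any(a > workspace[2, ]))
      stop("anchor ", nm, " outside workspace bounds")
  }
  d <- stats::dist(do.call(rbind, anchors))
  if (any(d < 1e-9)) stop("anchors must be pairwise distinct")
  structure(c(anchors, list(workspace = workspace)), class = "task_layout")
}

#' Gamma-probe counting model
#'
#' Idealized counting detector for simulation of the guidance signal:
#' expected rate = background + sensitivity * activity * (10 / d)^2 inside
#' the collimation cone (d = tip-source distance in mm, floored at 1 mm),
#' zero response outside; observed counts are Poisson.
#'
#' @param sensitivity Expected counts/s at 10 mm from a unit-activity
#'   source, on axis. Must be > 0. The default (1000 counts/s) matches a
#'   sub-MBq gamma source viewed by a collimated probe at close range:
#'   detector solid angle times emission rate times detection efficiency.
#' @param acceptance_half_angle_deg Collimation half angle, degrees
#'   (0, 90]. The default 90 models the weak collimation of tethered
#'   laparoscopic probes, which accept the full forward hemisphere.
#' @param background_rate Counts/s, >= 0.
#' @param source_activity Relative units, > 0.
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(sensitivity = 1000,
                        acceptance_half_angle_deg = 90,
                        background_rate = 5,
                        source_activity = 1) {
  stopifnot(sensitivity > 0,
            acceptance_half_angle_deg > 0, acceptance_half_angle_deg <= 90,
            background_rate >= 0, source_activity > 0)
  structure(list(sensitivity = sensitivity,
                 acceptance_half_angle_deg = acceptance_half_angle_deg,
                 background_rate = background_rate,
                 source_activity = source_activity),
            class = "probe_model")
}

## trial scripts ------------------------------------------------------------

# The ten movements of the phantom exercise, in order. Probe-handling
# movements (flagged) are the ones absorbed when the detector rides the
# instrument: probe pick-up at home, the return transit to home, the probe
# drop at home, and the separate second transit out to the target.
phantom_movements <- function() {
  data.frame(
    label = c("probe_pickup_home", "probe_to_target", "target_identification",
              "probe_back_home", "probe_drop_home", "instrument_to_target",
              "target_pickup", "target_to_bucket", "target_drop_bucket",
              "instrument_back_home"),
    from = c("home", "home", "target_source", "target_source", "home",
             "home", "target_source", "target_source", "collection_bucket",
             "collection_bucket"),
    to = c("home", "target_source", "target_source", "home", "home",
           "target_source", "target_source", "collection_bucket",
           "collection_bucket", "home"),
    probe_handling = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Movement script of a phantom trial
#'
#' Builds the ordered movement list for one trial. The integrated-probe
#' (`clickon`) script is the ten-movement tethered-probe (`dropin`) script
#' with the probe-handling movements removed: no probe pick-up at home, no
#' return-and-drop of the probe, and no separate second transit to the
#' target, because the detector travels on the instrument.
#'
#' @param mode "dropin" (all ten movements) or "clickon".
#' @param layout A `task_layout`.
#' @param transit_speed_mms Nominal straight-line transit speed, mm/s.
#' @param dwell_s Nominal duration of in-place movements (pick-up, identify,
#'   drop), seconds.
#' @return A `trial_script` data.frame: label, from, to, start/end anchors,
#'   nominal duration; segments temporally contiguous.
#' @export
trial_script <- function(mode = c("dropin", "clickon"), layout = task_layout(),
                         transit_speed_mms = 40, dwell_s = 1.5) {
  mode <- match.arg(mode)
  mv <- phantom_movements()
  if (mode == "clickon") mv <- mv[!mv$probe_handling, ]
  anchor <- function(nm) do.call(rbind, lapply(nm, function(n) layout[[n]]))
  p0 <- anchor(mv$from); p1 <- anchor(mv$to)
  seglen <- sqrt(rowSums((p1 - p0)^2))
  dur <- ifelse(seglen < 1e-9, dwell_s, seglen / transit_speed_mms)
  t1 <- cumsum(dur)
  out <- data.frame(label = mv$label, from = mv$from, to = mv$to,
                    t_start_s = c(0, t1[-length(t1)]), t_end_s = t1,
                    duration_s = dur, stringsAsFactors = FALSE)
  out$start <- p0; out$end <- p1
  attr(out, "mode") <- mode
  class(out) <- c("trial_script", "data.frame")
  out
}

#' Write / read a trial script as JSON
#' @param script A `trial_script`.
#' @param path File path.
#' @export
write_script_json <- function(script, path) {
  obj <- list(mode = attr(script, "mode"),
              segments = lapply(seq_len(nrow(script)), function(i)
                list(label = script$label[i], from = script$from[i],
                     to = script$to[i],
                     t_start_s = script$t_start_s[i],
                     t_end_s = script$t_end_s[i],
                     start_mm = as.numeric(script$start[i, ]),
                     end_mm = as.numeric(script$end[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
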