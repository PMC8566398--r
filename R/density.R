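## Occupancy density maps: percentage of trial time per 1-cm cell.

#' 3D occupancy map (%s/cm^3)
#'
#' Bins every trajectory sample (each contributing 1/fps seconds) into
#' half-open cubic cells `[lo, hi)` of edge `cell_mm` and converts cell
#' times to percentages of the total trial time. Samples falling outside
#' the grid are counted in an explicit out-of-grid bin (with a warning) so
#' the total is always 100%.
#'
#' @param traj A processed `trajectory`.
#' @param cell_mm Cell edge, mm; 10 mm cells give %s/cm^3.
#' @param origin Grid origin (length 3, mm). Default: the trajectory's
#'   bounding-box floor snapped down to a multiple of the cell edge.
#' @param dims Grid cell counts per axis (length 3). Default: cover the
#'   trajectory.
#' @return An `occupancy_map3d`: `percent` (3D array), `origin`, `cell_mm`,
#'   `total_time_s`, `out_of_grid_percent`.
#' @export
occupancy_3d <- function(traj, cell_mm = 10, origin = NULL, dims = NULL) {
  xyz <- traj_xyz(traj)
  n <- nrow(xyz)
  stopifnot(n >= 1, cell_mm > 0)
  if (is.null(origin))
    origin <- floor(apply(xyz, 2, min) / cell_mm) * cell_mm
  if (is.null(dims))
    dims <- pmax(1, ceiling((apply(xyz, 2, max) - origin) / cell_mm + 1e-9))
  dims <- as.integer(dims)

  idx <- sweep(xyz, 2, origin) / cell_mm
  ci <- floor(idx) + 1
  inb <- ci[, 1] >= 1 & ci[, 1] <= dims[1] &
    ci[, 2] >= 1 & ci[, 2] <= dims[2] &
    ci[, 3] >= 1 & ci[, 3] <= dims[3]
  if (any(!inb))
    warning(sum(!inb), " samples outside grid; counted in out-of-grid bin")

  arr <- array(0, dims)
  if (any(inb)) {
    lin <- (ci[inb, 3] - 1) * dims[1] * dims[2] +
      (ci[inb, 2] - 1) * dims[1] + ci[inb, 1]
    tb <- table(lin)
    arr[as.integer(names(tb))] <- as.integer(tb)
  }
  pct <- arr / n * 100
  structure(list(percent = pct, origin = origin, cell_mm = cell_mm,
                 total_time_s = n / attr(traj, "fps"),
                 out_of_grid_percent = sum(!inb) / n * 100),
            class = "occupancy_map3d")
}

#' 2D occupancy map (%s/cm^2): z-marginal of a 3D map
#'
#' @param map3d An `occupancy_map3d`.
#' @return An `occupancy_map2d` on the XY (image) plane: `percent` (matrix,
#'   x along rows, y along columns), `origin`, `cell_mm`,
#'   `out_of_grid_percent`.
#' @export
occupancy_2d <- function(map3d) {
  stopifnot(inherits(map3d, "occupancy_map3d"))
  pct <- apply(map3d$percent, c(1, 2), sum)
  structure(list(percent = pct, origin = map3d$origin[1:2],
                 cell_mm = map3d$cell_mm,
                 total_time_s = map3d$total_time_s,
                 out_of_grid_percent = map3d$out_of_grid_percent),
            class = "occupancy_map2d")
}

occupancy_total <- function(map)
  sum(map$percent) + map$out_of_grid_percent

#' Focus statistics of an occupancy map
#'
#' Scalar summaries of how concentrated the instrument's time was: the
#' maximum cell percentage and the Shannon entropy (bits) of the cell
#' distribution over nonzero cells. A confident, valid search shows a high
#' maximum at the target and low entropy.
#'
#' @param map An `occupancy_map3d` or `occupancy_map2d`.
#' @return List with `max_cell_percent` and `entropy_bits`.
#' @export
focus_statistics <- function(map) {
  p <- c(as.numeric(map$percent), map$out_of_grid_percent) / 100
  p <- p[p > 0]
  list(max_cell_percent = max(map$percent),
       entropy_bits = -sum(p * log2(p)))
}

#' Color overlay of a 2D occupancy map on a surgical-view image
#'
#' Maps cell percentages through a monotone blue-to-red ramp, normalized to
#' the per-trial maximum, and alpha-blends the result onto the background
#' image; cells at 0% stay fully transparent. Grid cells are projected at
#' the mean working depth to place them on the image plane.
#'
#' @param map2d An `occupancy_map2d` (track-frame coordinates, mm).
#' @param background h x w x 3 image array in [0, 1].
#' @param camera The `camera_model` that produced the trajectory; image
#'   size must match the background.
#' @param depth_mm Working depth at which the XY grid is projected, mm.
#' @param alpha_max Peak overlay opacity.
#' @return h x w x 3 image array.
#' @export
overlay_density <- function(map2d, background, camera, depth_mm = 150,
                            alpha_max = 0.6) {
  stopifnot(inherits(map2d, "occupancy_map2d"))
  h <- dim(background)[1]; w <- dim(background)[2]
  if (w != camera$image_size[1] || h != camera$image_size[2])
    stop("image/camera size mismatch")
  pk <- max(map2d$percent)
  out <- background
  if (pk <= 0) return(out)
  ramp <- grDevices::colorRamp(c("#2166ac", "#67a9cf", "#f7f7f7",
                                 "#ef8a62", "#b2182b"))
  dims <- dim(map2d$percent)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    pc <- map2d$percent[i, j]
    if (pc <= 0) next
    # cell corners in track frame -> camera frame -> pixels
    x0 <- map2d$origin[1] + (i - 1) * map2d$cell_mm
    y0 <- map2d$origin[2] + (j - 1) * map2d$cell_mm
    corners_track <- cbind(c(x0, x0 + map2d$cell_mm),
                           c(y0, y0 + map2d$cell_mm), depth_mm)
    cc <- cbind(corners_track[, 1], -corners_track[, 2], depth_mm)
    px <- project_points(camera, cc)
    us <- sort(px[, 1]); vs <- sort(px[, 2])
    c0 <- max(1L, floor(us[1])); c1 <- min(w, ceiling(us[2]))
    r0 <- max(1L, floor(vs[1])); r1 <- min(h, ceiling(vs[2]))
    if (c1 < c0 || r1 < r0) next
    a <- alpha_max * pc / pk
    col <- ramp(pc / pk)[1, ] / 255
    for (ch in 1:3)
      out[r0:r1, c0:c1, ch] <- out[r0:r1, c0:c1, ch] * (1 - a) + col[ch] * a
  }
  out
}

#' Write an occupancy map as plain text with a JSON sidecar
#'
#' The dense percentage array goes to a whitespace-delimited text file
#' (3D maps as z-slabs separated by blank lines); origin, cell size, units
#' and totals go to `<path>.json`.
#'
#' @param map An `occupancy_map3d` or `occupancy_map2d`.
#' @param path Output text file path.
#' @export
write_occupancy_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(map, "occupancy_map3d")) {
    for (k in seq_len(dim(map$percent)[3])) {
      utils::write.table(map$percent[, , k], con, row.names = FALSE,
                         col.names = FALSE)
      writeLines("", con)
    }
    units <- "%s/cm^3"
  } else {
    utils::write.table(map$percent, con, row.names = FALSE,
                       col.names = FALSE)
    units <- "%s/cm^2"
  }
  jsonlite::write_json(
    list(origin_mm = map$origin, cell_mm = map$cell_mm, units = units,
         dims = dim(map$percent), total_time_s = map$total_time_s,
         out_of_grid_percent = map$out_of_grid_percent),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
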