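## Marker segmentation, classification and monocular tip pose estimation.
##
## Sub-pixel measurement strategy: segmentation gives binary regions; the
## classifier then re-measures each region on a soft "coverage" map obtained
## by projecting pixel colors onto the marker/background color axis (alpha
## matting). Rectangle corners come from total-least-squares line fits to
## coverage-shifted edge pixels; ring centres are coverage-weighted
## centroids. Both estimators localise edges far below one pixel on
## well-focused video.

brush3 <- function() EBImage::makeBrush(3, "box")

as_mask <- function(x) {
  storage.mode(x) <- "double"
  x
}

#' Segment marker-colored regions in a frame
#'
#' Thresholds the frame in hue/saturation/value space against each marker's
#' color profile, cleans the masks with a morphological opening followed by
#' closing (3x3 box element) and labels connected regions, discarding
#' regions below `min_area` pixels. An empty result is valid output.
#'
#' @param frame h x w x 3 RGB array in [0, 1].
#' @param color_profiles Named list of color profiles (each with `hue`,
#'   `saturation`, `value` ranges), or a list of `marker_spec` objects.
#' @param min_area Minimum region area in pixels.
#' @return A `marker_segmentation`: per color class the cleaned mask, the
#'   label matrix and per-region statistics (area, centroid, bounding box).
#' @export
segment_markers <- function(frame, color_profiles, min_area = 30) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  if (inherits(color_profiles[[1]], "marker_spec")) {
    specs <- color_profiles
    check_marker_specs(specs)
    color_profiles <- lapply(specs, `[[`, "color_profile")
    names(color_profiles) <- vapply(specs, `[[`, "", "marker_id")
  }
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rgbm <- rbind(as.numeric(frame[, , 1]),
                as.numeric(frame[, , 2]),
                as.numeric(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)

  classes <- lapply(color_profiles, function(pr) {
    keep <- hsv[1, ] >= pr$hue[1] & hsv[1, ] <= pr$hue[2] &
      hsv[2, ] >= pr$saturation[1] & hsv[2, ] <= pr$saturation[2] &
      hsv[3, ] >= pr$value[1] & hsv[3, ] <= pr$value[2]
    mask <- matrix(as.numeric(keep), h, w)
    mask <- EBImage::closing(EBImage::opening(mask, brush3()), brush3())
    labels <- EBImage::bwlabel(mask)
    tab <- tabulate(labels[labels > 0])
    ids <- which(tab >= min_area)
    regions <- lapply(ids, function(id) {
      idx <- which(labels == id)
      rows <- ((idx - 1) %% h) + 1
      cols <- ((idx - 1) %/% h) + 1
      # pixel (row j, col i) covers x in [i-1, i], y in [j-1, j]
      list(id = id, area = length(idx),
           centroid_px = c(mean(cols) - 0.5, mean(rows) - 0.5),
           bbox = c(min(cols), max(cols), min(rows), max(rows)),
           idx = idx)
    })
    list(profile = pr, mask = mask, labels = labels, regions = regions)
  })
  structure(list(classes = classes, frame = frame,
                 image_size = c(w, h)),
            class = "marker_segmentation")
}

## soft coverage map for one region ----------------------------------------

region_soft_alpha <- function(frame, labels, region_id, margin = 6L,
                              exclude = NULL) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  idx <- which(labels == region_id)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  r0 <- max(1L, min(rows) - margin); r1 <- min(h, max(rows) + margin)
  c0 <- max(1L, min(cols) - margin); c1 <- min(w, max(cols) + margin)
  sub <- frame[r0:r1, c0:c1, 1:3, drop = FALSE]
  m <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
  m[cbind(rows - r0 + 1, cols - c0 + 1)] <- 1

  b5 <- EBImage::makeBrush(5, "disc")
  b9 <- EBImage::makeBrush(9, "disc")
  interior <- EBImage::erode(m, b5)
  if (sum(interior) < 4) interior <- m
  support <- EBImage::dilate(m, b5)
  outer <- EBImage::dilate(m, b9) - support
  if (!is.null(exclude)) {
    ex <- EBImage::dilate(exclude[r0:r1, c0:c1] * 1, b5)
    outer <- outer * (ex == 0)
    support <- support * (ex == 0)
  }

  chan <- function(msk) {
    ii <- which(msk > 0)
    c(mean(sub[, , 1][ii]), mean(sub[, , 2][ii]), mean(sub[, , 3][ii]))
  }
  mk <- chan(interior)
  bg <- if (sum(outer) >= 4) chan(outer) else c(0, 0, 0)
  axis <- mk - bg
  den <- sum(axis^2)
  if (den < 1e-9) {
    alpha <- m
  } else {
    alpha <- ((sub[, , 1] - bg[1]) * axis[1] +
              (sub[, , 2] - bg[2]) * axis[2] +
              (sub[, , 3] - bg[3]) * axis[3]) / den
    alpha[alpha < 0] <- 0; alpha[alpha > 1] <- 1
    alpha <- alpha * (support > 0)
  }
  list(alpha = alpha, origin = c(c0, r0), mask = m)
}

# coverage-weighted centroid in full-image pixel coordinates
soft_centroid <- function(sa) {
  a <- sa$alpha
  tot <- sum(a)
  ii <- which(a > 0)
  rows <- ((ii - 1) %% nrow(a)) + 1
  cols <- ((ii - 1) %/% nrow(a)) + 1
  c(sum((cols - 0.5) * a[ii]) / tot + sa$origin[1] - 1,
    sum((rows - 0.5) * a[ii]) / tot + sa$origin[2] - 1)
}

## geometry helpers ---------------------------------------------------------

min_area_rect <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    e <- hull[i %% n + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2)); if (len < 1e-9) next
    d <- e / len; nrm <- c(-d[2], d[1])
    p1 <- hull %*% d; p2 <- hull %*% nrm
    area <- (max(p1) - min(p1)) * (max(p2) - min(p2))
    if (area < best_area) {
      best_area <- area
      best <- list(d = d, n = nrm, r1 = range(p1), r2 = range(p2))
    }
  }
  corners <- rbind(
    best$d * best$r1[1] + best$n * best$r2[1],
    best$d * best$r1[2] + best$n * best$r2[1],
    best$d * best$r1[2] + best$n * best$r2[2],
    best$d * best$r1[1] + best$n * best$r2[2])
  list(corners = corners, area = best_area)
}

tls_line <- function(pts, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(pts))
  wc <- colSums(pts * weights) / sum(weights)
  cc <- sweep(pts, 2, wc)
  M <- crossprod(cc * sqrt(weights))
  ev <- eigen(M, symmetric = TRUE)
  d <- ev$vectors[, 1]
  perp <- cc %*% ev$vectors[, 2]
  list(point = wc, dir = d, rms = sqrt(sum(weights * perp^2) / sum(weights)))
}

line_intersect <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-12) return(c(NA, NA))
  ab <- solve(A, p2 - p1)
  p1 + ab[1] * d1
}

# order 4 corners: counterclockwise in image coords starting from the
# corner with the smallest angle from the centroid
order_corners <- function(corners) {
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  corners[order(ang), , drop = FALSE]
}

## classification -----------------------------------------------------------

#' Classify segmented regions into marker detections
#'
#' Rectangle candidates must fill at least `min_rectangularity` of their
#' minimum-area enclosing rectangle; their corners are refined to sub-pixel
#' precision by intersecting total-least-squares line fits to the
#' coverage-shifted edge pixels of the soft alpha map. Ring-triplet
#' candidates are triples of regions whose coverage-weighted centroids are
#' collinear (within `collinear_tol_px` plus 5% of the span) with adjacent
#' gap ratio in [0.8, 1.25]. When two candidate triplets share a region the
#' higher-quality one is kept and the conflict reported as a message.
#'
#' @param seg A `marker_segmentation`.
#' @param specs List of `marker_spec` (matched to color classes by id).
#' @param min_rectangularity Area ratio threshold for rectangles.
#' @param collinear_tol_px Base collinearity tolerance in pixels.
#' @param frame_index Frame index recorded on the detections.
#' @return List of `marker_detection` objects: marker id, kind, ordered
#'   image primitives (4 corners, or 3 ring centres), quality in [0, 1].
#' @export
classify_marker <- function(seg, specs, min_rectangularity = 0.85,
                            collinear_tol_px = 2, frame_index = NA_integer_) {
  detections <- list()
  # pixels of any marker class must not leak into another region's
  # background estimate during alpha matting
  all_mask <- Reduce(`+`, lapply(seg$classes, `[[`, "mask")) > 0
  for (spec in specs) {
    cls <- seg$classes[[spec$marker_id]]
    if (is.null(cls)) {
      # match by profile equality if ids differ
      for (nm in names(seg$classes))
        if (identical(seg$classes[[nm]]$profile$hue, spec$color_profile$hue))
          cls <- seg$classes[[nm]]
    }
    if (is.null(cls) || length(cls$regions) == 0) next

    if (spec$kind == "rectangle") {
      for (reg in cls$regions) {
        h <- dim(seg$frame)[1]
        rows <- ((reg$idx - 1) %% h) + 1
        cols <- ((reg$idx - 1) %/% h) + 1
        pts <- cbind(cols - 0.5, rows - 0.5)
        mar <- min_area_rect(pts)
        # pixel-area vs rect area; rasterized area underestimates slightly
        if (reg$area / mar$area < min_rectangularity) next
        excl <- all_mask & !(cls$labels == reg$id)
        det <- refine_rectangle(seg$frame, cls$labels, reg$id, mar,
                                exclude = excl)
        if (is.null(det)) next
        detections[[length(detections) + 1]] <-
          structure(list(frame_index = frame_index,
                         marker_id = spec$marker_id, kind = "rectangle",
                         primitives = det$corners, quality = det$quality),
                    class = "marker_detection")
      }
    } else {
      regs <- cls$regions
      if (length(regs) < 3) next
      cents <- do.call(rbind, lapply(regs, function(reg) {
        sa <- region_soft_alpha(seg$frame, cls$labels, reg$id,
                                exclude = all_mask & !(cls$labels == reg$id))
        soft_centroid(sa)
      }))
      combos <- utils::combn(length(regs), 3)
      cand <- list()
      for (k in seq_len(ncol(combos))) {
        tri <- combos[, k]
        p <- cents[tri, , drop = FALSE]
        fit <- tls_line(p)
        proj <- as.numeric(sweep(p, 2, fit$point) %*% fit$dir)
        o <- order(proj)
        g1 <- proj[o[2]] - proj[o[1]]; g2 <- proj[o[3]] - proj[o[2]]
        if (g1 <= 0 || g2 <= 0) next
        ratio <- g2 / g1
        span <- proj[o[3]] - proj[o[1]]
        tol <- collinear_tol_px + 0.05 * span
        if (ratio < 0.8 || ratio > 1.25 || fit$rms > tol) next
        q <- exp(-(fit$rms / tol + abs(log(ratio))))
        cand[[length(cand) + 1]] <-
          list(tri = tri, centers = p[o, , drop = FALSE], quality = q)
      }
      if (length(cand) > 0) {
        cand <- cand[order(-vapply(cand, `[[`, 0, "quality"))]
        used <- integer(0)
        for (cd in cand) {
          if (any(cd$tri %in% used)) {
            message("classify_marker: overlapping ring triplet candidates; ",
                    "keeping highest quality")
            next
          }
          used <- c(used, cd$tri)
          detections[[length(detections) + 1]] <-
            structure(list(frame_index = frame_index,
                           marker_id = spec$marker_id, kind = "ring_triplet",
                           primitives = cd$centers, quality = cd$quality),
                      class = "marker_detection")
          break  # one triplet per spec
        }
      }
    }
  }
  detections
}

# Sub-pixel rectangle corner refinement: shift each soft edge pixel onto
# the edge line by (coverage - 1/2) along the outward normal, fit one line
# per side, intersect adjacent lines.
refine_rectangle <- function(frame, labels, region_id, mar, exclude = NULL) {
  sa <- region_soft_alpha(frame, labels, region_id, exclude = exclude)
  a <- sa$alpha
  ii <- which(a > 0.02)            # soft edge band plus the interior
  if (length(ii) < 16) return(NULL)
  rows <- ((ii - 1) %% nrow(a)) + 1
  cols <- ((ii - 1) %/% nrow(a)) + 1
  pts <- cbind(cols - 0.5 + sa$origin[1] - 1, rows - 0.5 + sa$origin[2] - 1)
  cov <- a[ii]
  soft <- cov > 0.05 & cov < 0.95

  corners <- order_corners(mar$corners)
  rms <- rep(1, 4)
  # the reference quad sharpens each pass, so side assignment of the edge
  # pixels converges to the true (perspective) quadrilateral
  for (pass in 1:3) {
    tol_perp <- if (pass == 1) 2.5 else 1.2
    ctr <- colMeans(corners)
    sides <- lapply(1:4, function(i) {
      p0 <- corners[i, ]; p1 <- corners[i %% 4 + 1, ]
      d <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
      nrm <- c(-d[2], d[1])
      if (sum((ctr - p0) * nrm) > 0) nrm <- -nrm  # outward normal
      list(p0 = p0, d = d, n = nrm, len = sqrt(sum((p1 - p0)^2)))
    })
    lines <- vector("list", 4)
    for (i in 1:4) {
      s <- sides[[i]]
      rel <- sweep(pts, 2, s$p0)
      along <- rel %*% s$d
      perp <- rel %*% s$n
      near <- abs(perp) < tol_perp
      for (j in setdiff(1:4, i)) {
        sj <- sides[[j]]
        pj <- abs(sweep(pts, 2, sj$p0) %*% sj$n)
        near <- near & (abs(perp) <= pj + 1e-9)
      }
      # keep clear of the corners, where coverage mixes two edges; fall
      # back to a narrower margin on short or sparsely sampled sides
      inner <- along > 4 & along < s$len - 4
      sel <- which(near & soft & inner)
      if (length(sel) < 6)
        sel <- which(near & soft & along > 2 & along < s$len - 2)
      if (length(sel) < 4) {
        # edge exactly on a pixel boundary: no partially covered pixels
        # exist, so use the fully covered boundary row — the inversion
        # formula shifts it half a pixel outward onto the edge
        sel <- which(cov >= 0.95 & perp > -1 & perp < 0.25 &
                       along > 2 & along < s$len - 2)
      }
      if (length(sel) < 4) return(NULL)
      # exact inversion of the covered-area function of a unit pixel cut
      # by a straight edge: linear in the middle band, quadratic in the
      # corner-triangle bands, governed by the edge normal's components
      cc <- max(abs(s$n[1]), abs(s$n[2]))
      ss <- min(abs(s$n[1]), abs(s$n[2]))
      h1 <- (cc + ss) / 2
      a1 <- ss / (2 * cc)          # coverage at the band boundary
      A <- cov[sel]
      toff <- ifelse(A < a1, -h1 + sqrt(pmax(2 * cc * ss * A, 0)),
              ifelse(A > 1 - a1, h1 - sqrt(pmax(2 * cc * ss * (1 - A), 0)),
                     (A - 0.5) * cc))
      # toff is the signed distance of the edge from the pixel centre along
      # the outward normal; move the centre by it to land on the edge
      shifted <- pts[sel, , drop = FALSE] + outer(toff, as.numeric(s$n))
      fit <- tls_line(shifted)
      lines[[i]] <- fit
      rms[i] <- fit$rms
    }
    corners <- do.call(rbind, lapply(1:4, function(i) {
      j <- if (i == 1) 4 else i - 1
      line_intersect(lines[[j]]$point, lines[[j]]$dir,
                     lines[[i]]$point, lines[[i]]$dir)
    }))
    if (any(!is.finite(corners))) return(NULL)
    corners <- order_corners(corners)
  }
  list(corners = corners, quality = exp(-mean(rms)))
}
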