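#' 8-connected component labelling of a logical mask
#'
#' Iterative minimum-label propagation over the 8-neighbourhood. Labels are
#' renumbered consecutively in first-occurrence (column-major scan) order, so
#' ties between equally sized components break deterministically by scan
#' order.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(Inf, nr + 2, nc + 2)
  inner_r <- 2:(nr + 1)
  inner_c <- 2:(nc + 1)
  lab[inner_r, inner_c][mask] <- which(mask)
  repeat {
    cur <- lab[inner_r, inner_c]
    new <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      new <- pmin(new, lab[inner_r + dr, inner_c + dc])
    }
    new[!mask] <- Inf
    if (identical(new, cur)) break
    lab[inner_r, inner_c] <- new
  }
  res <- lab[inner_r, inner_c]
  res[!mask] <- 0
  out <- matrix(0L, nr, nc)
  ids <- unique(res[mask])          # column-major first occurrence order
  out[mask] <- match(res[mask], ids)
  out
}

#' Minimum-area rotated rectangle of a pixel set
#'
#' Rotating-calipers search over the convex hull: the minimum-area enclosing
#' rectangle has a side collinear with a hull edge. Coordinates are pixel
#' centres (row, col), 1-based; reported side lengths are the enclosed spans
#' plus one pixel, so an axis-aligned w x h block reports sides w and h.
#'
#' @param coords Two-column matrix of (row, col) pixel coordinates.
#' @return A list of class `contour_box`: `corners` (4 x 2, (row, col),
#'   sub-pixel), `lengths` (long, short side in pixels) and `angle` (degrees of
#'   the long axis from the column axis).
#' @export
min_area_rect <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  x <- coords[, 2]
  y <- coords[, 1]
  if (length(x) == 1) {
    corners <- cbind(y + c(-.5, -.5, .5, .5), x + c(-.5, .5, .5, -.5))
    return(structure(list(corners = corners, lengths = c(1, 1), angle = 0),
                     class = "contour_box"))
  }
  h <- grDevices::chull(x, y)
  hx <- x[h]
  hy <- y[h]
  k <- length(h)
  best <- NULL
  best_area <- Inf
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ex <- hx[j] - hx[i]
    ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    ca <- ex / len
    sa <- ey / len
    u <- ca * hx + sa * hy
    v <- -sa * hx + ca * hy
    du <- diff(range(u))
    dv <- diff(range(v))
    area <- (du + 1) * (dv + 1)
    if (area < best_area - 1e-9) {
      best_area <- area
      best <- list(ca = ca, sa = sa, u0 = min(u), u1 = max(u),
                   v0 = min(v), v1 = max(v))
    }
  }
  with(best, {
    uu <- c(u0, u1, u1, u0)
    vv <- c(v0, v0, v1, v1)
    cx <- ca * uu - sa * vv
    cy <- sa * uu + ca * vv
    du <- u1 - u0 + 1
    dv <- v1 - v0 + 1
    ang <- atan2(sa, ca) * 180 / pi
    if (dv > du) ang <- ang + 90
    ang <- ((ang + 90) %% 180) - 90     # long-axis angle in (-90, 90]
    structure(list(corners = cbind(row = cy, col = cx),
                   lengths = c(max(du, dv), min(du, dv)),
                   angle = ang),
              class = "contour_box")
  })
}

#' @export
print.contour_box <- function(x, ...) {
  cat(sprintf("<contour_box> %.1f x %.1f px at %.1f deg\n",
              x$lengths[1], x$lengths[2], x$angle))
  invisible(x)
}

#' Adaptive hue-threshold segmentation of a depth frame
#'
#' Binarizes the hue channel at a threshold that starts 15 degrees below the
#' frame's mean hue (lower thresholds are preferred because they capture more
#' of the animal): pixels with hue below the threshold are foreground. The
#' largest 8-connected foreground component is kept and its axis-aligned
#' bounding box checked against the image border; while any corner lies within
#' `border_px` pixels of the edge the threshold is raised one degree at a
#' time, up to 5 degrees above the mean hue. On success the component mask and
#' its minimum-area rotated rectangle are returned.
#'
#' @param frame A `depth_frame`.
#' @param border_px Required clearance (pixels) between box corners and the
#'   image edge.
#' @param range_below,range_above Search range below/above the mean hue
#'   (degrees).
#' @param crop Optional `list(rows =, cols =)` integer ranges applied before
#'   segmentation to remove extraneous surroundings (default none).
#' @return A list: `mask` (logical matrix, largest component only), `box`
#'   (`contour_box`), `threshold` (degrees) and `mean_hue`.
#' @section Errors: `pigtme_no_pig` if no threshold in range yields foreground;
#'   `pigtme_segmentation_failed` if the box still touches the border at the
#'   maximum threshold (the frame is dropped).
#' @export
adaptive_hue_threshold <- function(frame, border_px = 5, range_below = 15,
                                   range_above = 5, crop = NULL) {
  hue <- frame$hue
  if (!is.null(crop)) hue <- hue[crop$rows, crop$cols, drop = FALSE]
  nr <- nrow(hue)
  nc <- ncol(hue)
  mh <- mean(hue)
  any_fg <- FALSE
  for (thr in seq(mh - range_below, mh + range_above, by = 1)) {
    fg <- hue < thr
    # a valid foreground is a minority object; a threshold that turns most of
    # the frame white has found background, not a pig
    if (!any(fg) || mean(fg) > 0.5) next
    any_fg <- TRUE
    lab <- label_components(fg)
    sizes <- tabulate(lab[lab > 0])
    comp <- which.max(sizes)            # ties -> first occurrence in scan order
    mask <- lab == comp
    rs <- range(which(rowSums(mask) > 0))
    cs <- range(which(colSums(mask) > 0))
    if (rs[1] > border_px && rs[2] <= nr - border_px &&
        cs[1] > border_px && cs[2] <= nc - border_px) {
      coords <- which(mask, arr.ind = TRUE)
      return(list(mask = mask, box = min_area_rect(coords),
                  threshold = thr, mean_hue = mh))
    }
  }
  if (!any_fg)
    abort("no pig detected: no foreground at any threshold in range.",
          class = "pigtme_no_pig")
  abort("segmentation failed: bounding box touches the border at the maximum threshold.",
        class = "pigtme_segmentation_failed")
}

#' Remove head and tail from a segmented mask
#'
#' The head and tail move much more than the trunk, so pixels beyond a
#' fraction of the long axis at each end are discarded. The trimmed fraction
#' per end is `trim_ratio * width / length` (the body width-to-length ratio),
#' capped at 0.25, applied symmetrically along the box's long axis.
#'
#' @param mask Logical matrix from [adaptive_hue_threshold()].
#' @param box The accompanying `contour_box`.
#' @param trim_ratio Multiplier on the width/length ratio (default 1).
#' @return The trimmed logical mask.
#' @section Errors: `pigtme_over_trim` if trimming empties the mask.
#' @export
trim_head_tail <- function(mask, box, trim_ratio = 1) {
  if (trim_ratio == 0) return(mask)
  frac <- min(trim_ratio * box$lengths[2] / box$lengths[1], 0.25)
  coords <- which(mask, arr.ind = TRUE)
  th <- box$angle * pi / 180
  proj <- coords[, 2] * cos(th) + coords[, 1] * sin(th)
  lo <- min(proj)
  hi <- max(proj)
  cut <- frac * (hi - lo)
  keep <- proj >= lo + cut & proj <= hi - cut
  if (!any(keep))
    abort("over-trim: trimming emptied the mask.", class = "pigtme_over_trim")
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[coords[keep, , drop = FALSE]] <- TRUE
  out
}

#' Biometric features of one segmented frame
#'
#' Dorsal length and abdominal width are the long and short sides of the
#' minimum-area rectangle of the (trimmed) mask, in pixels. Zeros inside the
#' mask (missing depth) are replaced by the mean of the non-zero masked
#' distances before any statistic. Height is the camera height minus the mean
#' masked distance; volume is the sum over masked pixels of
#' (camera height - distance).
#'
#' @param mask Logical matrix (non-empty).
#' @param distance_map Numeric matrix of distances (m), same shape.
#' @param camera_height Camera height (m).
#' @return A one-row tibble: `dorsal_length`, `abdominal_width` (pixels),
#'   `height` (m), `volume` (m * px^2).
#' @section Errors: `pigtme_no_depth` if every masked distance is zero.
#' @export
extract_features <- function(mask, distance_map, camera_height = 1.40) {
  stopifnot(identical(dim(mask), dim(distance_map)))
  if (!any(mask)) abort("mask is empty.")
  d <- distance_map[mask]
  nz <- d > 0
  if (!any(nz))
    abort("no depth signal: all masked distances are zero.",
          class = "pigtme_no_depth")
  d[!nz] <- mean(d[nz])
  box <- min_area_rect(which(mask, arr.ind = TRUE))
  tibble(dorsal_length = box$lengths[1],
         abdominal_width = box$lengths[2],
         height = camera_height - mean(d),
         volume = sum(camera_height - d))
}

#' Segment a single frame end to end
#'
#' Adaptive hue thresholding, head/tail trimming, then feature extraction.
#'
#' @param frame A `depth_frame`.
#' @param trim_ratio See [trim_head_tail()].
#' @param camera_height Camera height (m); defaults to the frame's.
#' @inheritParams adaptive_hue_threshold
#' @return A one-row tibble of features plus `threshold` used.
#' @export
segment_frame <- function(frame, trim_ratio = 1, border_px = 5,
                          range_below = 15, range_above = 5, crop = NULL,
                          camera_height = frame$camera_height) {
  seg <- adaptive_hue_threshold(frame, border_px, range_below, range_above,
                                crop)
  dmap <- frame$distance_map
  if (!is.null(crop)) dmap <- dmap[crop$rows, crop$cols, drop = FALSE]
  trimmed <- trim_head_tail(seg$mask, seg$box, trim_ratio)
  dplyr::mutate(extract_features(trimmed, dmap, camera_height),
                threshold = seg$threshold)
}

#' Median aggregation of per-frame features
#'
#' @param features Tibble of per-frame biometric features (one row per frame).
#' @return One-row tibble with the component-wise medians of `dorsal_length`,
#'   `abdominal_width`, `height`, `volume`.
#' @export
aggregate_video <- function(features) {
  if (nrow(features) == 0) abort("no frames to aggregate.")
  dplyr::summarise(features,
                   dplyr::across(c("dorsal_length", "abdominal_width",
                                   "height", "volume"), median))
}

#' Segment a depth video into one feature record
#'
#' Segments every frame, drops frames whose segmentation fails (recording the
#' reason), and returns the per-video medians of the four biometric features.
#'
#' @param video A `depth_video`.
#' @inheritParams segment_frame
#' @return One-row tibble: median features, `n_frames`, `n_used`, `n_dropped`,
#'   `drop_reasons` (collapsed string). The per-frame table is attached as
#'   `attr(, "frames")`.
#' @export
segment_video <- function(video, trim_ratio = 1, border_px = 5,
                          range_below = 15, range_above = 5, crop = NULL) {
  res <- purrr::map(video$frames, function(fr) {
    tryCatch(segment_frame(fr, trim_ratio, border_px, range_below,
                           range_above, crop),
             pigtme_no_pig = function(e) "no_pig",
             pigtme_segmentation_failed = function(e) "segmentation_failed",
             pigtme_over_trim = function(e) "over_trim",
             pigtme_no_depth = function(e) "no_depth")
  })
  ok <- purrr::map_lgl(res, is.data.frame)
  if (!any(ok))
    abort("all frames dropped; no features for this video.",
          class = "pigtme_video_failed")
  per_frame <- dplyr::bind_rows(res[ok])
  out <- dplyr::mutate(aggregate_video(per_frame),
                       n_frames = length(res),
                       n_used = sum(ok),
                       n_dropped = sum(!ok),
                       drop_reasons = paste(unlist(res[!ok]), collapse = ";"))
  attr(out, "frames") <- per_frame
  out
}
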