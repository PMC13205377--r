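#' Hue / distance pseudo-color encoding
#'
#' The renderer colors each pixel by a fixed, invertible linear map between
#' camera-to-surface distance and hue: `hue = hue_max * d / camera_height`
#' (degrees). The floor plane (distance = camera height) carries the maximum
#' hue; nearer surfaces (the pig's back) carry proportionally lower hue, so
#' foreground pixels are the low-hue pixels.
#'
#' @param d Distance (m), in `(0, camera_height]`.
#' @param hue Hue (degrees).
#' @param camera_height Camera height (m).
#' @param hue_max Hue assigned to the floor plane (degrees).
#' @return Hue in degrees, or distance in metres.
#' @export
hue_from_distance <- function(d, camera_height = 1.40, hue_max = 240) {
  hue_max * d / camera_height
}

#' @rdname hue_from_distance
#' @export
distance_from_hue <- function(hue, camera_height = 1.40, hue_max = 240) {
  hue * camera_height / hue_max
}

#' Construct a depth frame
#'
#' @param distance_map Numeric matrix of camera-to-surface distances (m), all
#'   in `(0, camera_height]`.
#' @param camera_height Camera height (m).
#' @param hue_max Floor hue (degrees).
#' @param frame_index Integer frame number.
#' @return An object of class `depth_frame` with the distance map, the hue
#'   channel (same shape, degrees) and the geometry metadata.
#' @export
depth_frame <- function(distance_map, camera_height = 1.40, hue_max = 240,
                        frame_index = 1L) {
  if (any(distance_map <= 0) || any(distance_map > camera_height + 1e-9))
    abort("distances must lie in (0, camera_height].")
  structure(list(distance_map = distance_map,
                 hue = hue_from_distance(distance_map, camera_height, hue_max),
                 camera_height = camera_height,
                 hue_max = hue_max,
                 frame_index = as.integer(frame_index)),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame> %dx%d px, distance %.3f-%.3f m (camera %.2f m)\n",
              nrow(x$distance_map), ncol(x$distance_map),
              min(x$distance_map), max(x$distance_map), x$camera_height))
  invisible(x)
}

#' Pseudo-color rendering of a depth frame
#'
#' @param frame A `depth_frame`.
#' @return A rows x cols x 3 array of RGB values in `[0, 1]` obtained from the
#'   hue channel at full saturation and value.
#' @export
frame_color <- function(frame) {
  h <- pmin(pmax(frame$hue / 360, 0), 1)
  cols <- grDevices::col2rgb(grDevices::hsv(h, 1, 1)) / 255
  array(t(cols), dim = c(nrow(frame$hue), ncol(frame$hue), 3))
}

# surface height (m above floor) of the body envelope, NA outside footprint.
# Dorsal profile z = clearance + c * sqrt(1 - q^flatness) with
# q = (u/a)^2 + (v/b)^2; flatness = 1 is a half-ellipsoid, the default
# flatness = 3 gives the broad flat back of a finishing pig.
ellipsoid_height <- function(rows, cols, m_per_px, center_px, angle_deg,
                             half_len, half_wid, body_height, clearance,
                             head_len = 0, tail_len = 0, flatness = 3) {
  cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  rr <- matrix(rep(seq_len(rows), times = cols), rows, cols)
  x <- (cc - center_px[2]) * m_per_px
  y <- (rr - center_px[1]) * m_per_px
  th <- angle_deg * pi / 180
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  q <- (u / half_len)^2 + (v / half_wid)^2
  h <- matrix(NA_real_, rows, cols)
  inside <- q <= 1
  h[inside] <- clearance + body_height * sqrt(1 - q[inside]^flatness)
  # head/tail: half-width slabs protruding along the long axis at 40% height
  for (sgn in c(1, -1)) {
    ext <- if (sgn > 0) head_len else tail_len
    if (ext > 0) {
      blob <- u * sgn > 0 & u * sgn <= half_len + ext &
        abs(v) <= 0.5 * half_wid
      blob <- blob & !inside
      h[blob] <- clearance + 0.4 * body_height
    }
  }
  h
}

#' Render one synthetic depth frame
#'
#' The pig is an ellipsoidal body with a flattened (superelliptical) dorsal
#' profile standing `clearance` metres above the floor plane: floor pixels are
#' at `camera_height`, pig pixels at
#' `camera_height - (clearance + local body height)`, with the maximum local
#' height equal to `body_height`. The hue channel follows the fixed linear
#' hue/distance map.
#'
#' @param shape One-row tibble from [shape_from_weight()], or `NULL` for an
#'   empty scene (pure floor plane).
#' @param config A [sim_config()] providing the camera geometry.
#' @param center_px Body centre `(row, col)` in pixels; default frame centre.
#' @param angle_deg Orientation of the long axis (degrees from the column
#'   axis).
#' @param head_len,tail_len Lengths (m) of head/tail protrusions beyond the
#'   ellipse along the long axis.
#' @param frame_index Frame number stored on the frame.
#' @return A `depth_frame`.
#' @export
render_depth_frame <- function(shape, config, center_px = NULL,
                               angle_deg = 0, head_len = 0, tail_len = 0,
                               frame_index = 1L) {
  rows <- config$image_shape[1]
  cols <- config$image_shape[2]
  d <- matrix(config$camera_height, rows, cols)
  if (!is.null(shape)) {
    if (is.null(center_px)) center_px <- c((rows + 1) / 2, (cols + 1) / 2)
    # thin-lens perspective: a body raised above the floor is magnified in
    # the image by camera_height / (camera_height - mid-body height), so the
    # ventral clearance inflates every pixel dimension coherently
    M <- config$camera_height /
      (config$camera_height - (shape$clearance + shape$body_height / 2))
    half_len <- M * shape$body_length / 2
    half_wid <- M * shape$body_width / 2
    head_len <- M * head_len
    tail_len <- M * tail_len
    th <- angle_deg * pi / 180
    ext_x <- sqrt((half_len * cos(th))^2 + (half_wid * sin(th))^2) +
      max(head_len, tail_len)
    ext_y <- sqrt((half_len * sin(th))^2 + (half_wid * cos(th))^2) +
      max(head_len, tail_len)
    if (center_px[2] - ext_x / config$m_per_px < 1 ||
        center_px[2] + ext_x / config$m_per_px > cols ||
        center_px[1] - ext_y / config$m_per_px < 1 ||
        center_px[1] + ext_y / config$m_per_px > rows)
      abort("shape too large for frame at this camera geometry.")
    h <- ellipsoid_height(rows, cols, config$m_per_px, center_px, angle_deg,
                          half_len, half_wid, shape$body_height,
                          shape$clearance, head_len, tail_len,
                          flatness = config$dorsal_flatness)
    d[!is.na(h)] <- config$camera_height - h[!is.na(h)]
  }
  depth_frame(d, config$camera_height, config$hue_max, frame_index)
}

#' Render a synthetic depth video
#'
#' Renders `config$n_frames` frames of one animal with small per-frame jitter
#' of position and orientation and randomly varying head/tail protrusions,
#' emulating a restrained pig whose head and tail move more than its body.
#' Fully deterministic given `seed`.
#'
#' @param shape One-row tibble from [shape_from_weight()].
#' @param config A [sim_config()].
#' @param seed Integer seed for the jitter.
#' @return An object of class `depth_video`: list of `depth_frame`s plus the
#'   generating shape.
#' @export
render_depth_video <- function(shape, config, seed) {
  set.seed(seed)
  rows <- config$image_shape[1]
  cols <- config$image_shape[2]
  center0 <- c((rows + 1) / 2, (cols + 1) / 2)
  frames <- lapply(seq_len(config$n_frames), function(i) {
    render_depth_frame(
      shape, config,
      center_px = center0 + rnorm(2, 0, config$jitter_px),
      angle_deg = rnorm(1, 0, config$jitter_deg),
      head_len = abs(rnorm(1, 0.3, 0.15)) * shape$body_width,
      tail_len = abs(rnorm(1, 0.15, 0.1)) * shape$body_width,
      frame_index = i
    )
  })
  structure(list(frames = frames, shape = shape,
                 camera_height = config$camera_height,
                 hue_max = config$hue_max),
            class = "depth_video")
}

#' @export
print.depth_video <- function(x, ...) {
  cat(sprintf("<depth_video> %d frames, %dx%d px\n", length(x$frames),
              nrow(x$frames[[1]]$distance_map),
              ncol(x$frames[[1]]$distance_map)))
  invisible(x)
}
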