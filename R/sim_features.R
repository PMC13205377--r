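# Grid integration over the (trimmed) unit ellipse of the dorsal profile
# sqrt(1 - q^flatness): returns the trimmed footprint area as a fraction of
# the full ellipse and the mean profile height over the trimmed footprint.
# Used by the feature-space generator so that it agrees with what the
# segmentation pipeline extracts from rendered frames.
ellipse_patch_stats <- function(flatness = 3, trim_frac = 0.25, n = 401) {
  u <- seq(-1, 1, length.out = n)
  v <- seq(-1, 1, length.out = n)
  q <- outer(u^2, v^2, "+")
  inside <- q <= 1
  keep <- inside & abs(matrix(u, n, n)) <= (1 - 2 * trim_frac)
  prof <- sqrt(pmax(0, 1 - q[keep]^flatness))
  list(area_frac = sum(keep) / sum(inside),
       mean_height_frac = mean(prof))
}

#' Simulate per-video biometric features without rendering
#'
#' Feature-space mode of the generator: instead of rendering and segmenting
#' hundreds of depth videos, the per-video median features are drawn directly
#' from the body geometry that the renderer would produce, with multiplicative
#' log-normal noise of coefficient of variation `feature_cv` standing in for
#' segmentation and pose variability after median aggregation. The ventral
#' clearance enters the height and volume features exactly as the depth camera
#' sees it: the camera measures distance to the back, so apparent height is
#' clearance plus the mean dorsal height of the (head/tail-trimmed) footprint.
#'
#' @param phenotypes Phenotype tibble from [simulate_trait()] (one row per
#'   animal x time point; `scale_bw` is used as the true body mass).
#' @param clearance Clearance tibble from [simulate_clearance()].
#' @param config The [sim_config()].
#' @param trim_ratio Head/tail trim parameter mirrored from the segmentation
#'   stage (fraction per end = `trim_ratio * width/length`, capped at 0.25).
#' @return The phenotype tibble with columns `dorsal_length`,
#'   `abdominal_width` (pixels), `height` (m), `volume` (m * px^2) appended.
#' @details The analytic geometry is calibrated against a single rendered
#'   reference frame (median body weight and clearance, no jitter, mean
#'   head/tail protrusions) passed through the actual segmentation pipeline,
#'   so that the two generation modes agree on a rendered subset; the
#'   per-feature calibration ratios are in `attr(, "calibration")`.
#' @export
simulate_features <- function(phenotypes, clearance, config, trim_ratio = 1) {
  set.seed(config$seed + 3L)
  df <- dplyr::left_join(phenotypes, clearance, by = "animal_id")
  shp <- shape_from_weight(df$scale_bw, config$allometry, df$clearance)
  # per-animal conformation: length/width deviate from the allometric mean,
  # height balances them so that L*W*H stays proportional to body mass;
  # deviations are a property of the animal, constant across time points
  ids <- unique(df$animal_id)
  dl <- setNames(rnorm(length(ids), 0, config$shape_cv), ids)
  dw <- setNames(rnorm(length(ids), 0, config$shape_cv), ids)
  shp$body_length <- shp$body_length * exp(dl[df$animal_id])
  shp$body_width <- shp$body_width * exp(dw[df$animal_id])
  shp$body_height <- shp$body_height * exp(-dl[df$animal_id] -
                                             dw[df$animal_id])
  frac <- pmin(trim_ratio * shp$body_width / shp$body_length, 0.25)
  # trim fraction is effectively constant across animals (isometric scaling)
  st <- ellipse_patch_stats(config$dorsal_flatness, trim_frac = frac[1])
  analytic <- function(s) {
    f <- pmin(trim_ratio * s$body_width / s$body_length, 0.25)
    # same thin-lens magnification as the renderer: raised bodies appear
    # larger, so clearance inflates the pixel features coherently
    M <- config$camera_height /
      (config$camera_height - (s$clearance + s$body_height / 2))
    h_m <- s$clearance + st$mean_height_frac * s$body_height
    tibble(dorsal_length = M * s$body_length * (1 - 2 * f) / config$m_per_px,
           abdominal_width = M * s$body_width / config$m_per_px,
           height = h_m,
           volume = M^2 * pi / 4 * (s$body_length / config$m_per_px) *
             (s$body_width / config$m_per_px) * st$area_frac * h_m)
  }
  cal <- feature_calibration(df, config, trim_ratio, analytic)
  base <- analytic(shp)
  n <- nrow(df)
  cv <- config$feature_cv
  noise <- function() exp(rnorm(n, 0, cv))
  out <- dplyr::mutate(df,
                       body_length = shp$body_length,
                       body_width = shp$body_width,
                       body_height = shp$body_height,
                       dorsal_length = base$dorsal_length *
                         cal["dorsal_length"] * noise(),
                       abdominal_width = base$abdominal_width *
                         cal["abdominal_width"] * noise(),
                       height = base$height * cal["height"] * noise(),
                       volume = base$volume * cal["volume"] * noise())
  attr(out, "calibration") <- cal
  out
}

# ratio rendered/analytic for each feature on one deterministic reference
# frame (median shape, mean protrusions, no jitter); identity if the shape
# cannot be rendered in the configured frame
feature_calibration <- function(df, config, trim_ratio, analytic) {
  feats <- c("dorsal_length", "abdominal_width", "height", "volume")
  ref <- shape_from_weight(median(df$scale_bw), config$allometry,
                           median(df$clearance))
  rendered <- tryCatch({
    fr <- render_depth_frame(ref, config,
                             head_len = 0.3 * ref$body_width,
                             tail_len = 0.15 * ref$body_width)
    segment_frame(fr, trim_ratio = trim_ratio)
  }, error = function(e) {
    warning("feature calibration render failed (", conditionMessage(e),
            "); using analytic geometry uncalibrated.")
    NULL
  })
  if (is.null(rendered)) return(setNames(rep(1, 4), feats))
  unlist(rendered[feats]) / unlist(analytic(ref)[feats])
}
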