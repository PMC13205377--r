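#' Simulation configuration
#'
#' Builds the configuration object for the synthetic genotype / phenotype /
#' depth-video generator. Defaults describe a commercial finishing cohort:
#' 800 crossbred pigs in full-sib litters nested within 40 sires, genotyped at
#' 10,000 independent SNPs, weighed at four farm visits (T1--T4) under a depth
#' camera mounted 1.40 m above a one-way exit lane.
#'
#' @param n_individuals Number of animals.
#' @param n_markers Number of SNP markers (additive 0/1/2 coding).
#' @param maf_low,maf_high Allele-frequency range for marker sampling,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param n_qtl Number of body-weight QTL (sampled among the markers).
#' @param qtl_effect_dist `"equal"` (default: every QTL explains the same
#'   variance, signs random) or `"normal"` (effects drawn N(0,1) on the
#'   standardized scale).
#' @param h2_bw Narrow-sense heritability of scale body weight, in `[0, 1]`.
#' @param h2_clearance Heritability of ventral clearance (ground-to-abdomen
#'   gap), in `[0, 1]`. Zero gives the random-error scenario.
#' @param time_points Character vector of visit labels.
#' @param mean_bw Mean body weight (kg) per time point; recycled to
#'   `length(time_points)`.
#' @param sd_bw Phenotypic SD of body weight within a time point (kg).
#' @param fixed_effects Named list of effect magnitudes: `sex` (kg difference
#'   between sexes), `birth_farm_sd` (SD of farm shifts, kg), `pen_density`
#'   (kg per unit density deviation), `age` (kg per day of age deviation),
#'   `parity_sd` (SD of dam-parity shifts, kg).
#' @param n_sires,dams_per_sire Pedigree of the cohort: full-sib litters nested
#'   in sires. `n_sires = NULL` draws every animal independently (unrelated
#'   cohort, genotypes i.i.d. Binomial(2, p)).
#' @param clearance_mean,clearance_sd Mean and SD of ventral clearance (m).
#' @param clearance_maf_low,clearance_maf_high Observed-frequency window from
#'   which the clearance-increasing major locus is drawn when
#'   `h2_clearance > 0`.
#' @param camera_height Camera height above the floor (m).
#' @param image_shape Integer `(rows, cols)` of the rendered frames.
#' @param n_frames Frames per rendered video.
#' @param m_per_px Metres of floor per pixel at the floor plane.
#' @param hue_max Hue (degrees) assigned to the floor plane; hue is linear in
#'   distance with hue 0 at distance 0.
#' @param allometry Named coefficients `length`, `width`, `height` so that each
#'   body dimension equals `coefficient * bw^(1/3)` (m, bw in kg).
#' @param shape_cv Per-animal conformation variability: SD of the log-scale
#'   deviations of body length and width from the allometric mean at a given
#'   weight (the height deviation balances them so that length x width x
#'   height stays proportional to mass). Zero makes shape a deterministic
#'   function of weight.
#' @param feature_cv Coefficient of variation of the multiplicative noise on
#'   simulated per-video biometric features (feature-space mode).
#' @param image_noise_frac SD of i.i.d. image-BW noise as a fraction of the
#'   time-point mean BW (direct-noise mode).
#' @param jitter_px,jitter_deg Per-frame positional jitter (pixels) and
#'   orientation jitter (degrees) in rendered videos.
#' @param dorsal_flatness Exponent of the superelliptical dorsal profile
#'   (`1` = half-ellipsoid; the default `3` gives a broad flat back).
#' @param seed Integer seed; mandatory, drives every random draw downstream.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_individuals = 40, n_markers = 200, seed = 1)
#' cfg$h2_bw
#' @export
sim_config <- function(n_individuals = 800,
                       n_markers = 10000,
                       maf_low = 0.05,
                       maf_high = 0.5,
                       n_qtl = 10,
                       qtl_effect_dist = c("equal", "normal"),
                       h2_bw = 0.4,
                       h2_clearance = 0,
                       time_points = c("T1", "T2", "T3", "T4"),
                       mean_bw = c(65, 78, 92, 114),
                       sd_bw = 12,
                       fixed_effects = list(sex = 1.5, birth_farm_sd = 1,
                                            pen_density = 0.8, age = 0.25,
                                            parity_sd = 0.5),
                       n_sires = 40,
                       dams_per_sire = 2,
                       clearance_mean = 0.18,
                       clearance_sd = 0.01,
                       clearance_maf_low = 0.05,
                       clearance_maf_high = 0.10,
                       camera_height = 1.40,
                       image_shape = c(180L, 320L),
                       n_frames = 20,
                       m_per_px = 0.0083,
                       hue_max = 240,
                       allometry = c(length = 0.237, width = 0.069,
                                     height = 0.086),
                       shape_cv = 0.04,
                       feature_cv = 0.02,
                       image_noise_frac = 0.015,
                       jitter_px = 2,
                       jitter_deg = 5,
                       dorsal_flatness = 3,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    maf_low = maf_low, maf_high = maf_high,
    n_qtl = as.integer(n_qtl),
    qtl_effect_dist = match.arg(qtl_effect_dist),
    h2_bw = h2_bw, h2_clearance = h2_clearance,
    time_points = as.character(time_points),
    mean_bw = rep_len(mean_bw, length(time_points)),
    sd_bw = sd_bw,
    fixed_effects = fixed_effects,
    n_sires = if (is.null(n_sires)) NULL else as.integer(n_sires),
    dams_per_sire = as.integer(dams_per_sire),
    clearance_mean = clearance_mean, clearance_sd = clearance_sd,
    clearance_maf_low = clearance_maf_low,
    clearance_maf_high = clearance_maf_high,
    camera_height = camera_height,
    image_shape = as.integer(image_shape),
    n_frames = as.integer(n_frames),
    m_per_px = m_per_px,
    hue_max = hue_max,
    allometry = allometry,
    shape_cv = shape_cv,
    feature_cv = feature_cv,
    image_noise_frac = image_noise_frac,
    jitter_px = jitter_px, jitter_deg = jitter_deg,
    dorsal_flatness = dorsal_flatness,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$maf_low > 0 && cfg$maf_low <= cfg$maf_high && cfg$maf_high <= 0.5))
    abort("invalid MAF range: need 0 < maf_low <= maf_high <= 0.5.")
  if (cfg$n_qtl > cfg$n_markers)
    abort("n_qtl must not exceed n_markers.")
  for (h in c(cfg$h2_bw, cfg$h2_clearance))
    if (h < 0 || h > 1) abort("heritabilities must lie in [0, 1].")
  if (cfg$h2_bw == 1 && cfg$sd_bw == 0)
    abort("degenerate trait model: h2_bw = 1 with sd_bw = 0.")
  if (cfg$camera_height <= 0) abort("camera_height must be positive.")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape <= 0))
    abort("image_shape must be two positive integers (rows, cols).")
  if (!is.null(cfg$n_sires) && cfg$n_sires < 1)
    abort("n_sires must be NULL or a positive integer.")
  if (length(cfg$mean_bw) != length(cfg$time_points))
    abort("mean_bw must align with time_points.")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort : n = %d (%s), m = %d markers, MAF U(%.2f, %.2f)\n",
              x$n_individuals,
              if (is.null(x$n_sires)) "unrelated"
              else sprintf("%d sires x %d dams", x$n_sires, x$dams_per_sire),
              x$n_markers, x$maf_low, x$maf_high))
  cat(sprintf("  trait  : %d QTL, h2_bw = %.2f, h2_clearance = %.2f\n",
              x$n_qtl, x$h2_bw, x$h2_clearance))
  cat(sprintf("  visits : %s (mean BW %s kg, sd %.1f)\n",
              paste(x$time_points, collapse = ","),
              paste(x$mean_bw, collapse = "/"), x$sd_bw))
  cat(sprintf("  camera : %.2f m above floor, %dx%d px, %d frames\n",
              x$camera_height, x$image_shape[1], x$image_shape[2], x$n_frames))
  invisible(x)
}
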