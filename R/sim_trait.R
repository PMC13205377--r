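#' Simulate an additive trait and phenotype table
#'
#' Samples `n_qtl` QTL without replacement among the markers, draws their
#' additive effects, scales the breeding values so that
#' `var(u) = h2_bw * sd_bw^2`, and builds one phenotype record per animal and
#' time point: `scale_bw = mean_bw[t] + Xb + u + e` with
#' `e ~ N(0, (1 - h2_bw) * sd_bw^2)` drawn independently per visit. Fixed
#' effects are sex, birth farm, pen density, age and parity of dam, with the
#' magnitudes set in the configuration.
#'
#' @param geno A `geno_matrix` from [simulate_genotypes()].
#' @param config The [sim_config()] used to generate `geno`.
#' @return A list with `architecture` (QTL tibble, `breeding_values`) and
#'   `phenotypes` (tibble: one row per animal x time point with `scale_bw`,
#'   covariates and the true breeding value `true_bv`).
#' @examples
#' cfg <- sim_config(n_individuals = 40, n_markers = 100, n_qtl = 5,
#'                   n_sires = 4, seed = 2)
#' tr <- simulate_trait(simulate_genotypes(cfg), cfg)
#' head(tr$phenotypes)
#' @export
simulate_trait <- function(geno, config) {
  validate_sim_config(config)
  if (config$n_qtl > ncol(geno$codes))
    abort("n_qtl exceeds the number of markers in `geno`.")
  set.seed(config$seed + 1L)
  n <- nrow(geno$codes)
  fx <- config$fixed_effects

  # QTL must segregate in the cohort: sample among markers with variance
  poly <- which(colMeans(geno$codes^2) - colMeans(geno$codes)^2 > 0)
  if (length(poly) < config$n_qtl)
    abort("fewer polymorphic markers than n_qtl in this cohort.")
  qtl_idx <- sort(poly[sample.int(length(poly), config$n_qtl)])
  # equal variance per QTL on the standardized scale (random sign) unless a
  # normal effect-size distribution is requested
  effects <- switch(config$qtl_effect_dist,
                    equal = sample(c(-1, 1), config$n_qtl, replace = TRUE),
                    normal = rnorm(config$n_qtl))
  if (config$h2_bw > 0 && config$sd_bw > 0) {
    W_q <- standardize_markers(geno$codes[, qtl_idx, drop = FALSE])$W
    u_raw <- drop(W_q %*% effects)
    target_sd <- sqrt(config$h2_bw) * config$sd_bw
    scl <- target_sd / sd(u_raw)
    u <- (u_raw - mean(u_raw)) * scl
    effects <- effects * scl
  } else {
    u <- rep(0, n)
    effects <- rep(0, config$n_qtl)
  }

  ids <- rownames(geno$codes)
  sex <- sample(c("barrow", "gilt"), n, replace = TRUE)
  farm <- sample(paste0("F", 1:3), n, replace = TRUE)
  farm_shift <- setNames(rnorm(3, 0, fx$birth_farm_sd), paste0("F", 1:3))
  pen_density <- round(rnorm(n), 3)
  parity <- sample(1:5, n, replace = TRUE)
  parity_shift <- setNames(rnorm(5, 0, fx$parity_sd), 1:5)
  age_dev <- round(rnorm(n, 0, 3))
  visit_age <- setNames(c(103, 117, 131, 159)[seq_along(config$time_points)],
                        config$time_points)

  xb <- ifelse(sex == "gilt", fx$sex / 2, -fx$sex / 2) +
    farm_shift[farm] + fx$pen_density * pen_density +
    parity_shift[as.character(parity)]

  res_sd <- sqrt(max(0, 1 - config$h2_bw)) * config$sd_bw
  pheno <- purrr::map_dfr(seq_along(config$time_points), function(t) {
    tp <- config$time_points[t]
    tibble(
      animal_id = ids,
      time_point = tp,
      sex = sex,
      birth_farm = farm,
      pen_density = pen_density,
      age = visit_age[tp] + age_dev,
      parity = parity,
      true_bv = u,
      scale_bw = config$mean_bw[t] + xb + fx$age * age_dev + u +
        rnorm(n, 0, res_sd)
    )
  })
  if (any(pheno$scale_bw <= 0))
    abort("simulated scale_bw not positive; check mean_bw / sd_bw settings.")

  list(
    architecture = list(
      qtl = tibble(index = qtl_idx,
                   marker_id = colnames(geno$codes)[qtl_idx],
                   effect = effects),
      breeding_values = setNames(u, ids)
    ),
    phenotypes = pheno
  )
}

#' Simulate ventral clearance
#'
#' Ventral clearance is the ground-to-abdomen gap that a top-view depth camera
#' cannot see: it inflates the apparent height and volume of the animal. With
#' `h2_clearance = 0` clearance is pure environment
#' (`N(clearance_mean, clearance_sd^2)`, truncated at zero). With
#' `h2_clearance > 0` the genetic part comes from a single clearance-increasing
#' major locus segregating at low frequency (drawn from markers with observed
#' minor-allele frequency in the configured window, by default 0.05--0.10),
#' so that the clearance distribution is right-skewed: a minority of families
#' carries the allele that lifts the abdomen. The locus is disjoint from the
#' body-weight QTL when their indices are passed via `exclude`.
#'
#' @param geno A `geno_matrix`.
#' @param config The [sim_config()].
#' @param exclude Optional integer marker indices never used as the clearance
#'   locus (the BW QTL, typically).
#' @return A tibble with `animal_id`, `clearance` (m, `>= 0`) and
#'   `clearance_bv` (genetic part, m); the chosen locus index is in
#'   `attr(, "locus")` (NA when non-genetic).
#' @export
simulate_clearance <- function(geno, config, exclude = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(geno$codes)
  ids <- rownames(geno$codes)
  if (config$h2_clearance == 0) {
    cl <- config$clearance_mean + rnorm(n, 0, config$clearance_sd)
    out <- tibble(animal_id = ids, clearance = pmax(cl, 0), clearance_bv = 0)
    attr(out, "locus") <- NA_integer_
    return(out)
  }
  maf <- pmin(geno$allele_freq, 1 - geno$allele_freq)
  cand <- which(maf >= config$clearance_maf_low &
                  maf <= config$clearance_maf_high)
  cand <- setdiff(cand, exclude)
  if (!length(cand))
    abort("no candidate marker in the clearance frequency window.")
  locus <- cand[sample.int(length(cand), 1L)]
  dosage <- as.numeric(geno$codes[, locus])
  if (sd(dosage) == 0) abort("clearance locus is monomorphic in the cohort.")
  a <- sqrt(config$h2_clearance) * config$clearance_sd / sd(dosage)
  g <- a * (dosage - mean(dosage))
  env_sd <- sqrt(1 - config$h2_clearance) * config$clearance_sd
  cl <- config$clearance_mean + g + rnorm(n, 0, env_sd)
  out <- tibble(animal_id = ids, clearance = pmax(cl, 0), clearance_bv = g)
  attr(out, "locus") <- locus
  out
}
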