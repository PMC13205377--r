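#' Simulate SNP genotypes for a cohort
#'
#' Draws an n x m additive genotype matrix (codes 0/1/2). Marker allele
#' frequencies are sampled `p_j ~ Uniform(maf_low, maf_high)`. With
#' `n_sires = NULL` every animal is an independent `Binomial(2, p_j)` draw
#' (unrelated cohort). Otherwise the cohort is a sire x litter design:
#' founder sires and dams are independent binomial draws and each offspring
#' receives one Mendelian allele from its sire and one from its dam, giving
#' full-sib litters nested within sires (no linkage disequilibrium in either
#' mode; markers are independent).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `geno_matrix`: a list with `codes` (n x m
#'   integer matrix, rownames = animal ids, colnames = marker ids),
#'   `allele_freq` (observed column means / 2) and `pedigree` (a tibble with
#'   `animal_id`, `sire`, `dam`; founders are not part of the cohort).
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 20, n_markers = 50,
#'                                    n_sires = 4, seed = 1))
#' dim(g$codes)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_markers
  p <- runif(m, config$maf_low, config$maf_high)
  if (is.null(config$n_sires)) {
    codes <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    ped <- tibble(animal_id = sprintf("A%04d", seq_len(n)),
                  sire = NA_character_, dam = NA_character_)
  } else {
    n_sires <- config$n_sires
    n_dams <- n_sires * config$dams_per_sire
    litter <- rep(seq_len(n_dams), length.out = n)  # dam of each offspring
    sire_of_dam <- rep(seq_len(n_sires), each = config$dams_per_sire)
    sire_codes <- matrix(rbinom(n_sires * m, 2L, rep(p, each = n_sires)),
                         n_sires, m)
    dam_codes <- matrix(rbinom(n_dams * m, 2L, rep(p, each = n_dams)),
                        n_dams, m)
    # transmitted allele: Bernoulli(parent dosage / 2) per offspring x marker
    from_sire <- matrix(rbinom(n * m, 1L,
                               (sire_codes / 2)[sire_of_dam[litter], ]), n, m)
    from_dam <- matrix(rbinom(n * m, 1L, (dam_codes / 2)[litter, ]), n, m)
    codes <- from_sire + from_dam
    ped <- tibble(animal_id = sprintf("A%04d", seq_len(n)),
                  sire = sprintf("S%03d", sire_of_dam[litter]),
                  dam = sprintf("D%03d", litter))
  }
  storage.mode(codes) <- "integer"
  rownames(codes) <- ped$animal_id
  colnames(codes) <- sprintf("M%05d", seq_len(m))
  structure(list(codes = codes,
                 allele_freq = colMeans(codes) / 2,
                 drawn_freq = p,
                 pedigree = ped),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d markers (%s)\n",
              nrow(x$codes), ncol(x$codes),
              if (all(is.na(x$pedigree$sire))) "unrelated"
              else sprintf("%d sires", length(unique(x$pedigree$sire)))))
  invisible(x)
}

#' Subset a genotype matrix by marker
#'
#' @param geno A `geno_matrix`.
#' @param keep Logical or integer index over markers.
#' @return A `geno_matrix` with the retained markers, order preserved.
#' @keywords internal
subset_markers <- function(geno, keep) {
  codes <- geno$codes[, keep, drop = FALSE]
  structure(list(codes = codes,
                 allele_freq = colMeans(codes) / 2,
                 drawn_freq = geno$drawn_freq[keep],
                 pedigree = geno$pedigree),
            class = "geno_matrix")
}
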