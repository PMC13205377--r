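# shared fixtures, all generated in code

# small cohort configuration for module tests
tiny_cfg <- function(n = 60, m = 400, seed = 1, ...) {
  sim_config(n_individuals = n, n_markers = m, n_qtl = 5, n_sires = 6,
             time_points = c("T1", "T2"), mean_bw = c(65, 78), seed = seed,
             ...)
}

# depth frame holding a rectangular slab of known footprint at a uniform
# distance, floor at camera height
slab_frame <- function(rows = 60, cols = 80, slab_rows = 21:40,
                       slab_cols = 21:60, slab_dist = 1.0,
                       camera_height = 1.40) {
  d <- matrix(camera_height, rows, cols)
  d[slab_rows, slab_cols] <- slab_dist
  depth_frame(d, camera_height = camera_height)
}

# a cohort with GRM eigendecomposition cached, reused across expectations
make_cohort <- function(n = 200, m = 1500, seed = 42, ...) {
  cfg <- sim_config(n_individuals = n, n_markers = m, n_sires = max(4, n %/% 20),
                    time_points = "T2", mean_bw = 78, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  geno_f <- maf_filter(geno)
  grm <- build_grm(geno_f)
  list(cfg = cfg, geno = geno, geno_f = geno_f, grm = grm,
       eg = eigen(grm$G, symmetric = TRUE))
}
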