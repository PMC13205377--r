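test_that("TME is the absolute paired difference with scale as denominator", {
  d <- compute_tme(tibble::tibble(scale_bw = c(100, 80), image_bw = c(98, 84)))
  expect_equal(d$tme, c(2, 4))
  expect_equal(d$tme_percent, c(2.0, 5.0))
  same <- compute_tme(tibble::tibble(scale_bw = c(60, 70), image_bw = c(60, 70)))
  expect_true(all(same$tme == 0))
  # symmetry in the two measurements
  a <- compute_tme(tibble::tibble(scale_bw = c(90, 95), image_bw = c(85, 99)))
  b <- compute_tme(tibble::tibble(scale_bw = c(85, 99), image_bw = c(90, 95)))
  expect_equal(a$tme, b$tme)
  expect_error(compute_tme(tibble::tibble(scale_bw = c(1, NA),
                                          image_bw = c(1, 2))), "unpaired")
  expect_error(compute_tme(tibble::tibble(scale_bw = 100)), "missing columns")
})

make_ranking <- function(ids, order_ids) {
  tibble::tibble(marker_id = ids, rank = match(ids, order_ids))
}

test_that("top-k agreement counts the intersection and handles the extremes", {
  ids <- sprintf("M%04d", 1:500)
  self <- make_ranking(ids, ids)
  expect_equal(topk_agreement(self, self), 10)
  reversed <- make_ranking(ids, rev(ids))
  expect_equal(topk_agreement(self, reversed), 0)
  expect_error(topk_agreement(self, make_ranking(ids[-1], ids[-1])),
               "marker sets")
})

test_that("agreement with a random ranking matches the hypergeometric expectation", {
  ids <- sprintf("M%05d", 1:10000)
  ref <- make_ranking(ids, ids)
  set.seed(99)
  counts <- vapply(1:1000, function(i)
    topk_agreement(ref, make_ranking(ids, sample(ids))), numeric(1))
  expect_lt(abs(mean(counts) - 10 * 100 / 10000), 0.04)
})

test_that("agreement is monotone non-decreasing in the reference list size", {
  ids <- sprintf("M%04d", 1:1000)
  ref <- make_ranking(ids, ids)
  set.seed(5)
  other <- make_ranking(ids, sample(ids))
  counts <- vapply(c(10, 50, 100, 500, 1000), function(k)
    topk_agreement(ref, other, k_ref = k), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[5], 10)   # the full list always contains the top 10
})

test_that("consistently extreme animals are flagged across time points", {
  set.seed(8)
  base <- tidyr::expand_grid(animal_id = sprintf("A%03d", 1:50),
                             time_point = c("T1", "T2", "T3"))
  base$tme <- runif(nrow(base), 1, 5)
  base$tme[base$animal_id == "A001"] <- 0       # perfect at all visits
  base$tme[base$animal_id == "A002"] <- 50      # terrible at all visits
  cons <- tme_consistency(base, quantile = 0.1, min_times = 2)
  expect_true("A001" %in% cons$animal_id[cons$group == "low"])
  expect_true("A002" %in% cons$animal_id[cons$group == "high"])
})

test_that("the assembled report has one row per table for a single run and re-derivable totals", {
  fm <- tibble::tibble(time_point = "T2", method = "ols", split = "test",
                       r2 = 0.95, mape = 2.5, n = 40)
  h2 <- tibble::tibble(time_point = "T2", method = "ols", trait = "tme",
                       h2 = 0.01, se_h2 = 0.02, boundary = TRUE)
  ag <- tibble::tibble(time_point = "T2", method = "ols", agreement = 10L,
                       tme_overlap = 0L, k_top = 10L, k_ref = 100L)
  tme <- compute_tme(tibble::tibble(animal_id = sprintf("A%02d", 1:4),
                                    time_point = "T2", method = "ols",
                                    scale_bw = c(80, 90, 100, 110),
                                    image_bw = c(82, 89, 101, 110)))
  rep <- assemble_tme_report(fm, h2, ag, tme)
  expect_s3_class(rep, "tme_report")
  expect_equal(nrow(rep$fit_metrics), 1)
  expect_equal(nrow(rep$heritability), 1)
  expect_equal(nrow(rep$agreement), 1)
  expect_length(rep$gaps, 0)
  # totals re-derivable from the per-animal rows
  expect_equal(mean(rep$tme$tme),
               mean(abs(tme$scale_bw - tme$image_bw)))
  partial <- assemble_tme_report(fm, NULL, ag, tme)
  expect_equal(partial$gaps, "heritability")
})
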