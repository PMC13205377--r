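test_that("component labelling is 8-connective with deterministic tie-breaks", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE   # diagonal chain
  lab <- label_components(m)
  expect_equal(length(unique(lab[m])), 1)
  m2 <- matrix(FALSE, 5, 9)
  m2[2, 2:3] <- TRUE
  m2[4, 6:7] <- TRUE                          # two equal-size blobs
  lab2 <- label_components(m2)
  expect_equal(sort(unique(lab2[m2])), c(1L, 2L))
  expect_equal(lab2[2, 2], 1L)                # first in scan order labelled 1
})

test_that("the minimum-area rectangle recovers known rectangles", {
  # axis aligned 40 x 20 block
  coords <- as.matrix(expand.grid(row = 21:40, col = 21:60))
  box <- min_area_rect(coords)
  expect_equal(box$lengths, c(40, 20), tolerance = 1e-9)
  # rotated rectangle: opposite sides equal (rectangle invariant)
  th <- 30 * pi / 180
  u <- as.matrix(expand.grid(seq(0, 30, 0.5), seq(0, 10, 0.5)))
  pts <- cbind(row = 50 + u[, 1] * sin(th) + u[, 2] * cos(th),
               col = 50 + u[, 1] * cos(th) - u[, 2] * sin(th))
  b2 <- min_area_rect(pts)
  d <- function(i, j) sqrt(sum((b2$corners[i, ] - b2$corners[j, ])^2))
  expect_equal(d(1, 2), d(3, 4), tolerance = 1e-6)
  expect_equal(d(2, 3), d(4, 1), tolerance = 1e-6)
  expect_equal(b2$lengths[1], 31, tolerance = 1.2)
  expect_equal(b2$lengths[2], 11, tolerance = 1.2)
})

test_that("a slab is segmented to its exact footprint with exact features", {
  fr <- slab_frame()
  seg <- adaptive_hue_threshold(fr)
  truth <- matrix(FALSE, 60, 80)
  truth[21:40, 21:60] <- TRUE
  expect_identical(seg$mask, truth)
  expect_equal(seg$box$lengths, c(40, 20), tolerance = 1)
  feats <- extract_features(seg$mask, fr$distance_map)
  expect_equal(feats$height, 0.40, tolerance = 1e-12)
  expect_equal(feats$volume, 0.40 * sum(truth), tolerance = 1e-9)
})

test_that("zeros inside the mask are replaced by the average distance", {
  fr <- slab_frame()
  seg <- adaptive_hue_threshold(fr)
  d0 <- fr$distance_map
  d1 <- d0
  d1[30, 30] <- 0    # one missing depth reading inside the contour
  f0 <- extract_features(seg$mask, d0)
  f1 <- extract_features(seg$mask, d1)
  expect_equal(f1, f0, tolerance = 1e-12)
  dall <- d0
  dall[seg$mask] <- 0
  expect_error(extract_features(seg$mask, dall), class = "pigtme_no_depth")
})

test_that("a floor-only frame yields no pig", {
  fr <- depth_frame(matrix(1.4, 40, 40))
  expect_error(adaptive_hue_threshold(fr), class = "pigtme_no_pig")
})

test_that("an interior pig is accepted at the initial threshold and foreground grows with it", {
  cfg <- sim_config(seed = 1)
  fr <- render_depth_frame(shape_from_weight(80, cfg$allometry, 0.18), cfg)
  seg <- adaptive_hue_threshold(fr)
  expect_equal(seg$threshold, mean(fr$hue) - 15, tolerance = 1e-9)
  # thresholding monotonicity: higher thresholds never shrink the foreground
  a1 <- sum(fr$hue < seg$threshold)
  a2 <- sum(fr$hue < seg$threshold + 5)
  expect_lte(a1, a2)
})

test_that("threshold escalation recovers the pig when cold border noise dominates at first", {
  # low-contrast scene: a centred disk whose hue gradient straddles the
  # initial threshold, plus a very cold artifact strip on the border that is
  # the largest component at low thresholds; the threshold must escalate
  # until the disk outgrows the strip and its box clears the border
  rows <- 60; cols <- 80
  hue <- matrix(240, rows, cols)
  hue[1:8, 1:75] <- 10                       # border artifact, 600 px
  ctr <- c(30, 45); R <- 20
  rr <- outer(seq_len(rows), rep(1, cols)) - ctr[1]
  cc <- outer(rep(1, rows), seq_len(cols)) - ctr[2]
  rad <- sqrt(rr^2 + cc^2)
  disk <- rad <= R
  # self-consistent hue band [mh - 18, mh - 6] around the frame mean
  for (i in 1:20) {
    mh <- mean(hue)
    hue[disk] <- (mh - 18) + 12 * (rad[disk] / R)
  }
  fr <- depth_frame(hue * 1.4 / 240)
  seg <- adaptive_hue_threshold(fr)
  expect_gt(seg$threshold, mean(fr$hue) - 15 + 0.5)
  rs <- range(which(rowSums(seg$mask) > 0))
  expect_gt(rs[1], 8)                        # the strip is not in the mask
  expect_gt(sum(seg$mask), 600)              # the disk outgrew the strip
})

test_that("segmentation fails cleanly when the object always touches the border", {
  d <- matrix(1.4, 40, 40)
  d[1:39, 15:25] <- 1.0   # column touching the top edge at every threshold
  expect_error(adaptive_hue_threshold(depth_frame(d)),
               class = "pigtme_segmentation_failed")
})

test_that("head/tail trimming is the identity at ratio zero and shortens the long axis", {
  fr <- slab_frame()
  seg <- adaptive_hue_threshold(fr)
  expect_identical(trim_head_tail(seg$mask, seg$box, 0), seg$mask)
  tr <- trim_head_tail(seg$mask, seg$box, 1)
  extent <- function(m) diff(range(which(colSums(m) > 0)))
  expect_lt(extent(tr), extent(seg$mask))
  expect_true(all(tr[seg$mask == FALSE] == FALSE))  # subset of the input
})

test_that("trimming removes protruding head pixels on a rendered frame", {
  cfg <- sim_config(seed = 1)
  shp <- shape_from_weight(80, cfg$allometry, 0.18)
  fr <- render_depth_frame(shp, cfg, head_len = 0.4 * shp$body_width)
  seg <- adaptive_hue_threshold(fr)
  # head pixels: beyond the projected ellipse tip along +col from centre
  M <- cfg$camera_height / (cfg$camera_height -
                              (shp$clearance + shp$body_height / 2))
  tip_col <- (ncol(fr$hue) + 1) / 2 + M * shp$body_length / 2 / cfg$m_per_px
  head_px <- seg$mask & col(seg$mask) > tip_col
  expect_gt(sum(head_px), 0)
  trimmed <- trim_head_tail(seg$mask, seg$box, 1)
  expect_gte(1 - sum(trimmed & head_px) / sum(head_px), 0.90)
})

test_that("video aggregation is the component-wise median and robust to outliers", {
  one <- tibble::tibble(dorsal_length = 100, abdominal_width = 40,
                        height = 0.4, volume = 900)
  expect_equal(aggregate_video(one), one)
  three <- dplyr::bind_rows(
    dplyr::mutate(one, height = 0.3), dplyr::mutate(one, height = 0.4),
    dplyr::mutate(one, height = 0.5))
  expect_equal(aggregate_video(three)$height, 0.4)
  wild <- dplyr::bind_rows(three, dplyr::mutate(one, height = 5, volume = 1e6,
                                                dorsal_length = 1e4))
  agg <- aggregate_video(wild)
  expect_lte(agg$height, 0.5)
  expect_lte(agg$volume, 900)
  expect_error(aggregate_video(one[0, ]), "no frames")
})

test_that("threshold escalation terminates within the 21-step range", {
  # range -15..+5 at 1 degree steps is at most 21 candidate thresholds
  expect_equal(length(seq(-15, 5, by = 1)), 21)
  d <- matrix(1.4, 40, 40)
  d[1:39, 15:25] <- 1.0
  t0 <- Sys.time()
  try(adaptive_hue_threshold(depth_frame(d)), silent = TRUE)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
})
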