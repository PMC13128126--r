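test_that("depth normalization divides by the grand mean", {
  tr <- list(chr1 = c(10, 20, 30))
  expect_equal(unname(normalize_depth(tr)$chr1), c(0.5, 1.0, 1.5))
  const <- list(chr1 = rep(20, 100), chr2 = rep(20, 50))
  norm <- normalize_depth(const)
  expect_true(all(unlist(norm) == 1))
  expect_error(normalize_depth(list(chr1 = rep(0, 10))), "zero mean depth")
  # mean of the normalized track is 1 to numerical precision
  set.seed(2)
  rnd <- list(a = rpois(1e4, 7), b = rpois(5e3, 31))
  expect_equal(mean(unlist(normalize_depth(rnd))), 1, tolerance = 1e-9)
})

test_that("window means use the 1, 1+step grid with a flagged partial tail", {
  w <- window_means(list(chr1 = c(1, 1, 2, 2)), window_bp = 2, step_bp = 2)
  expect_equal(w$mean, c(1, 2))
  expect_false(any(w$partial))
  # window spanning the whole sequence equals the track mean
  w1 <- window_means(list(chr1 = c(3, 5, 7)), 3, 3)
  expect_equal(w1$mean, 5)
  # step 1, window 1 is the identity
  w2 <- window_means(list(chr1 = c(4, 6, 8)), 1, 1)
  expect_equal(w2$mean, c(4, 6, 8))
  # terminal window clipped at the sequence end and flagged
  w3 <- window_means(list(chr1 = 1:5), 3, 2)
  expect_equal(w3$end, c(3, 5, 5))
  expect_equal(w3$partial, c(FALSE, FALSE, TRUE))
  expect_error(window_means(list(a = 1:4), 1, 2), "window_bp >= step_bp")
})

test_that("window labels follow the copy-number threshold rules", {
  mk <- function(m, f) {
    win <- data.table::data.table(seq = "c", start = 1, end = 10,
                                  partial = FALSE)
    classify_windows(cbind(win, mean = m), cbind(win, mean = f))
  }
  expect_equal(mk(0.52, 0.98)$label, "X_like")
  expect_equal(mk(0.48, 0.07)$label, "Y_like")
  expect_equal(mk(1.0, 1.0)$label, "balanced")
  expect_equal(mk(0.75, 1.0)$label, "other")
  # closed interval boundaries
  expect_equal(mk(0.65, 1.15)$label, "X_like")
  expect_equal(mk(0.35, 0.85)$label, "X_like")
  m <- data.table::data.table(seq = "c", start = 1, end = 10, mean = 1,
                              partial = FALSE)
  f <- data.table::data.table(seq = "c", start = 11, end = 20, mean = 1,
                              partial = FALSE)
  expect_error(classify_windows(m, f), "not aligned")
})

test_that("noiseless multiplier tracks recover the region exactly", {
  L <- 1e6; b <- 400001; e <- 800000
  male <- list(chr1 = c(rep(1, b - 1), rep(0.5, e - b + 1), rep(1, L - e)))
  female_x <- list(chr1 = rep(1, L))
  wins <- classify_windows(window_means(male, 150000, 10000),
                           window_means(female_x, 150000, 10000))
  reg <- call_regions(wins, "X_specific", "chr1", c(1, L), male, female_x,
                      refine_window_bp = 20000, refine_step_bp = 1000)
  expect_equal(reg$start, b)
  expect_equal(reg$end, e)
  expect_true(reg$refined)
  # Y-specific flavour with an absent female track
  female_y <- list(chr1 = c(rep(1, b - 1), rep(0, e - b + 1), rep(1, L - e)))
  winsy <- classify_windows(window_means(male, 150000, 10000),
                            window_means(female_y, 150000, 10000))
  regy <- call_regions(winsy, "Y_specific", "chr1", c(1, L), male, female_y,
                       refine_window_bp = 20000, refine_step_bp = 1000)
  expect_equal(regy$start, b)
  expect_equal(regy$end, e)
  # search interval excluding the SDR yields nothing
  out <- call_regions(wins, "X_specific", "chr1", c(1, 200000), male, female_x)
  expect_equal(nrow(out), 0)
})

test_that("region calls are invariant to scaling both raw tracks", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  dp <- simulate_depth_tracks(tr, cfg, "specific")
  call_from <- function(scale) {
    mn <- normalize_depth(lapply(dp$male, function(v) v * scale))
    fn <- normalize_depth(lapply(dp$female, function(v) v * scale))
    wins <- classify_windows(window_means(mn, 15000, 1000),
                             window_means(fn, 15000, 1000))
    call_regions(wins, "Y_specific", "chr2", c(1, 1e6), mn, fn,
                 refine_window_bp = 2000, refine_step_bp = 100,
                 max_gap_bp = 15000)
  }
  expect_equal(call_from(1), call_from(7.3))
})

test_that("feature density is percent coverage of non-N bases", {
  feats <- IRanges::IRanges(start = 11, end = 35)   # 25 bp feature
  d <- feature_density(feats, "chr1", 100, window_bp = 100, step_bp = 100)
  expect_equal(d$density_pct, 25)
  # 20 N bp shrink the denominator: 20 feature bp / 80 non-N = 25%
  d2 <- feature_density(IRanges::IRanges(21, 40), "chr1", 100,
                        n_mask = IRanges::IRanges(1, 20),
                        window_bp = 100, step_bp = 100)
  expect_equal(d2$density_pct, 25)
  # no features
  d3 <- feature_density(IRanges::IRanges(), "chr1", 100,
                        window_bp = 100, step_bp = 100)
  expect_equal(d3$density_pct, 0)
  # overlapping features are merged first: density never exceeds 100
  d4 <- feature_density(IRanges::IRanges(c(1, 1, 50), c(100, 100, 100)),
                        "chr1", 100, window_bp = 50, step_bp = 50)
  expect_true(all(d4$density_pct <= 100))
  # all-N window is undefined
  d5 <- feature_density(IRanges::IRanges(1, 10), "chr1", 100,
                        n_mask = IRanges::IRanges(1, 50),
                        window_bp = 50, step_bp = 50)
  expect_true(is.na(d5$density_pct[1]))
  expect_equal(d5$density_pct[2], 0)
})

test_that("regions annotate spans and contained genes", {
  reg <- list(seq = "chr3", start = 23395001, end = 28209000)
  ann <- annotate_regions(reg)
  expect_equal(ann$span_bp, 4814000)
  genes <- GenomicRanges::GRanges("chr3",
    IRanges::IRanges(c(23400000, 23390000, 28208000),
                     c(23402000, 23392000, 28212000)))
  names(genes) <- c("inside", "before", "straddle")
  ann2 <- annotate_regions(reg, genes)
  expect_true("inside" %in% ann2$genes)
  expect_false("before" %in% ann2$genes)
  # straddling gene covered 1000/5001 < 50%: excluded
  expect_false("straddle" %in% ann2$genes)
  # full containment of a small gene in a large region
  g <- GenomicRanges::GRanges("c", IRanges::IRanges(100, 200))
  names(g) <- "g"
  expect_equal(annotate_regions(list(seq = "c", start = 50, end = 300), g)$genes, "g")
})
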