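test_that("normalization divides by library size and preserves proportionality", {
  tr <- make_const_track(c("a", "b"), c(c1 = 100), depth = 30, library_size = 1e6)
  nt <- normalize_coverage(tr)
  expect_equal(nt$depth$a$c1[1], 3e-5)
  # proportional tracks normalize to identical values
  tr2 <- tr
  tr2$depth$b$c1 <- tr2$depth$b$c1 * 4
  tr2$library_size[["b"]] <- tr2$library_size[["b"]] * 4
  nt2 <- normalize_coverage(tr2)
  expect_equal(nt2$depth$a$c1, nt2$depth$b$c1)
  # all-zero stays all-zero
  tr3 <- tr; tr3$depth$a$c1 <- rep(0, 100)
  expect_true(all(normalize_coverage(tr3)$depth$a$c1 == 0))
  tr4 <- tr; tr4$library_size[["a"]] <- 0
  expect_error(normalize_coverage(tr4), "library_size")
})

test_that("chromosome means exclude zero-depth positions", {
  tr <- make_const_track("s", c(c1 = 3), depth = 1, bin_size = 1)
  tr$depth$s$c1 <- c(2, 0, 4)
  cm <- chromosome_mean_coverage(tr)
  expect_equal(cm$mean, 3)
  expect_equal(cm$n_positions, 2)
  expect_equal(cm$mean_full, 2)
  # uniform depth: mean equals that constant
  tru <- make_const_track("s", c(c1 = 50), depth = 7, bin_size = 1)
  expect_equal(chromosome_mean_coverage(tru)$mean, 7)
  # appending zero-depth positions never changes the covered-only mean
  tr2 <- make_const_track("s", c(c1 = 6), depth = 1, bin_size = 1)
  tr2$depth$s$c1 <- c(2, 0, 4, 0, 0, 0)
  expect_equal(chromosome_mean_coverage(tr2)$mean, 3)
  # a fully uncovered chromosome is undefined-flagged with n = 0
  tr3 <- make_const_track("s", c(c1 = 5), depth = 0, bin_size = 1)
  cm3 <- chromosome_mean_coverage(tr3)
  expect_true(is.na(cm3$mean))
  expect_equal(cm3$n_positions, 0)
})

test_that("sliding-window frames follow the window arithmetic", {
  ww <- make_windows(1e6, 4e5, 2e5)
  expect_equal(ww$start, c(1, 200001, 400001, 600001))
  expect_equal(ww$end, ww$start + 4e5 - 1)
  expect_false(any(ww$partial))
  # chromosome shorter than the window: single truncated window, flagged
  w2 <- make_windows(3e5, 5e5, 1e5)
  expect_equal(nrow(w2), 1)
  expect_true(w2$partial)
  expect_equal(w2$end, 3e5)
})

test_that("sex-difference windows are zero for identical tracks and localize deletions", {
  tr <- make_const_track(c("m", "f"), c(c1 = 4e6), depth = 40, bin_size = 1e4)
  nt <- normalize_coverage(tr)
  sw <- sex_coverage_windows(nt, "m", "f", window = 5e5, step = 1e5)
  expect_true(all(abs(sw$value) < 1e-12))
  # deterministic half-depth male span 1500001..2400000
  tr2 <- tr
  bins <- 151:240
  tr2$depth$m$c1[bins] <- tr2$depth$m$c1[bins] * 0.5
  nt2 <- normalize_coverage(tr2)
  sw2 <- sex_coverage_windows(nt2, "m", "f", window = 5e5, step = 1e5)
  worst <- sw2[which.min(sw2$value), ]
  expect_true(worst$start <= 2.4e6 && worst$end >= 1.5e6 + 1)
  loc <- locate_coverage_deficit(sw2)
  expect_lt(abs(loc$start - 1500001), 1e5)
  expect_lt(abs(loc$end - 2400000), 1e5)
})

test_that("overlapping scan is consistent with disjoint-block means", {
  set.seed(8)
  tr <- make_const_track(c("m", "f"), c(c1 = 1e6), depth = 1, bin_size = 1e4)
  tr$depth$m$c1 <- rgamma(100, 20, rate = 0.5)
  tr$depth$f$c1 <- rgamma(100, 20, rate = 0.5)
  nt <- normalize_coverage(tr)
  sw <- sex_coverage_windows(nt, "m", "f", window = 2e5, step = 2e5)
  for (i in seq_len(nrow(sw))) {
    bins <- ((sw$start[i] - 1) / 1e4 + 1):(sw$end[i] / 1e4)
    manual <- mean(nt$depth$m$c1[bins]) - mean(nt$depth$f$c1[bins])
    expect_equal(sw$value[i], manual, tolerance = 1e-12)
  }
})

test_that("degeneration screen flags male-only low outliers", {
  sheet <- data.frame(sample_id = c("m1", "f1"), species = "sp",
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  chroms <- c(sprintf("a%02d", 1:20), "cand")
  set.seed(5)
  mk <- function(cand_mean) data.frame(
    sample = rep(c("m1", "f1"), each = 21), chrom = rep(chroms, 2),
    mean = c(rnorm(20, 1, 0.01), cand_mean, rnorm(20, 1, 0.01), 1.001),
    stringsAsFactors = FALSE)
  deg <- detect_degeneration(mk(0.55), sheet, "cand", chroms[1:20])
  expect_true(deg$summary$degenerate)
  expect_true(deg$summary$male_significant)
  expect_false(deg$summary$female_significant)
  # candidate equal to the autosome mean: not an outlier
  deg0 <- detect_degeneration(mk(1.0), sheet, "cand", chroms[1:20])
  expect_false(deg0$summary$degenerate)
  expect_gt(min(deg0$per_sample$p), 0.05)
  expect_error(detect_degeneration(mk(0.5), sheet, "cand", chroms[1:3]),
               ">= 4")
})
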