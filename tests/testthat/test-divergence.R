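test_that("depth mask bounds are inclusive and monotone", {
  tr <- make_const_track("s", c(c1 = 5), depth = 1, bin_size = 1)
  tr$depth$s$c1 <- c(19, 20, 200, 201, 50)
  m <- build_site_mask(tr, "s", 20, 200) # strict preset bounds
  expect_equal(mask_sites(m, rep("c1", 5), 1:5), c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(usable_bp(m, "c1", 1, 5), 3)
  loose <- build_site_mask(tr, "s", 10, 500)
  # strict-usable set is a subset of loose-usable
  expect_true(all(!mask_sites(m, rep("c1", 5), 1:5) |
                    mask_sites(loose, rep("c1", 5), 1:5)))
  # vacuous bounds keep every covered position
  all_ok <- build_site_mask(tr, "s", 0, Inf)
  expect_true(all(mask_sites(all_ok, rep("c1", 5), 1:5)))
  expect_error(build_site_mask(tr, "s", 200, 20), "lo < hi")
  expect_equal(mask_preset("strict"), c(20, 200))
  expect_equal(mask_preset("loose"), c(10, 500))
  # joint gating over several samples
  tr2 <- make_const_track(c("a", "b"), c(c1 = 3), depth = 1, bin_size = 1)
  tr2$depth$a$c1 <- c(50, 15, 50)
  tr2$depth$b$c1 <- c(50, 50, 15)
  m2 <- build_site_mask(tr2, c("a", "b"), 20, 200)
  expect_equal(mask_sites(m2, rep("c1", 3), 1:3), c(TRUE, FALSE, FALSE))
})

test_that("genome SNP rate counts hom as 1 and het as 0.5", {
  tr <- make_const_track("s", c(c1 = 10000), depth = 50, bin_size = 100)
  m <- build_site_mask(tr, "s", 20, 200)
  codes <- matrix(c(rep(2L, 10), rep(1L, 4)), ncol = 1)
  gm <- make_gm(codes, chrom = "c1", pos = seq_len(14) * 3L, samples = "s")
  r <- genome_snp_rate(gm, "s", m)
  expect_equal(r$rate, (10 + 0.5 * 4) / 10000)
  # identical to reference: rate 0; all hom-alt at every usable site: rate 1
  gm0 <- make_gm(matrix(0L, 5, 1), chrom = "c1", samples = "s")
  expect_equal(genome_snp_rate(gm0, "s", m)$rate, 0)
  tr1 <- make_const_track("s", c(c1 = 6), depth = 50, bin_size = 1)
  m1 <- build_site_mask(tr1, "s", 20, 200)
  gm1 <- make_gm(matrix(2L, 6, 1), chrom = "c1", pos = 1:6, samples = "s")
  expect_equal(genome_snp_rate(gm1, "s", m1)$rate, 1)
})

test_that("heterozygosity windows divide het counts by usable bp", {
  tr <- make_const_track("s", c(c1 = 10000), depth = 50, bin_size = 100)
  m <- build_site_mask(tr, "s", 20, 200)
  set.seed(4)
  pos <- sort(sample.int(10000, 25))
  gm <- make_gm(matrix(1L, 25, 1), chrom = "c1", pos = pos, samples = "s")
  hw <- het_windows(gm, "s", m, window = 10000, step = 10000)
  expect_equal(hw$value, 25 / 10000)
  # no het calls anywhere: all-zero
  gm0 <- make_gm(matrix(2L, 25, 1), chrom = "c1", pos = pos, samples = "s")
  expect_true(all(het_windows(gm0, "s", m, 10000, 10000)$value == 0))
  # tiling windows reconstruct the chromosome-level value
  hw2 <- het_windows(gm, "s", m, window = 2000, step = 2000)
  agg <- sum(hw2$value * hw2$n_informative) / sum(hw2$n_informative)
  expect_equal(agg, chromosome_het_proportion(gm, "s", m)$value)
})

test_that("X/Y SNP classification follows the diagnostic patterns", {
  # columns: 5 focal males, 5 focal females, 5 other females
  roles <- list(focal_males = sprintf("fm%d", 1:5),
                focal_females = sprintf("ff%d", 1:5),
                other_females = sprintf("of%d", 1:5))
  samples <- unlist(roles)
  row_of <- function(fm, ff, of) c(rep(fm, 5), rep(ff, 5), rep(of, 5))
  codes <- rbind(
    row_of(1L, 2L, 0L),  # X-specific (focal females fixed for the alt allele)
    row_of(1L, 0L, 0L),  # Y-specific (alt only on the focal Y)
    row_of(2L, 2L, 0L),  # shared by focal X and Y
    row_of(0L, 0L, 0L),  # invariant: unclassified
    row_of(1L, 2L, 2L),  # both female groups share one hom allele, males het: Y pattern
    c(1L, 1L, 1L, 1L, 0L, rep(2L, 5), rep(0L, 5)), # one male not het
    row_of(1L, 0L, 2L))  # X pattern with swapped allele labels
  gm <- make_gm(codes, samples = samples)
  cls <- classify_xy_snps(gm, roles)
  expect_equal(as.character(cls),
               c("X_specific", "Y_specific", "shared", "unclassified",
                 "Y_specific", "unclassified", "X_specific"))
  # allele-swapped X pattern (focal females hom-ref, others hom-alt)
  gm2 <- make_gm(rbind(row_of(1L, 0L, 2L)), samples = samples)
  expect_equal(as.character(classify_xy_snps(gm2, roles)), "X_specific")
  # any missing role genotype makes the site unclassified
  cm <- row_of(1L, 2L, 0L); cm[12] <- NA
  gm3 <- make_gm(rbind(cm), samples = samples)
  expect_equal(as.character(classify_xy_snps(gm3, roles)), "unclassified")
  # category conservation: counts always partition the sites
  expect_equal(sum(attr(cls, "counts")), length(cls))
})

test_that("species site classes separate fixed differences from polymorphism", {
  fa <- sprintf("a%d", 1:5); fb <- sprintf("b%d", 1:5)
  gm <- make_gm(rbind(
    c(rep(2L, 5), rep(0L, 5)),            # fixed difference
    c(1L, rep(2L, 4), rep(0L, 5)),        # polymorphic in A, not fixed
    c(rep(0L, 10)),                       # invariant
    c(rep(2L, 5), c(0L, 0L, 0L, 0L, 2L)), # polymorphic in B
    c(rep(0L, 5), rep(1L, 5))),           # all B het: polymorphic B
    samples = c(fa, fb))
  sc <- classify_species_sites(gm, fa, fb)
  expect_equal(sc$fixed_diff, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(sc$polymorphic_a, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sc$polymorphic_b, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # fixed_diff implies neither polymorphism flag
  expect_false(any(sc$fixed_diff & (sc$polymorphic_a | sc$polymorphic_b)))
})

test_that("fusion gradient fits decline and flags degenerate structure", {
  tr <- make_const_track("s", c(neo = 2e6), depth = 50, bin_size = 1e4)
  m <- build_site_mask(tr, "s", 20, 200)
  set.seed(12)
  # exponential decay from the fusion end at position 1
  starts <- seq(1, 2e6, by = 1000)
  p <- 0.01 * exp(-(starts + 500) / 5e5)
  cnt <- rbinom(length(starts), 1000, p)
  het_pos <- unlist(lapply(which(cnt > 0), function(i) starts[i] + sample.int(1000, cnt[i]) - 1))
  fit <- fusion_gradient("neo", het_pos, m, fusion_end = 1)
  expect_lt(fit$beta, 0)
  expect_lt(abs(fit$beta - (-1 / 5e5)) / fit$se_beta, 4)
  # uniform probability: slope not significant
  cnt0 <- rbinom(length(starts), 1000, 0.005)
  het0 <- unlist(lapply(which(cnt0 > 0), function(i) starts[i] + sample.int(1000, cnt0[i]) - 1))
  fit0 <- fusion_gradient("neo", het0, m, fusion_end = 1)
  expect_gt(fit0$p_beta, 0.01)
  # all het in the first bin only: separation flagged
  fit_sep <- fusion_gradient("neo", rep(1:500, 2)[1:600], m, fusion_end = 1)
  expect_true(fit_sep$separated)
})
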