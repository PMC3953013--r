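test_that("datasets are deterministic under the seed and differ across seeds", {
  ds1 <- tiny_dataset(seed = 11)
  ds2 <- tiny_dataset(seed = 11)
  ds3 <- tiny_dataset(seed = 12)
  expect_identical(ds1$gm$sites, ds2$gm$sites)
  expect_identical(ds1$gm$geno, ds2$gm$geno)
  expect_identical(ds1$coverage$depth$FM1$chrA01, ds2$coverage$depth$FM1$chrA01)
  expect_false(identical(ds1$gm$sites, ds3$gm$sites))
  # byte-identical files too
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(ds1, d1, reference = FALSE)
  write_dataset(ds2, d2, reference = FALSE)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
})

test_that("every variant site carries exactly one truth label and loads cleanly", {
  ds <- tiny_dataset()
  expect_equal(nrow(ds$truth), nrow(ds$gm$sites))
  expect_false(any(is.na(ds$truth$truth)))
  expect_false(anyDuplicated(paste(ds$gm$sites$chrom, ds$gm$sites$pos)) > 0)
  # emitted files pass the readers without warnings
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_no_warning(gm <- read_genotypes(file.path(dir, "genotypes.vcf"),
                                         ds$sample_sheet))
  expect_no_warning(read_gene_models(file.path(dir, "genes.gff3"),
                                     file.path(dir, "reference.fa")))
  expect_no_warning(read_coverage(file.path(dir, "coverage"), ds$sample_sheet))
  expect_identical(gm$geno, ds$gm$geno)
})

test_that("neo-sex heterozygosity matches the analytic decay expectation", {
  cfg <- sim_config(n_autosomes = 1, autosome_length = 1e5,
                    anc_sex = list(length = 1e5, xy_het_rate = 0,
                                   deleted_span = c(2e4, 5e4)),
                    neo_sex = list(length = 5e6, p_max = 0.01, decay_scale = 5e6),
                    species = list(fixed_diff_rate = 0, polymorphism_rate = 0,
                                   outgroup_divergence_rate = 0),
                    genes = list(per_chrom = 0), seed = 31)
  ds <- simulate_dataset(cfg)
  first_mb <- ds$gm$sites$chrom == "chrNeoSex" & ds$gm$sites$pos <= 1e6
  observed <- sum(first_mb) / 1e6
  # analytic mean of p_max * exp(-d/scale) over the first Mb
  expected <- 0.01 * 5e6 / 1e6 * (1 - exp(-1e6 / 5e6))
  se <- sqrt(expected / 1e6)
  expect_lt(abs(observed - expected), 3 * se)
  # every divergent site is heterozygous in all focal males, absent elsewhere
  roles <- roles_of(ds)
  neo <- ds$gm$sites$chrom == "chrNeoSex"
  fm <- ds$gm$geno[neo, roles$focal_males, drop = FALSE]
  expect_true(all(fm == 1L))
  of <- ds$gm$geno[neo, roles$other_females, drop = FALSE]
  expect_true(all(of == 0L))
})

test_that("male depth over the deleted span is halved relative to females", {
  ds <- tiny_dataset()
  del <- ds$deleted_span
  bs <- ds$coverage$bin_size
  bins <- (del[1] %/% bs + 1):(del[2] %/% bs)
  m <- ds$coverage$depth$FM1$chrAncSex[bins]
  f <- ds$coverage$depth$FF1$chrAncSex[bins]
  ratio <- mean(m[m > 0]) / mean(f[f > 0])
  # normalize out the samples' library-size difference using autosome depth
  auto_ratio <- mean(ds$coverage$depth$FM1$chrA01) / mean(ds$coverage$depth$FF1$chrA01)
  adj <- ratio / auto_ratio
  se <- 0.5 / sqrt(length(bins) * 20) * 3 # gamma shape 20 per bin
  expect_lt(abs(adj - 0.5), 3 * se + 0.05)
})

test_that("coding divergence simulation respects branch classes and boundaries", {
  # omega 0 on a branch: all its substitutions synonymous
  sim <- simulate_coding_divergence(200, c(focal = 0, sister = 0, ancestral = 0),
                                    ks = 0.1, seed = 2)
  k <- ng86_kaks(sim$focal, sim$ancestral)
  expect_equal(k$Nd, 0)
  expect_gt(k$Sd, 0)
  # zero substitutions: three identical sequences
  sim0 <- simulate_coding_divergence(100, c(focal = 0.5, sister = 0.5,
                                            ancestral = 0.5), ks = 0, seed = 3)
  expect_identical(sim0$focal, sim0$sister)
  expect_identical(sim0$focal, sim0$outgroup)
  # no stop codons are ever created
  sim2 <- simulate_coding_divergence(150, ks = 0.2, seed = 4)
  for (s in c(sim2$focal, sim2$sister, sim2$outgroup)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  }
  # determinism
  expect_identical(simulate_coding_divergence(100, ks = 0.05, seed = 9)$focal,
                   simulate_coding_divergence(100, ks = 0.05, seed = 9)$focal)
})

test_that("pairwise estimator recovers the simulated omega", {
  set.seed(60)
  est <- replicate(60, {
    sim <- simulate_coding_divergence(400, c(focal = 0.5, sister = 0.5,
                                             ancestral = 0.1), ks = 0.04)
    ng86_kaks(sim$focal, sim$sister)$ka_ks
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.5), 0.1)
})

test_that("random ORFs are valid coding sequences", {
  for (s in 1:5) {
    orf <- random_orf(50, seed = s)
    expect_equal(nchar(orf), 150)
    expect_equal(substr(orf, 1, 3), "ATG")
    aa <- codon_aa(substring(orf, seq(1, 148, 3), seq(3, 150, 3)))
    expect_false(any(aa == "*"))
  }
})

test_that("expression study simulator plants the configured bias fractions", {
  chroms <- c("a1", "a2", "a3", "cand")
  sim <- simulate_expression_study(chroms, genes_per_chrom = 500,
                                   biased_fraction = c(a1 = 0.05, a2 = 0.05,
                                                       a3 = 0.05, cand = 0.3),
                                   seed = 5)
  rate_cand <- mean(sim$truth_biased[sim$gene_chrom == "cand"])
  rate_auto <- mean(sim$truth_biased[sim$gene_chrom != "cand"])
  expect_lt(abs(rate_cand - 0.3), 3 * sqrt(0.3 * 0.7 / 500))
  expect_lt(abs(rate_auto - 0.05), 3 * sqrt(0.05 * 0.95 / 1500))
})
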