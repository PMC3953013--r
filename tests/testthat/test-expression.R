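test_that("expression normalization follows the three literal steps", {
  # 75th percentile of {10, 20, 30, 40} with linear interpolation is 32.5
  expect_equal(unname(stats::quantile(c(10, 20, 30, 40), 0.75, type = 7)), 32.5)
  mat <- rbind(p1 = c(10, 20, 30, 40),
               p2 = c(100, 90, 110, 120),
               p3 = c(5, 4, 6, 7))
  nm <- normalize_expression(mat)
  # step 1+2 by hand for the kept probes
  p75 <- apply(mat, 2, stats::quantile, 0.75, type = 7)
  lg <- log2(sweep(mat, 2, p75, "/"))
  med <- apply(lg, 1, stats::median)
  keep <- abs(med) >= 0.05
  expect_identical(rownames(nm$mat), rownames(mat)[keep])
  expect_equal(nm$mat, sweep(lg[keep, ], 1, med[keep], "/"))
  # scale invariance of step 1: doubling one array changes nothing
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 2
  nm2 <- normalize_expression(mat2)
  expect_equal(nm2$mat, nm$mat)
  # a probe with identical scaled values (away from log 0) normalizes to all 1
  s <- c(1, 2, 0.5, 3) # per-array scale factors cancel in step 1
  mat3 <- rbind(const = 2 * s, p2 = 100 * s)
  nm3 <- normalize_expression(mat3)
  expect_true(all(abs(nm3$mat["const", ] - 1) < 1e-12))
  # values below the floor are raised and counted
  mat4 <- mat; mat4[1, 1] <- 0
  expect_gt(normalize_expression(mat4)$n_floored, 0)
})

test_that("row-wise ANOVA matches stats::oneway.test exactly", {
  set.seed(14)
  for (k in 2:3) {
    groups <- factor(rep(seq_len(k), each = 4))
    mat <- matrix(rnorm(30 * 4 * k), 30)
    av <- neosexscan:::row_anova(mat, groups)
    for (i in c(1, 7, 30)) {
      ow <- stats::oneway.test(mat[i, ] ~ groups, var.equal = TRUE)
      expect_equal(unname(av$F[i]), unname(ow$statistic), tolerance = 1e-10)
      expect_equal(unname(av$p[i]), ow$p.value, tolerance = 1e-10)
    }
  }
})

test_that("biased-gene calling is calibrated under the null and powered with signal", {
  set.seed(15)
  groups <- factor(rep(c("m", "f"), each = 4))
  null_mat <- matrix(rnorm(8 * 10000), 10000)
  calls <- call_biased_genes(null_mat, groups, alpha = 0.01)
  fp <- mean(calls$flagged)
  expect_lt(abs(fp - 0.01), 3 * sqrt(0.01 * 0.99 / 10000) + 0.002)
  # 10-SD separation: essentially always flagged, with the right direction
  eff <- matrix(rnorm(8 * 200), 200)
  eff[, groups == "m"] <- eff[, groups == "m"] + 10
  ce <- call_biased_genes(eff, groups, alpha = 0.01)
  expect_gt(mean(ce$flagged), 0.99)
  expect_true(all(ce$direction[ce$flagged] == "m"))
  # alpha = 0 flags nothing
  expect_equal(sum(call_biased_genes(eff, groups, alpha = 0)$flagged), 0)
  # zero within-group variance is degenerate, not flagged
  dg <- rbind(rep(c(1, 2), each = 4))
  cd <- call_biased_genes(dg, groups)
  expect_true(cd$degenerate)
  expect_false(cd$flagged)
})

test_that("tissue specificity is presence-in-gonad and absence-in-brain", {
  pres <- cbind(testis = c(TRUE, TRUE, FALSE, FALSE),
                ovary = c(FALSE, TRUE, TRUE, FALSE),
                brain = c(FALSE, TRUE, FALSE, FALSE))
  rownames(pres) <- sprintf("g%d", 1:4)
  ts <- tissue_specific_genes(pres)
  expect_equal(ts$testis_specific, "g1")
  expect_equal(ts$ovary_specific, "g3")
  # random independent presence matches the analytic expectation
  set.seed(16)
  n <- 4000
  pres2 <- cbind(testis = runif(n) < 0.4, ovary = runif(n) < 0.3,
                 brain = runif(n) < 0.5)
  rownames(pres2) <- sprintf("g%d", seq_len(n))
  ts2 <- tissue_specific_genes(pres2)
  expected <- 0.4 * 0.5 * n
  expect_lt(abs(length(ts2$testis_specific) - expected),
            3 * sqrt(n * 0.2 * 0.8))
  # presence calls separate signal from background
  bg <- rnorm(20, 1, 0.2)
  sig <- rbind(high = rnorm(4, 10, 0.2), low = rnorm(4, 1, 0.2))
  pc <- presence_calls(sig, bg)
  expect_true(pc["high"])
  expect_false(pc["low"])
})

test_that("chromosome enrichment detects a planted biased chromosome", {
  set.seed(17)
  sim <- simulate_expression_study(c(sprintf("a%02d", 1:20), "cand"),
                                   genes_per_chrom = 300,
                                   biased_fraction = stats::setNames(
                                     c(rep(0.05, 20), 0.15), c(sprintf("a%02d", 1:20), "cand")),
                                   effect = 3, seed = 17)
  calls <- call_biased_genes(sim$mat, sim$groups, alpha = 0.01)
  flags <- stats::setNames(calls$flagged, calls$gene)
  enr <- chromosome_enrichment(flags, sim$gene_chrom, "cand", sprintf("a%02d", 1:20))
  expect_true(enr$per_candidate$significant)
  expect_equal(enr$per_candidate$direction, 1)
  expect_true("cand" %in% enr$outlier_scan$label)
  # uniform bias: candidate not significant
  sim0 <- simulate_expression_study(c(sprintf("a%02d", 1:20), "cand"),
                                    genes_per_chrom = 300, biased_fraction = 0.05,
                                    effect = 3, seed = 18)
  calls0 <- call_biased_genes(sim0$mat, sim0$groups, alpha = 0.01)
  enr0 <- chromosome_enrichment(stats::setNames(calls0$flagged, calls0$gene),
                                sim0$gene_chrom, "cand", sprintf("a%02d", 1:20))
  expect_false(enr0$per_candidate$significant)
  # chromosomes below the gene floor are excluded with a warning
  gc2 <- sim$gene_chrom
  gc2[seq_len(295)] <- "tiny" # leaves a01 with 5 genes
  expect_warning(chromosome_enrichment(flags, gc2, "cand",
                                       c(sprintf("a%02d", 2:20))),
                 "excluded")
})

test_that("cis-heterozygosity correlation counts strand-aware upstream windows", {
  gm <- make_gm(matrix(1L, 6, 1), chrom = "neo",
                pos = c(500L, 800L, 900L, 20500L, 21000L, 40000L), samples = "m")
  gene_pos <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "neo",
                         tss = c(1000L, 20000L, 45000L),
                         strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  # gA (+): [tss-10k, tss) holds 3 het sites; gB (-): (tss, tss+10k] holds 2;
  # gC (+): [35k, 45k) holds 1
  eff <- c(gA = 6, gB = 4, gC = 2)
  ct <- cis_het_correlation(eff, gm, "m", gene_pos, "neo", upstream_bp = 10000)
  expect_equal(ct$r, 1) # effects constructed proportional to the counts
  # constant counts are undefined-flagged
  eff2 <- c(gA = 1, gB = 5, gC = 2)
  gm2 <- make_gm(matrix(1L, 3, 1), chrom = "neo",
                 pos = c(500L, 20500L, 40000L), samples = "m")
  ct2 <- cis_het_correlation(eff2, gm2, "m", gene_pos, "neo", upstream_bp = 10000)
  expect_false(ct2$defined)
})
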