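test_that("synonymous site counts follow the standard code with stops as nonsynonymous", {
  s <- codon_syn_sites()
  expect_equal(unname(s["GGT"]), 1)       # 4-fold third position
  expect_equal(unname(s["TTT"]), 1 / 3)   # TTC only
  expect_equal(unname(s["ATG"]), 0)       # Met: no synonymous change
  expect_equal(unname(s["TGG"]), 0)       # Trp
  expect_true(all(is.na(s[c("TAA", "TAG", "TGA")])))
  sense <- names(s)[!is.na(s)]
  expect_length(sense, 61)
  expect_true(all(s[sense] >= 0 & s[sense] <= 3))
})

test_that("ng86_kaks reproduces hand-computed counts and is symmetric", {
  a <- paste0("TTT", strrep("GGT", 9))
  b <- paste0("TTC", strrep("GGT", 9))
  k <- ng86_kaks(a, b)
  expect_equal(k$Sd, 1)
  expect_equal(k$Nd, 0)
  expect_equal(k$pS, 3 / 28)
  expect_equal(k$Ks, -3 / 4 * log(1 - 4 * (3 / 28) / 3))
  expect_equal(k$Ka, 0)
  expect_equal(k$N + k$S, 3 * k$n_codons)
  # identity: everything 0, ratio undefined
  ki <- ng86_kaks(a, a)
  expect_equal(ki$Nd + ki$Sd, 0)
  expect_false(ki$ratio_defined)
  # two-difference codon averaged over both valid pathways
  k2 <- ng86_kaks("AAA", "AGG")
  expect_equal(k2$Nd, 1)
  expect_equal(k2$Sd, 1)
  # symmetry is exact
  set.seed(3)
  x <- random_orf(30); y <- random_orf(30)
  kx <- ng86_kaks(x, y); ky <- ng86_kaks(y, x)
  expect_identical(c(kx$Nd, kx$Sd, kx$N, kx$S), c(ky$Nd, ky$Sd, ky$N, ky$S))
  # codons containing ambiguity are skipped pairwise
  ks <- ng86_kaks("ATGNNNGGT", "ATGAAAGGT")
  expect_equal(ks$n_skipped, 1)
  expect_equal(ks$n_codons, 2)
})

test_that("pathway-averaged pair counts match exhaustive enumeration on random codon pairs", {
  pair <- codon_pair_counts()
  sense <- names(codon_syn_sites())[!is.na(codon_syn_sites())]
  set.seed(9)
  for (i in 1:150) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    oc <- oracle_pair_counts(a, b)
    if (is.null(oc)) next
    expect_equal(unname(pair$nd[a, b]), unname(oc["nd"]), tolerance = 1e-12)
    expect_equal(unname(pair$sd[a, b]), unname(oc["sd"]), tolerance = 1e-12)
  }
})

test_that("virtual haplotypes assign het alleles fairly and deterministically", {
  gene <- list(gene_id = "g", chrom = "c", strand = "+",
               cds = data.frame(start = 1, end = 12),
               cds_seq = "ATGAAAGGTTTT")
  # no variants: two identical reference CDS
  gm0 <- make_gm(matrix(integer(0), 0, 1), chrom = "c")
  hp0 <- build_virtual_haplotypes(gm0, "S1", gene)
  expect_identical(hp0$hap1, gene$cds_seq)
  expect_identical(hp0$hap2, gene$cds_seq)
  # one het site: pair differs exactly there, alt on exactly one haplotype
  gm1 <- make_gm(matrix(1L, 1, 1), chrom = "c", pos = 6L, ref = "A", alt = "G")
  hp1 <- build_virtual_haplotypes(gm1, "S1", gene, seed = 5)
  expect_equal(sum(substr(hp1$hap1, 6, 6) == "G", substr(hp1$hap2, 6, 6) == "G"), 1)
  expect_identical(build_virtual_haplotypes(gm1, "S1", gene, seed = 5)$hap1, hp1$hap1)
  # hom-alt goes into both haplotypes
  gm2 <- make_gm(matrix(2L, 1, 1), chrom = "c", pos = 6L, ref = "A", alt = "G")
  hp2 <- build_virtual_haplotypes(gm2, "S1", gene)
  expect_equal(substr(hp2$hap1, 6, 6), "G")
  expect_equal(substr(hp2$hap2, 6, 6), "G")
  # across seeds, the alt lands on haplotype 1 with frequency ~ 1/2
  hits <- vapply(1:400, function(s)
    substr(build_virtual_haplotypes(gm1, "S1", gene, seed = s)$hap1, 6, 6) == "G",
    logical(1))
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 400))
  # ref mismatch excludes the gene with a warning
  gm3 <- make_gm(matrix(1L, 1, 1), chrom = "c", pos = 6L, ref = "C", alt = "G")
  expect_warning(out <- build_virtual_haplotypes(gm3, "S1", gene), "mismatch")
  expect_null(out)
})

test_that("minus-strand genes complement alleles when substituting", {
  # gene on minus strand: genomic 1..9, CDS = revcomp(genomic)
  genomic <- "CATTTTCAT" # revcomp = ATGAAAATG
  gene <- list(gene_id = "g", chrom = "c", strand = "-",
               cds = data.frame(start = 1, end = 9),
               cds_seq = revcomp(genomic))
  # genomic hom-alt T>C at pos 5 -> CDS position 5 (A) becomes G
  gm <- make_gm(matrix(2L, 1, 1), chrom = "c", pos = 5L, ref = "T", alt = "C")
  hp <- build_virtual_haplotypes(gm, "S1", gene)
  expect_equal(substr(hp$hap1, 5, 5), "G")
})

test_that("consensus haploid is always one of the two virtual haplotypes", {
  gene <- list(gene_id = "g", chrom = "c", strand = "+",
               cds = data.frame(start = 1, end = 15),
               cds_seq = "ATGAAAGGTTTTCCC")
  gm <- make_gm(matrix(c(1L, 2L, 1L), 3, 1), chrom = "c", pos = c(6L, 9L, 13L),
                ref = c("A", "T", "C"), alt = c("G", "A", "T"))
  for (s in 1:20) {
    cons <- consensus_haploid(gm, "S1", gene, seed = s)
    hp <- build_virtual_haplotypes(gm, "S1", gene, seed = s)
    expect_true(cons %in% c(hp$hap1, hp$hap2))
  }
  # no het sites: deterministic regardless of seed
  gmh <- make_gm(matrix(2L, 1, 1), chrom = "c", pos = 6L, ref = "A", alt = "G")
  expect_identical(consensus_haploid(gmh, "S1", gene, seed = 1),
                   consensus_haploid(gmh, "S1", gene, seed = 999))
  # balanced allele choice at a het site
  gm1 <- make_gm(matrix(1L, 1, 1), chrom = "c", pos = 6L, ref = "A", alt = "G")
  picks <- vapply(1:400, function(s)
    substr(consensus_haploid(gm1, "S1", gene, seed = s), 6, 6) == "G", logical(1))
  expect_lt(abs(mean(picks) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("branch-specific omega assigns substitutions by parsimony", {
  # identical sequences: no substitutions, both omegas undefined
  anc <- "ATGAAAGGTTTTCCC"
  bo0 <- branch_specific_omega(anc, anc, anc)
  expect_false(bo0$omega1_defined)
  expect_false(bo0$omega0_defined)
  # focal has one nonsynonymous (AAA->AGA) and one synonymous (GGT->GGC)
  focal <- "ATGAGAGGCTTTCCC"
  bo <- branch_specific_omega(focal, anc, anc)
  expect_equal(bo$Nd1, 1)
  expect_equal(bo$Sd1, 1)
  expect_equal(bo$omega1, (1 / bo$N) / (1 / bo$S))
  expect_false(bo$omega0_defined)
  # outgroup odd: change goes to the background branch
  outg <- "ATGAAAGGTTTTCCG" # CCC->CCG synonymous on the outgroup lineage
  bo2 <- branch_specific_omega(anc, anc, outg)
  expect_equal(bo2$Sd0, 1)
  expect_equal(bo2$Nd1 + bo2$Sd1, 0)
  # sister odd is background too
  bo3 <- branch_specific_omega(anc, focal, anc)
  expect_equal(bo3$Nd0, 1)
  expect_equal(bo3$Sd0, 1)
  # three-allele codon positions are excluded and counted
  f <- "ATGAAA"; s <- "ATGACA"; o <- "ATGAGA"
  bo4 <- branch_specific_omega(f, s, o)
  expect_equal(bo4$n_excluded, 1)
  expect_equal(bo4$n_codons, 1)
})

test_that("SNP effects are annotated strand-aware from gene models", {
  genes <- list(
    g1 = list(gene_id = "g1", chrom = "c", strand = "+",
              cds = data.frame(start = 11, end = 19),
              cds_seq = "ATGGGTAAA"))
  sites <- data.frame(chrom = c("c", "c", "c", "c"),
                      pos = c(16L, 12L, 5L, 17L),
                      ref = c("T", "T", "A", "A"),
                      alt = c("C", "A", "G", "G"),
                      stringsAsFactors = FALSE)
  eff <- annotate_snp_effect(sites, genes)
  expect_equal(eff, c("synonymous",     # GGT -> GGC at 3rd codon position
                      "nonsynonymous",  # ATG -> AAG start disruption
                      "noncoding",      # outside the CDS
                      "nonsynonymous")) # AAA -> GAA
  # minus-strand gene: genomic ref/alt are complemented into CDS space
  genes_m <- list(
    gm = list(gene_id = "gm", chrom = "c", strand = "-",
              cds = data.frame(start = 1, end = 9),
              cds_seq = revcomp("CACTTTCAT"))) # CDS ATGAAAGTG
  s2 <- data.frame(chrom = "c", pos = 3L, ref = "C", alt = "T",
                   stringsAsFactors = FALSE)  # CDS pos 7: GTG -> ATG, nonsyn
  expect_equal(annotate_snp_effect(s2, genes_m), "nonsynonymous")
})

test_that("per-category nonsynonymous fractions flag empty categories", {
  nsf <- nonsyn_fraction_by_category(
    c("a", "a", "a", "b"),
    c("nonsynonymous", "synonymous", "synonymous", "noncoding"))
  expect_equal(nsf$nonsyn_fraction[nsf$category == "a"], 1 / 3)
  expect_true(is.na(nsf$nonsyn_fraction[nsf$category == "b"]))
})
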