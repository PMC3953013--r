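#' Pairwise Ka/Ks by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' coordinate-matched coding sequences by the NG86 method: per-codon
#' synonymous site fractions from the standard genetic code, pathway
#' averaging for codons differing at more than one position (pathways
#' through stop codons excluded), and Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)} of the proportions pN = Nd/N and
#' pS = Sd/S. Codon pairs containing ambiguity characters or a stop codon
#' are skipped pairwise and counted. The result is symmetric in its
#' arguments.
#'
#' @param cds_a,cds_b equal-length coding sequences (character strings,
#'   length divisible by 3).
#' @return object of class `kaks_result`: list with `Ka`, `Ks`, `ka_ks`,
#'   raw counts `Nd`, `Sd`, site totals `N`, `S`, `n_codons` (compared),
#'   `n_skipped`, and flags `ka_defined`, `ks_defined`, `ratio_defined`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  cds_a <- toupper(as.character(cds_a))
  cds_b <- toupper(as.character(cds_b))
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must have equal length")
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  syn <- codon_syn_sites()
  pair <- codon_pair_counts()
  codons <- names(syn)
  ok <- cod_a %in% codons & cod_b %in% codons &
    !is.na(syn[cod_a]) & !is.na(syn[cod_b])
  n_skipped <- sum(!ok)
  cod_a <- cod_a[ok]; cod_b <- cod_b[ok]
  n_cod <- length(cod_a)
  if (n_cod == 0) stop("no comparable codons")
  S_a <- sum(syn[cod_a]); S_b <- sum(syn[cod_b])
  S <- (S_a + S_b) / 2
  N <- 3 * n_cod - S
  idx <- cbind(match(cod_a, codons), match(cod_b, codons))
  Nd <- sum(pair$nd[idx])
  Sd <- sum(pair$sd[idx])
  pN <- Nd / N
  pS <- Sd / S
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  Ka <- jc(pN); Ks <- jc(pS)
  ka_def <- !is.na(Ka); ks_def <- !is.na(Ks)
  ratio_def <- ka_def && ks_def && Ks > 0
  structure(list(Ka = Ka, Ks = Ks,
                 ka_ks = if (ratio_def) Ka / Ks else NA_real_,
                 Nd = Nd, Sd = Sd, N = N, S = S,
                 pN = pN, pS = pS,
                 n_codons = n_cod, n_skipped = n_skipped,
                 ka_defined = ka_def, ks_defined = ks_def,
                 ratio_defined = ratio_def,
                 method = "NG86 + Jukes-Cantor"),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("NG86 Ka/Ks\n")
  cat(sprintf("  Nd = %.3f over N = %.2f nonsynonymous sites (pN = %.5f)\n", x$Nd, x$N, x$pN))
  cat(sprintf("  Sd = %.3f over S = %.2f synonymous sites (pS = %.5f)\n", x$Sd, x$S, x$pS))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s\n",
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              if (x$ratio_defined) format(x$ka_ks, digits = 4) else "undefined"))
  if (x$n_skipped > 0) cat(sprintf("  (%d codon pairs skipped)\n", x$n_skipped))
  invisible(x)
}

# Map genomic positions of variant sites onto CDS coordinates of one gene.
# Returns data.frame(site_row, cds_pos) for sites landing in the CDS, with
# alleles complemented for minus-strand genes handled by the caller.
.gene_site_map <- function(gm, gene) {
  on_chrom <- which(gm$sites$chrom == gene$chrom)
  if (length(on_chrom) == 0) return(data.frame(site_row = integer(0), cds_pos = integer(0)))
  pos <- gm$sites$pos[on_chrom]
  cds_positions <- unlist(Map(seq.int, gene$cds$start, gene$cds$end))
  cds_positions <- sort(cds_positions)
  if (identical(gene$strand, "-")) cds_positions <- rev(cds_positions)
  hit <- match(pos, cds_positions)
  keep <- !is.na(hit)
  data.frame(site_row = on_chrom[keep], cds_pos = hit[keep])
}

# substitute single bases into a CDS string (strand-aware alleles already resolved)
.substitute_bases <- function(seq, cds_pos, base) {
  for (i in seq_along(cds_pos)) substr(seq, cds_pos[i], cds_pos[i]) <- base[i]
  seq
}

#' Virtual haplotype pair for one gene of one individual
#'
#' Builds two haploid coding sequences from a diploid genotype set:
#' homozygous-alt sites are substituted into both haplotypes; each
#' heterozygous site's alt allele is assigned to haplotype 1 or 2 with
#' probability 1/2, independently per site, deterministically under `seed`.
#' Missing genotypes are treated as reference and counted. A site whose
#' reference allele does not match the gene's CDS sequence excludes the
#' gene (returns NULL with a warning).
#'
#' @param gm genotype matrix (see [read_genotypes()]).
#' @param sample sample id.
#' @param gene one gene model (element of [read_gene_models()] output).
#' @param seed integer seed for the random haplotype assignment.
#' @return list of class `haplotype_pair` with `hap1`, `hap2`, `gene_id`,
#'   `seed`, `n_het`, `n_hom`, `n_missing`, or NULL if the gene is excluded.
#' @export
build_virtual_haplotypes <- function(gm, sample, gene, seed = 1L) {
  smap <- .gene_site_map(gm, gene)
  geno <- gm$geno[smap$site_row, sample]
  alt <- gm$sites$alt[smap$site_row]
  ref <- gm$sites$ref[smap$site_row]
  minus <- identical(gene$strand, "-")
  if (minus) { alt <- complement_base(alt); ref <- complement_base(ref) }
  n_missing <- sum(is.na(geno))
  geno[is.na(geno)] <- 0L
  use <- geno > 0L
  if (any(use)) {
    have <- substring(gene$cds_seq, smap$cds_pos[use], smap$cds_pos[use])
    if (!all(have == ref[use])) {
      warning("gene ", gene$gene_id, ": reference allele mismatch with CDS; gene excluded")
      return(NULL)
    }
  }
  hap1 <- hap2 <- gene$cds_seq
  hom <- which(geno == 2L)
  het <- which(geno == 1L)
  hap1 <- .substitute_bases(hap1, smap$cds_pos[hom], alt[hom])
  hap2 <- .substitute_bases(hap2, smap$cds_pos[hom], alt[hom])
  if (length(het) > 0) {
    to_h1 <- with_local_seed(seed, stats::runif(length(het)) < 0.5)
    hap1 <- .substitute_bases(hap1, smap$cds_pos[het[to_h1]], alt[het[to_h1]])
    hap2 <- .substitute_bases(hap2, smap$cds_pos[het[!to_h1]], alt[het[!to_h1]])
  }
  structure(list(hap1 = hap1, hap2 = hap2, gene_id = gene$gene_id, seed = seed,
                 n_het = length(het), n_hom = length(hom), n_missing = n_missing),
            class = "haplotype_pair")
}

#' Consensus haploid coding sequence for one gene of one individual
#'
#' Homozygous calls are applied directly; each heterozygous call is resolved
#' by a fair coin under `seed`. The result always equals one of the two
#' virtual haplotypes constructible from the same genotypes.
#'
#' @inheritParams build_virtual_haplotypes
#' @return character CDS, or NULL if the gene is excluded.
#' @export
consensus_haploid <- function(gm, sample, gene, seed = 1L) {
  smap <- .gene_site_map(gm, gene)
  geno <- gm$geno[smap$site_row, sample]
  alt <- gm$sites$alt[smap$site_row]
  ref <- gm$sites$ref[smap$site_row]
  if (identical(gene$strand, "-")) { alt <- complement_base(alt); ref <- complement_base(ref) }
  geno[is.na(geno)] <- 0L
  use <- geno > 0L
  if (any(use)) {
    have <- substring(gene$cds_seq, smap$cds_pos[use], smap$cds_pos[use])
    if (!all(have == ref[use])) {
      warning("gene ", gene$gene_id, ": reference allele mismatch with CDS; gene excluded")
      return(NULL)
    }
  }
  seq <- gene$cds_seq
  hom <- which(geno == 2L)
  seq <- .substitute_bases(seq, smap$cds_pos[hom], alt[hom])
  het <- which(geno == 1L)
  if (length(het) > 0) {
    take_alt <- with_local_seed(seed, stats::runif(length(het)) < 0.5)
    seq <- .substitute_bases(seq, smap$cds_pos[het[take_alt]], alt[het[take_alt]])
  }
  seq
}

#' Two-ratio branch-specific dN/dS by parsimony counting
#'
#' Assigns substitutions among three coordinate-matched coding sequences
#' (focal, sister, outgroup) to branches by parsimony: positions where the
#' focal sequence differs while sister = outgroup go to the focal branch
#' (omega_1); positions where the sister or the outgroup is the odd one go
#' to the background (omega_0). Codons containing a three-allele position,
#' an ambiguity, or a stop are excluded and counted. Within each codon the
#' parsimony-ancestral codon is reconstructed and per-branch (Nd, Sd) are
#' obtained by NG86 pathway averaging against it; site totals N and S are
#' taken from the ancestral sequence. omega = (Nd/N)/(Sd/S) per branch,
#' undefined-flagged when the branch has no synonymous substitutions.
#'
#' @param focal_cds,sister_cds,outgroup_cds equal-length CDS strings.
#' @return object of class `branch_omega`: list with `omega1`, `omega0`,
#'   per-branch counts, `N`, `S`, `n_codons`, `n_excluded`, flags, and
#'   `method = "NG86-two-ratio"`.
#' @export
branch_specific_omega <- function(focal_cds, sister_cds, outgroup_cds) {
  f <- split_codons(toupper(as.character(focal_cds)))
  s <- split_codons(toupper(as.character(sister_cds)))
  o <- split_codons(toupper(as.character(outgroup_cds)))
  if (length(unique(c(length(f), length(s), length(o)))) != 1)
    stop("sequences must have equal length")
  syn <- codon_syn_sites()
  pair <- codon_pair_counts()
  codons <- names(syn)
  valid <- f %in% codons & s %in% codons & o %in% codons &
    !is.na(syn[match(f, codons)]) & !is.na(syn[match(s, codons)]) &
    !is.na(syn[match(o, codons)])
  same <- valid & f == s & s == o
  Nd1 <- Sd1 <- Nd0 <- Sd0 <- 0
  Stot <- sum(syn[f[same]])
  n_used <- sum(same)
  n_excluded <- sum(!valid)
  for (i in which(valid & !same)) {
    cf <- f[i]; cs <- s[i]; co <- o[i]
    bf <- strsplit(cf, "")[[1]]; bs <- strsplit(cs, "")[[1]]; bo <- strsplit(co, "")[[1]]
    three_allele <- any(bf != bs & bs != bo & bf != bo)
    if (three_allele) { n_excluded <- n_excluded + 1L; next }
    # parsimony ancestral base: the allele carried by at least two sequences
    anc <- ifelse(bf == bs | bf == bo, bf, bs)
    ca <- paste(anc, collapse = "")
    if (!(ca %in% codons) || is.na(syn[ca])) { n_excluded <- n_excluded + 1L; next }
    n_used <- n_used + 1L
    Stot <- Stot + syn[[ca]]
    Nd1 <- Nd1 + pair$nd[ca, cf]; Sd1 <- Sd1 + pair$sd[ca, cf]
    Nd0 <- Nd0 + pair$nd[ca, cs] + pair$nd[ca, co]
    Sd0 <- Sd0 + pair$sd[ca, cs] + pair$sd[ca, co]
  }
  if (n_used == 0) stop("no comparable codons")
  N <- 3 * n_used - Stot
  om <- function(nd, sd) if (sd > 0) (nd / N) / (sd / Stot) else NA_real_
  structure(list(omega1 = om(Nd1, Sd1), omega0 = om(Nd0, Sd0),
                 Nd1 = Nd1, Sd1 = Sd1, Nd0 = Nd0, Sd0 = Sd0,
                 N = N, S = Stot, n_codons = n_used, n_excluded = n_excluded,
                 omega1_defined = Sd1 > 0, omega0_defined = Sd0 > 0,
                 method = "NG86-two-ratio"),
            class = "branch_omega")
}

#' @export
print.branch_omega <- function(x, ...) {
  cat("Two-ratio branch dN/dS (NG86 counting, parsimony assignment)\n")
  cat(sprintf("  focal branch:      Nd = %.2f, Sd = %.2f, omega1 = %s\n",
              x$Nd1, x$Sd1, if (x$omega1_defined) format(x$omega1, digits = 4) else "undefined"))
  cat(sprintf("  background:        Nd = %.2f, Sd = %.2f, omega0 = %s\n",
              x$Nd0, x$Sd0, if (x$omega0_defined) format(x$omega0, digits = 4) else "undefined"))
  cat(sprintf("  sites: N = %.2f, S = %.2f over %d codons (%d excluded)\n",
              x$N, x$S, x$n_codons, x$n_excluded))
  invisible(x)
}

#' Annotate the coding effect of single-nucleotide variants
#'
#' For each site, finds the gene model(s) whose CDS contains the position
#' and classifies the ref-to-alt substitution as synonymous or
#' nonsynonymous from the codon it falls in (strand-aware). Sites outside
#' every CDS are `noncoding`; sites in several genes with conflicting
#' effects are `ambiguous`.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models list of gene models (see [read_gene_models()]).
#' @return character vector in
#'   \{"noncoding", "synonymous", "nonsynonymous", "ambiguous"\}.
#' @export
annotate_snp_effect <- function(sites, gene_models) {
  gc <- Biostrings::GENETIC_CODE
  # exon table per chromosome with per-exon cumulative CDS offsets
  ex <- do.call(rbind, lapply(seq_along(gene_models), function(i) {
    g <- gene_models[[i]]
    ord <- order(g$cds$start)
    lens <- (g$cds$end - g$cds$start + 1)[ord]
    data.frame(chrom = g$chrom, start = g$cds$start[ord], end = g$cds$end[ord],
               cum_before = cumsum(c(0, lens[-length(lens)])),
               total = sum(lens), gene = i, stringsAsFactors = FALSE)
  }))
  out <- rep("noncoding", nrow(sites))
  if (is.null(ex) || nrow(ex) == 0 || nrow(sites) == 0) return(out)
  effect_of <- function(g, cds_pos, ref, alt) {
    if (identical(g$strand, "-")) { ref <- complement_base(ref); alt <- complement_base(alt) }
    cod_start <- 3 * ((cds_pos - 1) %/% 3) + 1
    codon <- substring(g$cds_seq, cod_start, cod_start + 2)
    offset <- cds_pos - cod_start + 1
    if (substr(codon, offset, offset) != ref) return(NA_character_) # ref/model mismatch
    new_codon <- codon
    substr(new_codon, offset, offset) <- alt
    if (!codon %in% names(gc) || !new_codon %in% names(gc)) return(NA_character_)
    if (gc[codon] == gc[new_codon]) "synonymous" else "nonsynonymous"
  }
  for (chr in unique(sites$chrom)) {
    exc <- ex[ex$chrom == chr, , drop = FALSE]
    if (nrow(exc) == 0) next
    idx <- which(sites$chrom == chr)
    for (i in idx) {
      p <- sites$pos[i]
      hits <- which(exc$start <= p & p <= exc$end)
      if (length(hits) == 0) next
      effects <- character(0)
      for (h in hits) {
        g <- gene_models[[exc$gene[h]]]
        fwd <- exc$cum_before[h] + (p - exc$start[h] + 1)
        cds_pos <- if (identical(g$strand, "-")) exc$total[h] - fwd + 1 else fwd
        e <- effect_of(g, cds_pos, sites$ref[i], sites$alt[i])
        if (!is.na(e)) effects <- c(effects, e)
      }
      if (length(effects) == 0) next
      out[i] <- if (length(unique(effects)) > 1) "ambiguous" else effects[1]
    }
  }
  out
}

#' Proportion of nonsynonymous SNPs per category
#'
#' For each SNP category, the fraction nonsyn / (nonsyn + syn) among coding
#' SNPs. Categories with no coding SNPs are returned NA (undefined-flagged).
#'
#' @param categories factor/character of per-site categories.
#' @param effects per-site coding effects from [annotate_snp_effect()].
#' @return data.frame with `category`, `n_nonsyn`, `n_syn`,
#'   `nonsyn_fraction`.
#' @export
nonsyn_fraction_by_category <- function(categories, effects) {
  stopifnot(length(categories) == length(effects))
  cats <- sort(unique(as.character(categories)))
  res <- lapply(cats, function(cc) {
    e <- effects[categories == cc]
    nn <- sum(e == "nonsynonymous"); ns <- sum(e == "synonymous")
    data.frame(category = cc, n_nonsyn = nn, n_syn = ns,
               nonsyn_fraction = if (nn + ns > 0) nn / (nn + ns) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
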