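# Expression normalization, biased-gene calling, tissue specificity,
# chromosomal enrichment and the cis-heterozygosity correlation.

#' Normalize an expression matrix
#'
#' Three literal steps: (1) divide each array by its 75th percentile
#' (linear-interpolation quantile), (2) log2-transform, (3) divide each
#' probe's log values by the probe's median log value. Signals below
#' `floor_eps` are raised to it and counted. Step 3 is numerically fragile
#' when a probe's median log value is near zero, so probes with
#' |median| < `delta` are flagged unstable and excluded.
#'
#' @param mat probes x arrays matrix of positive raw signals.
#' @param floor_eps positivity floor.
#' @param delta exclusion half-width around a zero probe median.
#' @return list with `mat` (normalized, unstable probes removed),
#'   `excluded_probes`, `n_floored`.
#' @export
normalize_expression <- function(mat, floor_eps = 1e-6, delta = 0.05) {
  mat <- as.matrix(mat)
  n_floored <- sum(mat < floor_eps)
  mat[mat < floor_eps] <- floor_eps
  p75 <- apply(mat, 2, stats::quantile, probs = 0.75, type = 7)
  if (any(p75 <= 0)) stop("array with non-positive 75th percentile")
  scaled <- sweep(mat, 2, p75, "/")
  lg <- log2(scaled)
  med <- apply(lg, 1, stats::median)
  unstable <- abs(med) < delta
  norm <- sweep(lg[!unstable, , drop = FALSE], 1, med[!unstable], "/")
  list(mat = norm, excluded_probes = rownames(mat)[unstable] %||% which(unstable),
       n_floored = n_floored)
}

# vectorized one-way ANOVA across rows: classic F from between/within sums
# of squares; identical to anova(lm(...)) per gene (cross-checked in tests
# against stats::oneway.test(var.equal = TRUE))
row_anova <- function(mat, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(mat)
  gm <- rowMeans(mat)
  ssb <- 0
  group_means <- matrix(0, nrow(mat), k)
  for (j in seq_len(k)) {
    sel <- groups == levels(groups)[j]
    m_j <- rowMeans(mat[, sel, drop = FALSE])
    group_means[, j] <- m_j
    ssb <- ssb + sum(sel) * (m_j - gm)^2
  }
  sst <- rowSums((mat - gm)^2)
  ssw <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, df1 = df1, df2 = df2, ssw = ssw, group_means = group_means,
       levels = levels(groups))
}

#' Call differentially expressed genes between groups
#'
#' Per-gene one-way ANOVA across the groups (for two groups this is the
#' pooled-variance t-test, F = t^2); genes with p < `alpha` are flagged,
#' with direction taken from the group means. Genes with zero within-group
#' variance are excluded as degenerate.
#'
#' @param mat normalized genes x arrays matrix.
#' @param groups factor over arrays (e.g. sex or species).
#' @param alpha significance level (the conventional screening threshold
#'   0.01 by default).
#' @return data.frame with `gene`, `effect` (first group mean minus second,
#'   for 2 groups; max minus min otherwise), `p`, `direction` (level with
#'   the highest mean), `flagged`, `degenerate`.
#' @export
call_biased_genes <- function(mat, groups, alpha = 0.01) {
  mat <- as.matrix(mat)
  groups <- droplevels(as.factor(groups))
  if (min(table(groups)) < 2) stop("call_biased_genes needs >= 2 replicates per group")
  av <- row_anova(mat, groups)
  degenerate <- av$ssw <= 0 | !is.finite(av$p)
  effect <- if (length(av$levels) == 2) av$group_means[, 1] - av$group_means[, 2]
  else apply(av$group_means, 1, max) - apply(av$group_means, 1, min)
  direction <- av$levels[max.col(av$group_means)]
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             effect = effect, p = av$p, direction = direction,
             flagged = !degenerate & av$p < alpha,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Presence calls against background (error) signals
#'
#' A gene is present in a tissue when its replicate signals are
#' significantly higher than the supplied background signals (one-sided
#' two-sample t-test at `p_threshold`).
#'
#' @param signal genes x replicate-arrays matrix for one tissue.
#' @param background numeric vector of error/background signals.
#' @param p_threshold significance threshold.
#' @return logical vector per gene.
#' @export
presence_calls <- function(signal, background, p_threshold = 0.001) {
  apply(as.matrix(signal), 1, function(x) {
    if (stats::sd(x) == 0 && stats::sd(background) == 0) return(mean(x) > mean(background))
    stats::t.test(x, background, alternative = "greater")$p.value < p_threshold
  })
}

#' Tissue-specific gene sets
#'
#' Testis-specific genes are present in testis and absent in brain;
#' ovary-specific genes analogously.
#'
#' @param presence logical matrix genes x tissues with columns including
#'   `testis`, `ovary`, `brain`.
#' @return list with `testis_specific` and `ovary_specific` (gene names or
#'   indices).
#' @export
tissue_specific_genes <- function(presence) {
  presence <- as.matrix(presence)
  need <- c("testis", "ovary", "brain")
  if (!all(need %in% colnames(presence)))
    stop("presence matrix needs columns: ", paste(need, collapse = ", "))
  ids <- rownames(presence) %||% seq_len(nrow(presence))
  list(testis_specific = ids[presence[, "testis"] & !presence[, "brain"]],
       ovary_specific = ids[presence[, "ovary"] & !presence[, "brain"]])
}

#' Chromosomal enrichment of flagged genes
#'
#' Per-chromosome proportion of flagged (e.g. sex-biased) genes, with each
#' candidate tested as a Grubbs outlier against the autosomes and an
#' iterative outlier scan over all chromosomes. Chromosomes with fewer
#' than `min_genes` genes are excluded with a warning.
#'
#' @param flags named logical per gene (names = gene ids).
#' @param gene_chrom named chromosome per gene.
#' @param candidates candidate chromosome names.
#' @param autosomes autosomal chromosome names (>= 4 with enough genes).
#' @param alpha significance level for the outlier calls.
#' @param min_genes minimum genes per chromosome.
#' @return list with `proportions` (per chromosome), `per_candidate`
#'   (Grubbs results), `outlier_scan` (iterative scan over autosomes +
#'   candidates).
#' @export
chromosome_enrichment <- function(flags, gene_chrom, candidates, autosomes,
                                  alpha = 0.05, min_genes = 20) {
  gene_chrom <- gene_chrom[names(flags)] %||% gene_chrom
  tab <- tapply(flags, gene_chrom, mean)
  cnt <- table(gene_chrom)
  small <- names(cnt)[cnt < min_genes]
  if (length(small) > 0) {
    warning("chromosome(s) excluded with < ", min_genes, " genes: ",
            paste(small, collapse = ", "))
    tab <- tab[!names(tab) %in% small]
  }
  autosomes <- intersect(autosomes, names(tab))
  if (length(autosomes) < 4) stop("need >= 4 autosomes with enough genes")
  per_candidate <- do.call(rbind, lapply(intersect(candidates, names(tab)), function(cand) {
    vals <- c(tab[autosomes], tab[cand])
    g <- grubbs_test(vals, length(vals))
    data.frame(chrom = cand, proportion = tab[[cand]], G = g$statistic,
               p = g$p.value, direction = g$direction,
               significant = g$p.value < alpha, stringsAsFactors = FALSE)
  }))
  keep <- c(autosomes, intersect(candidates, names(tab)))
  scan <- iterative_outlier_scan(tab[keep], keep, alpha = alpha)
  list(proportions = tab, per_candidate = per_candidate, outlier_scan = scan)
}

#' Sliding-window profile of flagged-gene proportion
#'
#' Proportion of flagged genes among genes whose TSS falls in each window
#' (gene-count denominators, not bp).
#'
#' @param gene_pos data.frame with `gene_id`, `chrom`, `tss`.
#' @param flags named logical per gene.
#' @param chrom chromosome to profile.
#' @param chrom_len its length.
#' @param window,step window and step in bp.
#' @return window data.frame with `value` (proportion) and `n_informative`
#'   (genes in window).
#' @export
expression_bias_windows <- function(gene_pos, flags, chrom, chrom_len,
                                    window = 2e6, step = 1e5) {
  ww <- make_windows(chrom_len, window, step)
  sel <- gene_pos$chrom == chrom
  tss <- gene_pos$tss[sel]
  fl <- flags[gene_pos$gene_id[sel]]
  val <- n <- numeric(nrow(ww))
  for (i in seq_len(nrow(ww))) {
    inw <- tss >= ww$start[i] & tss <= ww$end[i]
    n[i] <- sum(inw)
    val[i] <- if (n[i] > 0) mean(fl[inw]) else NA_real_
  }
  data.frame(chrom = chrom, start = ww$start, end = ww$end, value = val,
             n_informative = n,
             flag = ifelse(n == 0, "empty", ifelse(ww$partial, "partial", "")),
             stringsAsFactors = FALSE)
}

#' Correlation of expression sex-bias with upstream heterozygosity
#'
#' Counts heterozygous sites of one (male) sample in the strand-aware
#' upstream window of each gene's TSS and correlates the counts with the
#' absolute sex effect (Pearson). Reported for each requested upstream
#' width (10 kb and 3 kb by default).
#'
#' @param sex_effect named numeric per gene (signed effects are taken
#'   absolute).
#' @param gm [genotype_matrix()].
#' @param sample the male sample whose heterozygous sites measure X-Y
#'   divergence.
#' @param gene_pos data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param chrom restrict to genes on this chromosome.
#' @param upstream_bp upstream widths to evaluate.
#' @return data.frame with one row per width: `upstream_bp`, `r`, `p`, `n`,
#'   `defined`.
#' @export
cis_het_correlation <- function(sex_effect, gm, sample, gene_pos, chrom,
                                upstream_bp = c(10000, 3000)) {
  sel <- gene_pos$chrom == chrom & gene_pos$gene_id %in% names(sex_effect)
  gp <- gene_pos[sel, ]
  het_pos <- gm$sites$pos[gm$sites$chrom == chrom &
                            !is.na(gm$geno[, sample]) & gm$geno[, sample] == 1L]
  out <- lapply(upstream_bp, function(up) {
    counts <- vapply(seq_len(nrow(gp)), function(i) {
      if (gp$strand[i] == "-") sum(het_pos > gp$tss[i] & het_pos <= gp$tss[i] + up)
      else sum(het_pos >= gp$tss[i] - up & het_pos < gp$tss[i])
    }, numeric(1))
    ct <- correlation_test(counts, abs(sex_effect[gp$gene_id]), "pearson")
    data.frame(upstream_bp = up, r = ct$estimate, p = ct$p.value, n = ct$n,
               defined = ct$defined)
  })
  do.call(rbind, out)
}
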