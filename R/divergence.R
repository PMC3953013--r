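# Heterozygosity scans, X/Y SNP pattern classification, species site
# classes and the fusion-distance gradient.

#' Coverage mask presets
#'
#' `strict` = (20, 200): guards heterozygosity-based analyses against
#' undercalled heterozygotes at low depth and collapsed duplicates at high
#' depth. `loose` = (10, 500) for the remaining analyses.
#'
#' @param preset `"strict"` or `"loose"`.
#' @return numeric `c(lo, hi)`.
#' @export
mask_preset <- function(preset = c("strict", "loose")) {
  switch(match.arg(preset), strict = c(20, 200), loose = c(10, 500))
}

#' Build a depth-based site usability mask
#'
#' A position is usable iff every required sample has depth within
#' `[lo, hi]` (inclusive: depth 19 is masked under strict bounds, 20 and
#' 200 are kept). Tightening the bounds never unmasks a position.
#'
#' @param track raw (unnormalized) [coverage_track()].
#' @param samples samples whose depth jointly gates the mask.
#' @param lo,hi depth bounds; `lo < hi` required.
#' @return object of class `site_mask`: per-chromosome logical usability at
#'   the track's bin resolution.
#' @export
build_site_mask <- function(track, samples = NULL, lo = 20, hi = 200) {
  if (lo >= hi) stop("mask bounds require lo < hi")
  samples <- samples %||% track$samples
  chroms <- names(track$depth[[samples[1]]])
  usable <- list()
  for (chr in chroms) {
    u <- rep(TRUE, length(track$depth[[samples[1]]][[chr]]))
    for (s in samples) {
      v <- track$depth[[s]][[chr]]
      u <- u & v >= lo & v <= hi
    }
    usable[[chr]] <- u
  }
  structure(list(usable = usable, bin_size = track$bin_size,
                 chrom_lengths = track$chrom_lengths[chroms],
                 lo = lo, hi = hi, samples = samples),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  tot <- sum(vapply(names(x$usable), function(chr)
    usable_bp(x, chr, 1, x$chrom_lengths[[chr]]), numeric(1)))
  cat(sprintf("site_mask: depth in [%g, %g] for %d sample(s); %.0f usable bp\n",
              x$lo, x$hi, length(x$samples), tot))
  invisible(x)
}

#' Query a site mask
#'
#' @param mask [build_site_mask()] result.
#' @param chrom,pos positions to test.
#' @return logical usability per position.
#' @export
mask_sites <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    u <- mask$usable[[chr]]
    if (is.null(u)) { out[sel] <- FALSE; next }
    idx <- pmax(1, pmin(length(u), ceiling(pos[sel] / mask$bin_size)))
    out[sel] <- u[idx] & pos[sel] >= 1 & pos[sel] <= mask$chrom_lengths[[chr]]
  }
  out
}

#' @rdname mask_sites
#' @param start,end 1-based inclusive interval (vectors allowed).
#' @return usable base pairs within each interval.
#' @export
usable_bp <- function(mask, chrom, start, end) {
  stopifnot(length(unique(chrom)) <= 1)
  if (length(start) == 0) return(numeric(0))
  chr <- chrom[1]
  u <- mask$usable[[chr]]
  if (is.null(u)) return(rep(0, length(start)))
  P <- prefix_sum(as.numeric(u), mask$bin_size, mask$chrom_lengths[[chr]])
  P(end) - P(start - 1)
}

#' Genome-wide SNP rate relative to the reference
#'
#' Counts homozygous-alt sites as 1 and heterozygous sites as 0.5, over the
#' usable positions of the mask.
#'
#' @param gm [genotype_matrix()].
#' @param sample sample id.
#' @param mask [build_site_mask()] result.
#' @return list with `rate`, `n_hom`, `n_het`, `usable_bp`, `defined`.
#' @export
genome_snp_rate <- function(gm, sample, mask) {
  ok <- mask_sites(mask, gm$sites$chrom, gm$sites$pos)
  g <- gm$geno[ok, sample]
  tot <- sum(vapply(names(mask$usable), function(chr)
    usable_bp(mask, chr, 1, mask$chrom_lengths[[chr]]), numeric(1)))
  n_hom <- sum(g == 2L, na.rm = TRUE)
  n_het <- sum(g == 1L, na.rm = TRUE)
  list(rate = if (tot > 0) (n_hom + 0.5 * n_het) / tot else NA_real_,
       n_hom = n_hom, n_het = n_het, usable_bp = tot, defined = tot > 0)
}

# generic windowed proportion of flagged sites over usable bp
site_flag_windows <- function(chrom, pos, flag, mask, window, step) {
  res <- list()
  for (chr in names(mask$usable)) {
    len <- mask$chrom_lengths[[chr]]
    ww <- make_windows(len, window, step)
    den <- usable_bp(mask, rep(chr, nrow(ww)), ww$start, ww$end)
    p <- pos[chrom == chr & flag]
    cnt <- if (length(p) == 0) rep(0, nrow(ww)) else
      vapply(seq_len(nrow(ww)), function(i) sum(p >= ww$start[i] & p <= ww$end[i]), numeric(1))
    res[[chr]] <- data.frame(chrom = chr, start = ww$start, end = ww$end,
                             value = ifelse(den > 0, cnt / pmax(den, 1), NA_real_),
                             n_informative = den,
                             flag = ifelse(den == 0, "empty",
                                           ifelse(ww$partial, "partial", "")),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sliding windows of heterozygous-site proportion
#'
#' Per window, the number of heterozygous calls of one sample divided by
#' the usable (non-masked) base pairs. Windows with zero usable positions
#' are flagged `empty`.
#'
#' @param gm [genotype_matrix()].
#' @param sample sample id.
#' @param mask [build_site_mask()] result (the strict preset is
#'   recommended for heterozygosity).
#' @param window,step window and step in bp.
#' @return window data.frame (`chrom`, `start`, `end`, `value`,
#'   `n_informative`, `flag`).
#' @export
het_windows <- function(gm, sample, mask, window = 500000, step = 100000) {
  ok <- mask_sites(mask, gm$sites$chrom, gm$sites$pos)
  het <- !is.na(gm$geno[, sample]) & gm$geno[, sample] == 1L & ok
  site_flag_windows(gm$sites$chrom, gm$sites$pos, het, mask, window, step)
}

#' Per-chromosome heterozygous-site proportion
#'
#' Chromosome-level aggregate of [het_windows()], for outlier comparisons
#' of candidate sex chromosomes against autosomes.
#'
#' @inheritParams het_windows
#' @return data.frame with `chrom`, `value` (het sites / usable bp),
#'   `n_het`, `usable_bp`.
#' @export
chromosome_het_proportion <- function(gm, sample, mask) {
  ok <- mask_sites(mask, gm$sites$chrom, gm$sites$pos)
  het <- !is.na(gm$geno[, sample]) & gm$geno[, sample] == 1L & ok
  res <- lapply(names(mask$usable), function(chr) {
    den <- usable_bp(mask, chr, 1, mask$chrom_lengths[[chr]])
    data.frame(chrom = chr,
               value = if (den > 0) sum(het[gm$sites$chrom == chr]) / den else NA_real_,
               n_het = sum(het[gm$sites$chrom == chr]), usable_bp = den,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

.all_hom_same <- function(g) all(!is.na(g)) && all(g == g[1]) && g[1] %in% c(0L, 2L)

#' Classify putatively X-specific, Y-specific and shared SNPs
#'
#' Applies the diagnostic-pattern rules over the role samples at every
#' eligible site (all role genotypes non-missing; passes the mask when one
#' is supplied):
#' * `X_specific`: other-species females all homozygous for one allele,
#'   focal females all homozygous for the other, focal males all
#'   heterozygous (the derived allele is fixed on the focal X).
#' * `Y_specific`: other-species and focal females all homozygous for the
#'   same allele, focal males all heterozygous (derived allele on the
#'   focal Y only).
#' * `shared`: focal males and females all homozygous for one allele,
#'   other-species females homozygous for the other (on both X and Y).
#' * everything else, including any missing role genotype: `unclassified`.
#'
#' @param gm [genotype_matrix()].
#' @param roles list with `focal_males`, `focal_females`, `other_females`
#'   (see [sample_roles()]).
#' @param mask optional [build_site_mask()]; sites failing it are
#'   unclassified.
#' @return factor per site with levels X_specific, Y_specific, shared,
#'   unclassified; attribute `counts` holds the tabulation.
#' @export
classify_xy_snps <- function(gm, roles, mask = NULL) {
  fm <- gm$geno[, roles$focal_males, drop = FALSE]
  ff <- gm$geno[, roles$focal_females, drop = FALSE]
  of <- gm$geno[, roles$other_females, drop = FALSE]
  n <- nrow(gm$sites)
  complete <- rowSums(is.na(fm)) == 0 & rowSums(is.na(ff)) == 0 & rowSums(is.na(of)) == 0
  if (!is.null(mask)) complete <- complete & mask_sites(mask, gm$sites$chrom, gm$sites$pos)
  hom_same <- function(m) {
    first <- m[, 1]
    (rowSums(m == first) == ncol(m)) & (first %in% c(0L, 2L))
  }
  fm0 <- fm; ff0 <- ff; of0 <- of
  fm0[is.na(fm0)] <- -1L; ff0[is.na(ff0)] <- -1L; of0[is.na(of0)] <- -1L
  males_het <- rowSums(fm0 == 1L) == ncol(fm0)
  ff_hom <- hom_same(ff0); of_hom <- hom_same(of0); fm_hom <- hom_same(fm0)
  ff_allele <- ff0[, 1]; of_allele <- of0[, 1]; fm_allele <- fm0[, 1]
  x_spec <- complete & males_het & ff_hom & of_hom & ff_allele != of_allele
  y_spec <- complete & males_het & ff_hom & of_hom & ff_allele == of_allele
  shared <- complete & fm_hom & ff_hom & of_hom &
    fm_allele == ff_allele & fm_allele != of_allele
  cat_chr <- rep("unclassified", n)
  cat_chr[shared] <- "shared"
  cat_chr[x_spec] <- "X_specific"
  cat_chr[y_spec] <- "Y_specific"
  out <- factor(cat_chr, levels = c("X_specific", "Y_specific", "shared", "unclassified"))
  attr(out, "counts") <- table(out)
  out
}

#' Classify fixed differences and within-species polymorphism
#'
#' From the females of two species: a site is a `fixed_diff` when all
#' species-A females are homozygous for one allele and all species-B
#' females homozygous for a different one; a species is polymorphic at a
#' site when at least one of its females is heterozygous or carries a
#' homozygote differing from the others. Sites with any missing female
#' genotype (or failing the mask) are ineligible.
#'
#' @param gm [genotype_matrix()].
#' @param females_a,females_b sample ids of the two species' females.
#' @param mask optional [build_site_mask()].
#' @return data.frame per site: `eligible`, `fixed_diff`, `polymorphic_a`,
#'   `polymorphic_b`.
#' @export
classify_species_sites <- function(gm, females_a, females_b, mask = NULL) {
  ga <- gm$geno[, females_a, drop = FALSE]
  gb <- gm$geno[, females_b, drop = FALSE]
  eligible <- rowSums(is.na(ga)) == 0 & rowSums(is.na(gb)) == 0
  if (!is.null(mask)) eligible <- eligible & mask_sites(mask, gm$sites$chrom, gm$sites$pos)
  ga0 <- ga; gb0 <- gb
  ga0[is.na(ga0)] <- -1L; gb0[is.na(gb0)] <- -1L
  poly <- function(m) {
    mx <- mn <- m[, 1]
    for (j in seq_len(ncol(m))) { mx <- pmax(mx, m[, j]); mn <- pmin(mn, m[, j]) }
    rowSums(m == 1L) > 0 | mx != mn
  }
  hom_same <- function(m) (rowSums(m == m[, 1]) == ncol(m)) & (m[, 1] %in% c(0L, 2L))
  fixed <- eligible & hom_same(ga0) & hom_same(gb0) & ga0[, 1] != gb0[, 1]
  pa <- eligible & poly(ga0)
  pb <- eligible & poly(gb0)
  data.frame(eligible = eligible,
             fixed_diff = fixed,
             polymorphic_a = pa & !fixed,
             polymorphic_b = pb & !fixed)
}

#' Windowed site-class proportions
#'
#' Sliding-window proportion of flagged sites (e.g. fixed differences or
#' polymorphic sites) over usable bp, optionally expressed relative to the
#' mean over a set of autosomes.
#'
#' @param gm [genotype_matrix()].
#' @param flag logical per site.
#' @param mask [build_site_mask()].
#' @param window,step window and step in bp.
#' @param relative_to optional character vector of autosome names; when
#'   given, window values are divided by the pooled autosomal proportion.
#' @return window data.frame; with `relative_to`, an extra column
#'   `relative`.
#' @export
site_class_windows <- function(gm, flag, mask, window = 500000, step = 100000,
                               relative_to = NULL) {
  ww <- site_flag_windows(gm$sites$chrom, gm$sites$pos, flag, mask, window, step)
  if (!is.null(relative_to)) {
    num <- sum(flag & gm$sites$chrom %in% relative_to)
    den <- sum(vapply(relative_to, function(chr)
      usable_bp(mask, chr, 1, mask$chrom_lengths[[chr]]), numeric(1)))
    auto_mean <- if (den > 0) num / den else NA_real_
    ww$relative <- ww$value / auto_mean
  }
  ww
}

#' Logistic gradient of heterozygosity against fusion distance
#'
#' Partitions a chromosome into fixed bins (default 1 kb, right-open),
#' counts heterozygous sites and usable positions per bin, and fits a
#' binomial logistic regression of the per-bin proportion on the bin
#' midpoint's distance from the fusion end. A negative slope means
#' heterozygosity declines away from the fusion. Complete separation is
#' flagged on the returned fit.
#'
#' @param chrom chromosome name.
#' @param het_pos positions of heterozygous sites on `chrom` (already
#'   mask-filtered).
#' @param mask [build_site_mask()] providing usable-bp denominators.
#' @param fusion_end coordinate of the fusion end on `chrom`.
#' @param bin bin width in bp.
#' @return `gradient_fit` (see [logistic_fit()]) with extra fields
#'   `fusion_end`, `bin`, `n_bins_used`.
#' @export
fusion_gradient <- function(chrom, het_pos, mask, fusion_end, bin = 1000) {
  len <- mask$chrom_lengths[[chrom]]
  if (is.null(len)) stop("chromosome ", chrom, " not in mask")
  starts <- seq(1, len, by = bin)
  ends <- pmin(starts + bin - 1, len)
  den <- usable_bp(mask, rep(chrom, length(starts)), starts, ends)
  cnt <- tabulate(pmin(length(starts), (het_pos - 1) %/% bin + 1), nbins = length(starts))
  keep <- den > 0
  if (sum(keep) < 2) stop("fusion_gradient needs >= 2 non-empty bins")
  dist <- abs((starts + ends) / 2 - fusion_end)
  fit <- logistic_fit(cnt[keep], round(den[keep]), dist[keep])
  fit$fusion_end <- fusion_end
  fit$bin <- bin
  fit$n_bins_used <- sum(keep)
  fit
}
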