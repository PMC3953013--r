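# Y-degeneration detection from sex-differential normalized read depth.

# prefix-sum evaluator over fixed-width bins: returns a function P(x) giving
# sum over positions 1..x of the per-position value implied by per-bin values
prefix_sum <- function(per_bin, bin_size, chrom_len) {
  n <- length(per_bin)
  w <- bin_widths(chrom_len, bin_size)
  cs <- c(0, cumsum(per_bin * w))
  function(x) {
    x <- pmax(0, pmin(x, chrom_len))
    idx <- pmax(1, pmin(n, ceiling(x / bin_size)))
    cs[idx] + per_bin[idx] * (x - (idx - 1) * bin_size)
  }
}

#' Normalize coverage by library size
#'
#' Divides every depth value by the sample's total mapped read count, making
#' depth comparable across libraries of different size.
#'
#' @param track [coverage_track()] with positive `library_size` per sample.
#' @return normalized [coverage_track()].
#' @export
normalize_coverage <- function(track) {
  for (s in track$samples) {
    ls <- track$library_size[[s]]
    if (is.null(ls) || is.na(ls) || ls <= 0)
      stop("library_size must be > 0 for sample ", s)
    track$depth[[s]] <- lapply(track$depth[[s]], function(v) v / ls)
  }
  track$normalized <- TRUE
  track
}

#' Mean coverage per chromosome
#'
#' Mean depth over covered positions only (depth > 0 excluded positions are
#' typically repeat-masked or unmappable); the full-length mean (zeros
#' included) is reported alongside since either convention is found in
#' practice.
#'
#' @param track [coverage_track()].
#' @param samples samples to summarize (default all).
#' @return data.frame with `sample`, `chrom`, `mean` (covered-only; NA when
#'   nothing is covered), `mean_full`, `n_positions` (covered bp).
#' @export
chromosome_mean_coverage <- function(track, samples = NULL) {
  samples <- samples %||% track$samples
  res <- list()
  for (s in samples) {
    for (chr in names(track$depth[[s]])) {
      v <- track$depth[[s]][[chr]]
      w <- bin_widths(track$chrom_lengths[[chr]], track$bin_size)
      cov <- v > 0
      nbp <- sum(w[cov])
      res[[length(res) + 1]] <- data.frame(
        sample = s, chrom = chr,
        mean = if (nbp > 0) sum(v[cov] * w[cov]) / nbp else NA_real_,
        mean_full = sum(v * w) / sum(w),
        n_positions = nbp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# sliding-window frame for one chromosome: 1-based inclusive starts/ends
make_windows <- function(chrom_len, window, step) {
  if (chrom_len < window) {
    return(data.frame(start = 1, end = chrom_len, partial = TRUE))
  }
  starts <- seq(1, chrom_len - window + 1, by = step)
  data.frame(start = starts, end = starts + window - 1, partial = FALSE)
}

#' Sliding windows of male - female normalized coverage
#'
#' Per window, the difference of mean normalized depth between one male and
#' one female sample, each mean taken over the positions covered (> 0) in
#' that sample. Windows with no covered positions in either sample are
#' flagged; a chromosome shorter than the window yields a single truncated
#' window flagged partial.
#'
#' @param track normalized [coverage_track()].
#' @param male,female sample ids.
#' @param window,step window and step size in bp (multiples of the track's
#'   bin size).
#' @return data.frame with `chrom`, `start`, `end`, `value`
#'   (male mean - female mean), `n_informative` (bp covered in both),
#'   `flag` ("" / "partial" / "empty").
#' @export
sex_coverage_windows <- function(track, male, female, window = 500000, step = 100000) {
  if (!track$normalized) stop("normalize_coverage() must be applied first")
  res <- list()
  for (chr in intersect(names(track$depth[[male]]), names(track$depth[[female]]))) {
    len <- track$chrom_lengths[[chr]]
    vm <- track$depth[[male]][[chr]]
    vf <- track$depth[[female]][[chr]]
    Pm_num <- prefix_sum(vm * (vm > 0), track$bin_size, len)
    Pm_den <- prefix_sum(as.numeric(vm > 0), track$bin_size, len)
    Pf_num <- prefix_sum(vf * (vf > 0), track$bin_size, len)
    Pf_den <- prefix_sum(as.numeric(vf > 0), track$bin_size, len)
    Pboth <- prefix_sum(as.numeric(vm > 0 & vf > 0), track$bin_size, len)
    ww <- make_windows(len, window, step)
    a <- ww$start - 1; b <- ww$end
    m_n <- Pm_num(b) - Pm_num(a); m_d <- Pm_den(b) - Pm_den(a)
    f_n <- Pf_num(b) - Pf_num(a); f_d <- Pf_den(b) - Pf_den(a)
    val <- ifelse(m_d > 0 & f_d > 0, m_n / pmax(m_d, 1e-300) - f_n / pmax(f_d, 1e-300), NA_real_)
    flag <- ifelse(m_d == 0 | f_d == 0, "empty", ifelse(ww$partial, "partial", ""))
    res[[chr]] <- data.frame(chrom = chr, start = ww$start, end = ww$end,
                             value = val, n_informative = Pboth(b) - Pboth(a),
                             flag = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Locate a coverage-deficit region from window differences
#'
#' Estimates the span of depressed male-female coverage as the run of
#' windows whose value falls below the midpoint between the chromosome's
#' baseline (median) and its minimum, correcting the run's edges by half a
#' window. Used to localize hemizygous (Y-deleted) regions.
#'
#' @param windows window data.frame for one chromosome (from
#'   [sex_coverage_windows()]).
#' @return list with `start`, `end` (estimated deficit span) and
#'   `n_windows`; NULL when no window dips below the midpoint.
#' @export
locate_coverage_deficit <- function(windows) {
  v <- windows$value
  ok <- is.finite(v)
  if (!any(ok)) return(NULL)
  base <- stats::median(v[ok])
  lo <- min(v[ok])
  if (lo >= base) return(NULL)
  below0 <- ok & v < (base + lo) / 2
  if (!any(below0)) return(NULL)
  deficit <- stats::median(v[below0]) # robust level of the depressed run
  thresh <- (base + deficit) / 2
  below <- ok & v < thresh
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- starts_i[best]; i2 <- ends_i[best]
  window <- windows$end[1] - windows$start[1] + 1
  step <- if (nrow(windows) > 1) windows$start[2] - windows$start[1] else window
  # refine each edge by interpolating the threshold crossing between the
  # adjacent window values (window means are piecewise linear in overlap)
  left <- windows$start[i1] + window / 2
  if (i1 > 1 && is.finite(v[i1 - 1]) && v[i1] != v[i1 - 1]) {
    s_cross <- windows$start[i1 - 1] +
      step * (thresh - v[i1 - 1]) / (v[i1] - v[i1 - 1])
    left <- s_cross + window / 2
  }
  right <- windows$end[i2] - window / 2
  if (i2 < nrow(windows) && is.finite(v[i2 + 1]) && v[i2 + 1] != v[i2]) {
    s_cross <- windows$start[i2] +
      step * (thresh - v[i2]) / (v[i2 + 1] - v[i2])
    right <- s_cross + window / 2
  }
  list(start = left, end = right, n_windows = i2 - i1 + 1)
}

#' Detect chromosome-scale Y degeneration
#'
#' For each sample and each candidate chromosome, runs a Grubbs outlier
#' test of the candidate's mean normalized coverage against the autosomes
#' plus the candidate. A candidate is called `degenerate` only when every
#' male is a significant low outlier and no female is significant - the
#' hemizygosity signature.
#'
#' @param chrom_means data.frame from [chromosome_mean_coverage()] on a
#'   normalized track.
#' @param sample_sheet sample sheet data.frame.
#' @param candidates candidate chromosome names.
#' @param autosomes reference (autosomal) chromosome names (>= 4).
#' @param alpha per-test significance level.
#' @return object of class `degeneration_report`: list with `per_sample`
#'   (sample x candidate Grubbs results) and `summary` (per candidate:
#'   male/female significance and the `degenerate` flag).
#' @export
detect_degeneration <- function(chrom_means, sample_sheet, candidates, autosomes,
                                alpha = 0.01) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  if (length(autosomes) < 4)
    stop("detect_degeneration requires >= 4 reference chromosomes")
  rows <- list()
  for (s in sample_sheet$sample_id) {
    cm <- chrom_means[chrom_means$sample == s, ]
    vals_auto <- cm$mean[match(autosomes, cm$chrom)]
    if (anyNA(vals_auto)) stop("missing autosome mean for sample ", s)
    for (cand in candidates) {
      vc <- cm$mean[match(cand, cm$chrom)]
      if (is.na(vc)) stop("missing candidate mean for ", cand, ", sample ", s)
      g <- grubbs_test(c(vals_auto, vc), length(vals_auto) + 1)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, sex = sample_sheet$sex[sample_sheet$sample_id == s],
        chrom = cand, G = g$statistic, p = g$p.value,
        direction = g$direction,
        significant = g$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  summ <- lapply(candidates, function(cand) {
    d <- per_sample[per_sample$chrom == cand, ]
    males <- d[d$sex == "male", ]
    females <- d[d$sex == "female", ]
    male_sig <- nrow(males) > 0 && all(males$significant & males$direction < 0)
    female_sig <- nrow(females) > 0 && any(females$significant)
    data.frame(chrom = cand,
               n_males = nrow(males), n_females = nrow(females),
               male_significant = male_sig,
               female_significant = female_sig,
               degenerate = male_sig && !female_sig,
               stringsAsFactors = FALSE)
  })
  structure(list(per_sample = per_sample, summary = do.call(rbind, summ),
                 alpha = alpha),
            class = "degeneration_report")
}

#' @export
print.degeneration_report <- function(x, ...) {
  cat("Chromosome-scale degeneration scan (Grubbs, alpha =", x$alpha, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
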