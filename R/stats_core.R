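#' Grubbs' test for a single outlier
#'
#' Tests whether one designated value is an outlier relative to the rest of
#' the sample, assuming an approximately normal null. The statistic is
#' \eqn{G = |x_c - \bar{x}| / s} with \eqn{\bar{x}} and \eqn{s} (the n-1
#' denominator sample SD) computed over *all* values including the candidate.
#' The two-sided p-value uses the closed form relating G to a Student-t
#' quantile: \eqn{t^2 = n(n-2)G^2 / ((n-1)^2 - nG^2)} and
#' \eqn{p = \min(1,\; 2n\,P(T_{n-2} > t))}. When \eqn{nG^2 \ge (n-1)^2}
#' (G at its algebraic maximum \eqn{(n-1)/\sqrt{n}}) the p-value is 0.
#'
#' @param values numeric vector, length >= 4.
#' @param candidate_index index of the value under test.
#' @return list with `statistic` (G), `p.value`, `n`, `direction`
#'   (+1 if the candidate lies above the mean, -1 below), and `candidate`.
#' @export
grubbs_test <- function(values, candidate_index) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("grubbs_test requires n >= 4 (got n = ", n, ")")
  if (candidate_index < 1 || candidate_index > n) stop("candidate_index out of range")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("grubbs_test undefined: zero or non-finite sd")
  m <- mean(values)
  dev <- values[candidate_index] - m
  G <- abs(dev) / s
  denom <- (n - 1)^2 - n * G^2
  if (denom <= 0) {
    p <- 0
  } else {
    t <- sqrt(n * (n - 2) * G^2 / denom)
    p <- min(1, 2 * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
  }
  list(statistic = G, p.value = p, n = n,
       direction = if (dev >= 0) 1L else -1L,
       candidate = values[candidate_index],
       method = "Grubbs two-sided")
}

#' Iterative Grubbs outlier scan
#'
#' Repeatedly applies [grubbs_test()] to the most extreme remaining value,
#' removing it if significant at `alpha`, until no further outlier is found
#' or fewer than 4 values remain. Mirrors the detect-and-remove screening
#' used for chromosome-level summaries.
#'
#' @param values numeric vector (length >= 5 recommended).
#' @param labels optional labels, same length as `values`.
#' @param alpha significance level for removal.
#' @return data.frame with columns `label`, `value`, `G`, `p`, `iteration`,
#'   `direction`; zero rows when no outlier is detected.
#' @export
iterative_outlier_scan <- function(values, labels = NULL, alpha = 0.05) {
  if (is.null(labels)) labels <- as.character(seq_along(values))
  stopifnot(length(labels) == length(values))
  out <- data.frame(label = character(0), value = numeric(0), G = numeric(0),
                    p = numeric(0), iteration = integer(0), direction = integer(0),
                    stringsAsFactors = FALSE)
  vals <- as.numeric(values)
  labs <- as.character(labels)
  iter <- 0L
  while (length(vals) >= 4) {
    idx <- which.max(abs(vals - mean(vals)))
    g <- grubbs_test(vals, idx)
    if (g$p.value >= alpha) break
    iter <- iter + 1L
    out <- rbind(out, data.frame(label = labs[idx], value = vals[idx],
                                 G = g$statistic, p = g$p.value,
                                 iteration = iter, direction = g$direction,
                                 stringsAsFactors = FALSE))
    vals <- vals[-idx]
    labs <- labs[-idx]
  }
  out
}

#' Mann-Whitney U test
#'
#' Wrapper around [stats::wilcox.test()] reporting the U statistic for the
#' first sample (number of (x, y) pairs with x > y, counting ties as 1/2).
#' Uses exact enumeration when both samples are small (min(n, m) <= 8) and
#' tie-free, otherwise the normal approximation with midranks and tie
#' correction.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `U`, `p.value`, `n`, `m`, `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("mann_whitney_u requires n >= 2 per group")
  ties <- any(duplicated(c(x, y)))
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       n = length(x), m = length(y), exact = use_exact)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of tables at
#' most as probable as the observed one (the [stats::fisher.test()]
#' convention).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return list with `p.value` and `odds.ratio` (conditional MLE).
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("fisher_exact expects a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  ft <- stats::fisher.test(counts)
  list(p.value = ft$p.value, odds.ratio = unname(ft$estimate))
}

#' Correlation test
#'
#' Pearson or Spearman correlation with its p-value, via
#' [stats::cor.test()]. Degenerate inputs (zero variance) are returned
#' undefined-flagged rather than erroring.
#'
#' @param x,y paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p.value`, `n`, `method`, `defined`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p.value = NA_real_, n = length(x),
                method = method, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x),
       method = method, defined = TRUE)
}

#' Binomial logistic regression of grouped successes on one covariate
#'
#' Fits logit(p) = intercept + beta * covariate by iteratively reweighted
#' least squares ([stats::glm()], binomial family, convergence tolerance
#' 1e-8, at most 100 iterations). Complete separation is flagged rather
#' than silently reported.
#'
#' @param successes,totals integer vectors per observation unit (e.g. het
#'   sites and usable sites per 1-kb bin).
#' @param covariate numeric covariate (e.g. distance from the fusion end, bp).
#' @return object of class `gradient_fit`: list with `beta`, `intercept`,
#'   `se_beta`, `se_intercept`, `p_beta`, `p_intercept`, `n`, `converged`,
#'   `separated`.
#' @export
logistic_fit <- function(successes, totals, covariate) {
  stopifnot(length(successes) == length(totals),
            length(successes) == length(covariate))
  keep <- totals > 0 & is.finite(covariate)
  successes <- successes[keep]; totals <- totals[keep]; covariate <- covariate[keep]
  if (length(successes) < 2) stop("logistic_fit needs >= 2 usable observations")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(successes, totals - successes) ~ covariate,
               family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  if (!is.matrix(cf) || nrow(cf) < 2) {
    cf <- rbind(cf, c(NA, NA, NA, NA))
  }
  structure(list(beta = cf[2, 1], intercept = cf[1, 1],
                 se_beta = cf[2, 2], se_intercept = cf[1, 2],
                 p_beta = cf[2, 4], p_intercept = cf[1, 4],
                 n = length(successes), converged = fit$converged,
                 separated = separated || abs(cf[2, 1]) > 1e3 * max(1e-12, 1 / diff(range(covariate)))),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("Binomial logistic fit (IRLS)\n")
  cat(sprintf("  beta      = %.6g (SE %.3g, p = %.3g)\n", x$beta, x$se_beta, x$p_beta))
  cat(sprintf("  intercept = %.6g (SE %.3g, p = %.3g)\n",
              x$intercept, x$se_intercept, x$p_intercept))
  cat(sprintf("  n = %d bins; converged: %s; separation: %s\n",
              x$n, x$converged, x$separated))
  invisible(x)
}
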