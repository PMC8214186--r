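#' Lin concordance correlation coefficient
#'
#' Agreement between paired measurements that penalizes both loss of
#' correlation and location/scale shift:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`.
#' Population (1/n) moments by default, matching Lin's original formulation;
#' `population = FALSE` switches to n-1 moments. Always
#' `|rho_c| <= |pearson r|`, with equality only when the two measurements
#' share mean and variance.
#'
#' @param x,y Paired measurement vectors of equal length (>= 2), same units.
#' @param population Use 1/n moments (default) rather than 1/(n-1).
#' @return `rho_c` in `[-1, 1]`; `NA` when both vectors are constant.
#' @examples
#' lin_ccc(c(1, 2, 3, 4), c(1.1, 2.0, 3.2, 3.9))
#' @export
lin_ccc <- function(x, y, population = TRUE) {
  check_pairs(x, y)
  n <- length(x)
  f <- if (population) (n - 1) / n else 1
  sxy <- stats::cov(x, y) * f
  sx <- stats::var(x) * f
  sy <- stats::var(y) * f
  den <- sx + sy + (mean(x) - mean(y))^2
  if (den == 0) return(NA_real_)  # both constant with equal means
  2 * sxy / den
}

check_pairs <- function(x, y) {
  if (length(x) != length(y))
    hs_invalid_input("paired vectors must have equal length")
  if (length(x) < 2) hs_invalid_input("need at least 2 pairs")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    hs_invalid_input("paired vectors must be finite and complete")
  invisible(TRUE)
}

#' Bland-Altman analysis of paired differences
#'
#' Bias and 95% limits of agreement of `test - reference` differences:
#' `bias = mean(d)`, limits `bias +/- 1.96 sd(d)` (sample sd, n-1). The
#' `(mean, difference)` pairs are returned for plotting.
#'
#' @param reference,test Paired measurement vectors, same units.
#' @return A list of class `bland_altman`: `bias`, `loa` (lower, upper),
#'   `sd_diff`, `means`, `diffs`, `n`.
#' @export
bland_altman <- function(reference, test) {
  check_pairs(reference, test)
  d <- test - reference
  s <- stats::sd(d)
  bias <- mean(d)
  structure(list(bias = bias, loa = c(lower = bias - 1.96 * s,
                                      upper = bias + 1.96 * s),
                 sd_diff = s, means = (reference + test) / 2, diffs = d,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g; 95%% limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair",
                 ylab = "difference (test - reference)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "red")
  invisible(x)
}

#' Percent error of paired measurements
#'
#' Per-pair percent error `100 |test - reference| / reference` (absolute by
#' default; `signed = TRUE` keeps the sign). Pairs with a zero reference are
#' excluded with a warning.
#'
#' @param reference,test Paired vectors; reference nonzero.
#' @param signed Keep the sign of the error.
#' @return A list: `per_pair` (percent), `mean`, `sd`, `n_used`.
#' @export
percent_error <- function(reference, test, signed = FALSE) {
  check_pairs(reference, test)
  keep <- reference != 0
  if (!all(keep))
    warning(sprintf("%d pair(s) with zero reference excluded", sum(!keep)))
  if (!any(keep)) hs_insufficient_data("no pairs with nonzero reference")
  e <- 100 * (test[keep] - reference[keep]) / reference[keep]
  if (!signed) e <- abs(e)
  list(per_pair = e, mean = mean(e), sd = stats::sd(e), n_used = sum(keep))
}

#' Test-retest intraclass correlation coefficient
#'
#' Single-measure, absolute-agreement, two-way random-effects ICC — the
#' standard test-retest form, ICC(2,1) in the Shrout-Fleiss taxonomy —
#' computed from the two-way mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `n` subjects
#' and `k` repeats. Subjects with fewer than 2 non-missing repeats are
#' dropped with a warning; remaining missing cells are handled listwise
#' (the subject is dropped).
#'
#' @param measurements Numeric matrix, subjects in rows, repeats in columns.
#' @return A list of class `icc`: `value`, `variant`, `n`, `k`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_test_retest <- function(measurements) {
  m <- as.matrix(measurements)
  if (ncol(m) < 2) hs_invalid_input("need at least 2 repeats (columns)")
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("%d subject(s) with missing repeats dropped (listwise)",
                    sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2) hs_invalid_input("need at least 2 complete subjects")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(value = icc,
                 variant = "ICC(2,1) two-way random, absolute agreement, single measure",
                 n = n, k = k, msr = msr, msc = msc, mse = mse),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("<icc> %.4f [%s; n = %d subjects, k = %d repeats]\n",
              x$value, x$variant, x$n, x$k))
  invisible(x)
}

#' Window retention as a function of confidence cutoff
#'
#' For each cutoff `c`, the fraction of analysis windows whose confidence
#' score is at least `c`. Non-increasing in the cutoff; 1 at cutoff 0.
#'
#' @param confidences Confidence scores in `[0, 1]`.
#' @param cutoffs Cutoff grid (default 0 to 1 by 0.05).
#' @return A data.frame with `cutoff` and `retained` columns.
#' @export
retention_curve <- function(confidences, cutoffs = seq(0, 1, by = 0.05)) {
  if (any(confidences < 0 | confidences > 1))
    hs_invalid_input("confidences must lie in [0, 1]")
  data.frame(cutoff = cutoffs,
             retained = vapply(cutoffs,
                               function(cc) mean(confidences >= cc),
                               numeric(1)))
}

#' Full agreement report for paired measurements
#'
#' Bundles the validation statistics used for method comparison: Lin
#' concordance, Pearson correlation, Bland-Altman bias and limits of
#' agreement, and mean percent error.
#'
#' @param reference,test Paired measurement vectors, same units.
#' @return An object of class `agreement_report`: `lin_ccc`, `pearson_r`,
#'   `ba` ([bland_altman()] result), `percent_error` ([percent_error()]
#'   result), `n`.
#' @examples
#' set.seed(1)
#' ref <- rnorm(30, 100, 10)
#' agreement_report(ref, ref + rnorm(30, 1, 3))
#' @export
agreement_report <- function(reference, test) {
  check_pairs(reference, test)
  structure(list(lin_ccc = lin_ccc(reference, test),
                 pearson_r = stats::cor(reference, test),
                 ba = bland_altman(reference, test),
                 percent_error = percent_error(reference, test),
                 n = length(reference)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n))
  cat(sprintf("  Lin concordance rho_c = %.4f (Pearson r = %.4f)\n",
              x$lin_ccc, x$pearson_r))
  cat(sprintf("  Bland-Altman bias %.4g, limits [%.4g, %.4g]\n",
              x$ba$bias, x$ba$loa[1], x$ba$loa[2]))
  cat(sprintf("  mean percent error %.3f%%\n", x$percent_error$mean))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) plot(x$ba, ...)
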