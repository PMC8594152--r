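#' Prevalence with confidence interval
#'
#' @param n_affected,n_total counts.
#' @param conf confidence level (default 0.95).
#' @param method `"wald"` (normal approximation, default) or `"wilson"`.
#' @return List of class `"prevalence"`: `n_affected`, `n_total`, `p_hat`,
#'   `ci_low`, `ci_high`, `conf`, `method`. The Wald lower bound is clipped
#'   at 0 and the upper bound at 1.
#' @examples
#' prevalence(168, 1156)
#' @export
prevalence <- function(n_affected, n_total, conf = 0.95,
                       method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n_total <= 0) stop("n_total must be positive")
  if (n_affected < 0 || n_affected > n_total)
    stop("n_affected must be in [0, n_total]")
  p <- n_affected / n_total
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n_total)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    den <- 1 + z^2 / n_total
    ctr <- (p + z^2 / (2 * n_total)) / den
    half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / den
    lo <- max(0, ctr - half); hi <- min(1, ctr + half)
  }
  structure(list(n_affected = n_affected, n_total = n_total, p_hat = p,
                 ci_low = lo, ci_high = hi, conf = conf, method = method),
            class = "prevalence")
}

#' @export
print.prevalence <- function(x, ...) {
  cat(sprintf("Prevalence: %d/%d = %.1f%% (%d%% CI %.1f-%.1f%%, %s)\n",
              x$n_affected, x$n_total, 100 * x$p_hat,
              round(100 * x$conf), 100 * x$ci_low, 100 * x$ci_high,
              x$method))
  invisible(x)
}

#' Chi-squared test of a prevalence difference between sexes
#'
#' Pearson chi-squared test on a 2x2 table of affected/unaffected counts by
#' sex, without continuity correction.
#'
#' @param tab 2x2 matrix of counts, rows = groups (sexes), columns =
#'   affected/unaffected (orientation does not matter).
#' @return List of class `"contingency_test"` with the table, `chi2`, `df`
#'   and `p_value`.
#' @export
sex_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be a 2x2 matrix")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a table margin is zero")
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(table = tab, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (no continuity correction): X2(%d, N = %d) = %.2f, p = %.3f\n",
              x$df, sum(x$table), x$chi2, x$p_value))
  invisible(x)
}

#' Grading distribution among affected animals
#'
#' @param clean a [clean_records()] dataset (or any data frame with columns
#'   `diagnosis` and `grade`).
#' @return List with `counts` (named: mild, moderate, severe, ungraded),
#'   `pct_among_affected` and `pct_among_graded` (percentages; `NULL` when
#'   the respective denominator is zero).
#' @export
grading_summary <- function(clean) {
  aff <- clean[clean$diagnosis == "affected", , drop = FALSE]
  counts <- c(mild = sum(aff$grade == "mild"),
              moderate = sum(aff$grade == "moderate"),
              severe = sum(aff$grade == "severe"),
              ungraded = sum(aff$grade == "none"))
  n_aff <- sum(counts)
  n_graded <- n_aff - counts[["ungraded"]]
  pct_affected <- if (n_aff > 0) 100 * counts / n_aff else NULL
  pct_graded <- if (n_graded > 0)
    100 * counts[c("mild", "moderate", "severe")] / n_graded else NULL
  list(counts = counts, n_affected = n_aff, n_graded = n_graded,
       pct_among_affected = pct_affected, pct_among_graded = pct_graded)
}

#' Screening coverage percentage
#'
#' @param n_screened number of screened units (animals or litters).
#' @param n_registered number registered in the same period.
#' @param digits decimals in the rounded value (default 1).
#' @return List with `pct` (full precision) and `pct_rounded`.
#' @export
coverage <- function(n_screened, n_registered, digits = 1) {
  if (n_registered <= 0) stop("n_registered must be positive")
  pct <- 100 * n_screened / n_registered
  list(pct = pct, pct_rounded = round_half_up(pct, digits))
}

## round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
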