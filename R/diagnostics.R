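#' Effective sample size of an MCMC chain
#'
#' Computes `ESS = n / (1 + 2 * sum(rho_k))`, truncating the autocorrelation
#' sum by Geyer's initial positive sequence rule: sums of consecutive
#' autocorrelation pairs `rho_{2m} + rho_{2m+1}` are accumulated while they
#' remain positive.
#'
#' @param samples numeric vector, length >= 100.
#' @return The effective sample size (a positive real). For a constant
#'   (degenerate) chain the nominal length is returned with attribute
#'   `degenerate = TRUE` and a warning.
#' @examples
#' set.seed(1)
#' effective_sample_size(rnorm(1000))
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples; got ", n)
  if (stats::var(samples) == 0) {
    warning("degenerate (constant) chain; reporting nominal size")
    return(structure(as.numeric(n), degenerate = TRUE))
  }
  rho <- autocorr_fft(samples)
  ## Geyer initial positive sequence: accumulate pair sums
  ## Gamma_m = rho_{2m} + rho_{2m+1} (m = 0, 1, ...) while positive;
  ## tau = 2 * sum(Gamma_m) - 1  (the -1 corrects double-counted rho_0)
  tau <- -1
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    g <- rho[2L * m + 1L] + rho[2L * m + 2L]   # rho[k + 1] is lag k
    if (!is.finite(g) || g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1L
  }
  if (m == 0L) tau <- 1   # even Gamma_0 <= 0: treat as uncorrelated
  n / max(tau, .Machine$double.eps)
}

## autocorrelation function via FFT, lags 0 .. n-1 (rho[1] = lag 0 = 1)
autocorr_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(xc, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m
  ac / ac[1L]
}

#' Highest posterior density interval
#'
#' Empirical shortest-interval (Chen-Shao) HPD: the shortest contiguous
#' window over the sorted samples that contains `ceiling(level * n)` points;
#' ties are broken by taking the leftmost such window.
#'
#' @param samples numeric vector, length >= 100.
#' @param level probability content, in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' set.seed(1)
#' hpd_interval(rnorm(10000))  # ~ (-1.96, 1.96)
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples; got ", n)
  s <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1L], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)   # which.min takes the leftmost on ties
  c(s[i], s[i + m - 1L])
}

#' Posterior summary of stored Gibbs samples
#'
#' Posterior mean, HPD region and effective sample size for each stored
#' parameter of a [threshold_gibbs()] chain (or any data frame / matrix of
#' stored samples).
#'
#' @param chain a `threshold_gibbs` object, or a matrix/data frame whose
#'   columns are parameters.
#' @param level HPD probability content (default 0.95).
#' @return Data frame with one row per parameter: `parameter`, `mean`,
#'   `hpd_low`, `hpd_high`, `ess`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  samples <- if (inherits(chain, "threshold_gibbs")) {
    as.matrix(chain$samples[, c("sigma2_a", "h2"), drop = FALSE])
  } else {
    as.matrix(as.data.frame(chain))
  }
  if (nrow(samples) < 100L)
    stop("need at least 100 stored samples; got ", nrow(samples))
  rows <- lapply(colnames(samples), function(p) {
    x <- samples[, p]
    hpd <- hpd_interval(x, level)
    data.frame(parameter = p, mean = mean(x),
               hpd_low = hpd[1L], hpd_high = hpd[2L],
               ess = as.numeric(effective_sample_size(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
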