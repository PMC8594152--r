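#' Bayesian threshold animal model via Gibbs sampling
#'
#' Fits the threshold (liability) animal model to a binary diagnosis: a
#' latent Gaussian liability `l = X beta + a + e` determines the phenotype
#' through a threshold fixed at 0, with the residual variance restricted to
#' unity for identifiability. Each Gibbs round updates (i) the liabilities
#' from their truncated-normal full conditionals, (ii) the fixed effects
#' jointly, (iii) the breeding values by single-site updates over the sparse
#' A-inverse neighbourhood in pedigree code order, and (iv) the genetic
#' variance from a scaled inverse chi-square full conditional. Because each
#' animal carries a single binary record - a setting known to give poorly
#' mixing variance updates - the quadratic form of the variance update is,
#' by default, restricted to the animals that have offspring, using the
#' inverse of the relationship matrix of that parental subset.
#'
#' Heritability is computed per stored sample as
#' `h2 = sigma2_a / (sigma2_a + 1)`.
#'
#' @param clean a [clean_records()] dataset (binary `y`).
#' @param ped a [pedigree()] covering all recorded animals.
#' @param model fixed-effects model 1, 2 or 3 (see [build_design()]).
#' @param n_rounds total Gibbs rounds (default 1,100,000).
#' @param burn_in rounds discarded (default 100,000).
#' @param thin storage interval (default 10).
#' @param seed integer seed; when supplied, `set.seed(seed)` makes the chain
#'   reproducible.
#' @param prior list `list(nu, s2)` for the scaled-inverse-chi-square prior
#'   on `sigma2_a`; the default `nu = -2, s2 = 0` is the improper flat prior
#'   on (0, Inf).
#' @param variance_update `"parents_only"` (default) or `"all_animals"`.
#' @param A_inv optional precomputed [relationship_inverse()].
#' @param start_sigma2a starting genetic variance (default 0.5).
#' @param merge_min passed to [build_design()].
#' @return Object of class `"threshold_gibbs"` with components `samples`
#'   (data frame: `round`, `sigma2_a`, `h2`), `ebv` (posterior-mean breeding
#'   values, named), `fixef` (posterior means), `final_liability`, `config`
#'   and `n_parents`. Residual variance is identically 1.
#' @seealso [summarize_chain()], [effective_sample_size()], [hpd_interval()]
#' @export
threshold_gibbs <- function(clean, ped, model = 1,
                            n_rounds = 1100000, burn_in = 100000, thin = 10,
                            seed = NULL,
                            prior = list(nu = -2, s2 = 0),
                            variance_update = c("parents_only",
                                                "all_animals"),
                            A_inv = NULL, start_sigma2a = 0.5,
                            merge_min = 1) {
  stopifnot(inherits(ped, "pedigree"))
  variance_update <- match.arg(variance_update)
  if (burn_in >= n_rounds) stop("burn_in must be smaller than n_rounds")
  if (thin < 1) stop("thin must be >= 1")

  des <- build_design(clean, model = model, merge_min = merge_min)
  y <- as.integer(des$y)
  if (all(y == 1L) || all(y == 0L))
    stop("all animals share one diagnosis; the threshold is unidentifiable")
  anim_code <- match(des$animal, ped$id)
  if (anyNA(anim_code))
    stop("recorded animal(s) missing from pedigree: ",
         paste(utils::head(des$animal[is.na(anim_code)], 5L),
               collapse = ", "))
  if (is.null(A_inv)) A_inv <- relationship_inverse(ped)

  ## CSR of the full symmetric A-inverse
  Ag <- methods::as(methods::as(A_inv, "generalMatrix"), "RsparseMatrix")
  q <- nrow(Ag)

  parents <- parent_subset(ped)
  if (variance_update == "parents_only") {
    if (length(parents) < 3L)
      stop("parental subset too small for parents_only variance update; ",
           "use variance_update = \"all_animals\"")
    ## every ancestor of a parent is itself a parent, so the parental
    ## subset is ancestrally closed and the relationship matrix of the
    ## subset pedigree equals the corresponding submatrix of A
    sub <- trace_ancestors(ped, parents)
    App_inv <- solve(relationship_matrix(sub))
    U_pp <- chol((App_inv + t(App_inv)) / 2)
    pidx <- match(sub$id, ped$id)
  } else {
    pidx <- integer(0)
    U_pp <- matrix(0, 0, 0)
  }

  XtX_inv <- chol2inv(chol(crossprod(des$X)))
  Uc <- chol((XtX_inv + t(XtX_inv)) / 2)

  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_threshold_cpp(y, des$X, anim_code - 1L,
                              Ag@p, Ag@j, Ag@x,
                              Uc, U_pp, pidx - 1L,
                              variance_update == "parents_only",
                              as.integer(n_rounds), as.integer(burn_in),
                              as.integer(thin),
                              as.numeric(prior$nu), as.numeric(prior$s2),
                              as.numeric(start_sigma2a))

  samples <- data.frame(round = res$round, sigma2_a = res$sigma2_a,
                        h2 = res$h2)
  ebv <- stats::setNames(res$ebv_mean, ped$id)
  fixef <- stats::setNames(res$beta_mean, colnames(des$X))

  structure(list(
    samples = samples,
    ebv = ebv,
    fixef = fixef,
    final_liability = stats::setNames(res$final_liability, des$animal),
    y = stats::setNames(y, des$animal),
    n_parents = length(parents),
    config = list(model = model, n_rounds = n_rounds, burn_in = burn_in,
                  thin = thin, seed = seed, prior = prior,
                  variance_update = variance_update,
                  start_sigma2a = start_sigma2a)
  ), class = "threshold_gibbs")
}

#' @export
print.threshold_gibbs <- function(x, ...) {
  cfg <- x$config
  cat("Bayesian threshold animal model (Gibbs sampler) - model",
      cfg$model, "\n")
  cat(sprintf("  %d rounds, %d burn-in, thin %d -> %d stored samples\n",
              cfg$n_rounds, cfg$burn_in, cfg$thin, nrow(x$samples)))
  cat(sprintf("  residual variance fixed at 1; variance update: %s (%d parents)\n",
              cfg$variance_update, x$n_parents))
  cat(sprintf("  posterior mean sigma2_a = %.3f, posterior mean h2 = %.3f\n",
              mean(x$samples$sigma2_a), mean(x$samples$h2)))
  invisible(x)
}

#' @export
summary.threshold_gibbs <- function(object, level = 0.95, ...) {
  out <- summarize_chain(object, level = level)
  class(out) <- c("summary.threshold_gibbs", "data.frame")
  out
}

#' @export
print.summary.threshold_gibbs <- function(x, ...) {
  cat("Posterior summaries (mean, HPD region, effective sample size):\n")
  print.data.frame(cbind(x[1L],
                         round(x[, c("mean", "hpd_low", "hpd_high")], 4),
                         ess = round(x$ess, 1)))
  invisible(x)
}

#' Trace plots for a Gibbs chain
#'
#' @param x a [threshold_gibbs()] object.
#' @param parameters which stored parameters to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.threshold_gibbs <- function(x, parameters = c("h2", "sigma2_a"), ...) {
  old <- graphics::par(mfrow = c(length(parameters), 1L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    graphics::plot(x$samples$round, x$samples[[p]], type = "l",
                   xlab = "round", ylab = p,
                   main = paste("Trace:", p), ...)
  }
  invisible(x)
}

#' @export
ebv.threshold_gibbs <- function(object, ...) object$ebv

#' @export
as.data.frame.threshold_gibbs <- function(x, ...) x$samples
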