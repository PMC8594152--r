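## Linear animal model on the observed 0/1 scale, fitted by average
## information REML with EM fallback, via the mixed model equations (MME).
##
## Model: y = X b + Z a + e,  a ~ N(0, sigma2_a * A),  e ~ N(0, sigma2_e * I)
## with A the pedigree additive relationship matrix. The restricted
## log-likelihood is evaluated through the MME coefficient matrix
## factorization, never through a dense N x N inverse of V.

#' Fixed-effect design for the three screening models
#'
#' Builds the response and full-rank fixed-effects design matrix for one of
#' the three standard model formulations on a cleaned dataset:
#' \describe{
#'   \item{model 1}{`y = Sex + Age + a + e` (age in completed years as a
#'     class effect)}
#'   \item{model 2}{`y = Sex + R_Year + Age + a + e` (adds diagnosis year as
#'     a class effect)}
#'   \item{model 3}{`y = Sex + R_Year + b * C_Age + a + e` (age as a
#'     centered linear covariate)}
#' }
#' Factors with a single observed level are dropped with a warning; age
#' classes with fewer than `merge_min` records are merged into the nearest
#' age class.
#'
#' @param clean a [clean_records()] dataset (columns `y`, `sex`,
#'   `age_years`, `age_continuous`, `diagnosis_year`, `animal`).
#' @param model 1, 2 or 3.
#' @param merge_min minimum records per age class before merging (default 1
#'   = no merging).
#' @return List with `y`, `X` (full column rank, with intercept), `animal`
#'   (ids, one per record) and `model`.
#' @export
build_design <- function(clean, model = 1, merge_min = 1) {
  stopifnot(model %in% 1:3)
  y <- as.numeric(clean$y)
  n <- length(y)

  age_cls <- clean$age_years
  if (merge_min > 1) age_cls <- merge_rare_classes(age_cls, merge_min)

  terms <- list(sex = factor(clean$sex))
  if (model %in% c(1, 2)) terms$age <- factor(age_cls)
  if (model %in% c(2, 3)) terms$year <- factor(clean$diagnosis_year)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(terms)) {
    f <- terms[[nm]]
    if (nlevels(droplevels(f)) < 2L) {
      warning("factor '", nm, "' has a single level; dropped from the design")
      next
    }
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(nm, levels(droplevels(f))[-1])
    X <- cbind(X, mm)
  }
  if (model == 3)
    X <- cbind(X, c_age = clean$age_continuous - mean(clean$age_continuous))

  ## drop aliased columns, keeping a full-rank reparameterization
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  list(y = y, X = X, animal = as.character(clean$animal), model = model)
}

merge_rare_classes <- function(cls, min_n) {
  repeat {
    tab <- table(cls)
    if (length(tab) < 2L || all(tab >= min_n)) break
    lv <- as.numeric(names(tab))
    worst <- which.min(tab)
    target <- setdiff(seq_along(lv), worst)
    nearest <- target[which.min(abs(lv[target] - lv[worst]))]
    cls[cls == lv[worst]] <- lv[nearest]
  }
  cls
}

#' Fit the linear animal model by AI-REML
#'
#' Estimates the additive genetic and residual variances of a Gaussian
#' animal model on the observed 0/1 diagnosis by restricted maximum
#' likelihood, using average-information (AI) updates with an EM-REML
#' fallback whenever an AI step would leave the parameter space. Standard
#' errors come from the inverse AI matrix at convergence, the heritability
#' standard error by the delta method, and breeding values for all pedigree
#' animals from the mixed model equations at the converged variances.
#'
#' @param clean a [clean_records()] dataset.
#' @param ped a [pedigree()] covering all recorded animals.
#' @param model fixed-effects model, 1, 2 or 3 (see [build_design()]).
#' @param A_inv optional precomputed [relationship_inverse()] for `ped`.
#' @param start optional starting values `c(sigma2_a, sigma2_e)`; default
#'   splits `var(y)` equally.
#' @param tol_par,tol_grad convergence tolerances on the relative parameter
#'   change and the gradient norm.
#' @param max_iter maximum number of iterations (default 200).
#' @param merge_min passed to [build_design()].
#' @param verbose print iteration progress.
#' @return Object of class `"reml_animal"` with components `sigma2`
#'   (named: `a`, `e`), `se`, `vcov` (2x2, from the AI matrix), `h2_obs`,
#'   `se_h2`, `loglik`, `fixef`, `ebv` (named vector over all pedigree
#'   animals), `iterations`, `converged`, `boundary`, `gradient`, `model`.
#' @seealso [dempster_lerner()] to move the estimate to the liability scale,
#'   [threshold_gibbs()] for the Bayesian threshold counterpart.
#' @export
reml_animal <- function(clean, ped, model = 1, A_inv = NULL, start = NULL,
                        tol_par = 1e-8, tol_grad = 1e-6, max_iter = 200,
                        merge_min = 1, verbose = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  des <- build_design(clean, model = model, merge_min = merge_min)
  if (length(des$y) < 3L || length(unique(des$y)) < 2L)
    stop("response is constant; variance components not identifiable")
  anim_code <- match(des$animal, ped$id)
  if (anyNA(anim_code))
    stop("recorded animal(s) missing from pedigree: ",
         paste(utils::head(des$animal[is.na(anim_code)], 5L),
               collapse = ", "))
  if (is.null(A_inv)) A_inv <- relationship_inverse(ped)

  fit <- reml_ai_core(des$y, des$X, anim_code, A_inv,
                      start = start, tol_par = tol_par,
                      tol_grad = tol_grad, max_iter = max_iter,
                      verbose = verbose)
  names(fit$ebv) <- ped$id
  fit$model <- model
  fit$call <- match.call()
  fit
}

## core AI-REML given response, full-rank X, animal codes (1..q) and sparse
## A-inverse; q = number of pedigree animals
reml_ai_core <- function(y, X, anim, A_inv, start = NULL,
                         tol_par = 1e-8, tol_grad = 1e-6,
                         max_iter = 200, verbose = FALSE) {
  n <- length(y)
  p <- ncol(X)
  q <- nrow(A_inv)
  Ainv <- as.matrix(A_inv)          # dense at study scale
  ldet_Ainv <- as.numeric(Matrix::determinant(A_inv, logarithm = TRUE)$modulus)

  ## record incidence: Z is n x q with one 1 per row; Z't aggregates by animal
  nrec <- tabulate(anim, nbins = q)
  zt <- function(v) {                      # Z'v as a length-q vector
    rs <- rowsum(v, group = anim)
    out <- numeric(q)
    out[as.integer(rownames(rs))] <- rs[, 1L]
    out
  }
  XtX <- crossprod(X)
  rsX <- rowsum(X, group = anim)
  XtZ <- matrix(0, p, q)
  XtZ[, as.integer(rownames(rsX))] <- t(rsX)
  Xty <- crossprod(X, y)[, 1L]
  Zty <- zt(y)
  yty <- sum(y * y)
  ax <- seq_len(p)
  aa <- p + seq_len(q)

  vy <- stats::var(y)
  th <- if (is.null(start)) c(vy / 2, vy / 2) else as.numeric(start)
  stopifnot(length(th) == 2L, all(th > 0))
  floor_v <- 1e-8 * vy
  boundary <- FALSE
  converged <- FALSE
  push_down <- 0L
  iter <- 0L
  grad <- c(NA_real_, NA_real_)
  AI <- diag(2)

  ## solve the MME for a given rhs vector (length p + q), reusing a Cholesky
  mme_solve <- function(ch, rhs) backsolve(ch, backsolve(ch, rhs,
                                                         transpose = TRUE))

  repeat {
    iter <- iter + 1L
    s2a <- th[1L]; s2e <- th[2L]
    C <- matrix(0, p + q, p + q)
    C[ax, ax] <- XtX / s2e
    C[ax, aa] <- XtZ / s2e
    C[aa, ax] <- t(XtZ) / s2e
    C[aa, aa] <- Ainv / s2a
    diag(C)[aa] <- diag(C)[aa] + nrec / s2e
    ch <- chol(C)
    rhs <- c(Xty, Zty) / s2e
    sol <- mme_solve(ch, rhs)
    bhat <- sol[ax]; ahat <- sol[aa]
    yPy <- yty / s2e - sum(sol * rhs)
    ldetC <- 2 * sum(log(diag(ch)))
    loglik <- -0.5 * (n * log(s2e) + q * log(s2a) - ldet_Ainv +
                      ldetC + yPy + (n - p) * log(2 * pi))

    Cinv <- chol2inv(ch)
    Tr <- sum(Cinv[aa, aa] * Ainv)            # tr(A^-1 C^aa)
    aAa <- sum(ahat * (Ainv %*% ahat))
    ehat <- y - X %*% bhat - ahat[anim]
    ete <- sum(ehat * ehat)

    grad <- c(-0.5 * (q / s2a - Tr / s2a^2 - aAa / s2a^2),
              -0.5 * ((n - p - q + Tr / s2a) / s2e - ete / s2e^2))

    ## average information from working vectors f_a = Z ahat / s2a,
    ## f_e = Py = ehat / s2e;  P f = (f - X b_f - Z a_f) / s2e
    fa <- ahat[anim] / s2a
    fe <- as.numeric(ehat) / s2e
    Pf <- function(f) {
      rhs_f <- c(crossprod(X, f)[, 1L], zt(f))
      sol_f <- mme_solve(ch, rhs_f / s2e)
      (f - X %*% sol_f[ax] - sol_f[aa][anim]) / s2e
    }
    Pfa <- Pf(fa); Pfe <- Pf(fe)
    AI <- 0.5 * matrix(c(sum(fa * Pfa), sum(fa * Pfe),
                         sum(fa * Pfe), sum(fe * Pfe)), 2L, 2L)

    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    new_th <- NULL
    used_em <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      ## AI step with halving to stay inside the parameter space
      kappa <- 1
      while (kappa >= 1 / 64) {
        cand <- th + kappa * step
        if (all(is.finite(cand)) && all(cand > floor_v)) {
          new_th <- cand
          break
        }
        kappa <- kappa / 2
      }
    }
    if (is.null(new_th)) {
      ## EM-REML fallback always stays in the space
      new_th <- c((aAa + Tr) / q, s2e * yPy / (n - p))
      used_em <- TRUE
      ## AI persistently pushing sigma2_a negative while EM creeps down:
      ## the optimum sits on the boundary; pin instead of crawling
      if (!is.null(step) && step[1L] < 0 && new_th[1L] < th[1L]) {
        push_down <- push_down + 1L
        if (push_down >= 3L) new_th[1L] <- floor_v
      }
    } else {
      push_down <- 0L
    }
    if (new_th[1L] <= floor_v) {
      new_th[1L] <- floor_v
      boundary <- TRUE
    }
    if (verbose)
      message(sprintf("iter %d: s2a=%.6g s2e=%.6g logL=%.6f |g|=%.3g%s",
                      iter, th[1L], th[2L], loglik,
                      sqrt(sum(grad^2)), if (used_em) " [EM]" else ""))

    relchg <- max(abs(new_th - th) / pmax(abs(th), 1e-12))
    th <- new_th
    if (relchg < tol_par && sqrt(sum(grad^2)) < tol_grad) {
      converged <- TRUE
      break
    }
    ## constrained optimum on sigma2_a >= 0: the free-gradient criterion
    ## cannot be met there; accept once sigma2_e has settled
    if (boundary && th[1L] <= floor_v * (1 + 1e-9) &&
        abs(new_th[2L] - s2e) / s2e < 1e-8) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  if (!converged)
    warning("AI-REML did not meet the convergence tolerances in ",
            iter, " iterations (|grad| = ", signif(sqrt(sum(grad^2)), 3),
            "); estimates returned with diagnostics")
  if (th[1L] <= floor_v * (1 + 1e-6)) boundary <- TRUE

  s2a <- th[1L]; s2e <- th[2L]
  vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  h2 <- s2a / (s2a + s2e)
  gh <- c(s2e, -s2a) / (s2a + s2e)^2
  se_h2 <- sqrt(max(0, drop(t(gh) %*% vc %*% gh)))

  ## final solve for fixed effects, EBVs and log-likelihood at the optimum
  C <- matrix(0, p + q, p + q)
  C[ax, ax] <- XtX / s2e
  C[ax, aa] <- XtZ / s2e
  C[aa, ax] <- t(XtZ) / s2e
  C[aa, aa] <- Ainv / s2a
  diag(C)[aa] <- diag(C)[aa] + nrec / s2e
  ch <- chol(C)
  rhs <- c(Xty, Zty) / s2e
  sol <- mme_solve(ch, rhs)
  yPy <- yty / s2e - sum(sol * rhs)
  loglik <- -0.5 * (n * log(s2e) + q * log(s2a) - ldet_Ainv +
                    2 * sum(log(diag(ch))) + yPy + (n - p) * log(2 * pi))
  fixef <- stats::setNames(sol[ax], colnames(X))

  structure(list(
    sigma2 = c(a = s2a, e = s2e),
    se = c(a = se[1L], e = se[2L]),
    vcov = vc,
    h2_obs = h2, se_h2 = se_h2,
    loglik = loglik,
    fixef = fixef,
    ebv = sol[aa],
    n = n, n_animals = q, rank_X = p,
    iterations = iter, converged = converged, boundary = boundary,
    gradient = grad
  ), class = "reml_animal")
}

#' @export
print.reml_animal <- function(x, ...) {
  cat("Linear animal model (AI-REML)",
      if (!is.null(x$model)) paste0("- model ", x$model), "\n")
  cat(sprintf("  records: %d, pedigree animals: %d\n", x$n, x$n_animals))
  cat(sprintf("  sigma2_a = %.4f (SE %.4f)\n", x$sigma2["a"], x$se["a"]))
  cat(sprintf("  sigma2_e = %.4f (SE %.4f)\n", x$sigma2["e"], x$se["e"]))
  cat(sprintf("  h2 (observed scale) = %.3f (SE %.3f)\n", x$h2_obs, x$se_h2))
  cat(sprintf("  REML log-likelihood %.3f after %d iterations (%s)%s\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) " [variance at boundary]" else ""))
  invisible(x)
}

#' @export
summary.reml_animal <- function(object, ...) {
  print(object)
  cat("Fixed effects:\n")
  print(round(object$fixef, 4))
  invisible(object)
}

#' @export
coef.reml_animal <- function(object, ...) object$fixef

#' @export
logLik.reml_animal <- function(object, ...) {
  structure(object$loglik, df = 2L + object$rank_X, class = "logLik")
}

#' @export
vcov.reml_animal <- function(object, ...) {
  v <- object$vcov
  dimnames(v) <- list(c("sigma2_a", "sigma2_e"), c("sigma2_a", "sigma2_e"))
  v
}

#' Estimated breeding values
#'
#' @param object a fitted model (`reml_animal` or `threshold_gibbs`).
#' @param ... unused.
#' @return Named numeric vector of breeding values over all pedigree animals
#'   (posterior means for the Gibbs fit).
#' @export
ebv <- function(object, ...) UseMethod("ebv")

#' @export
ebv.reml_animal <- function(object, ...) object$ebv
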