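#' Additive relationship matrix (tabular method)
#'
#' Computes the dense numerator relationship matrix A by the tabular
#' recursion: for animal j with parents s, d (in code order, parents first),
#' `A[i, j] = (A[i, s] + A[i, d]) / 2` for `i < j` and
#' `A[j, j] = 1 + A[s, d] / 2`; an unknown parent contributes 0.
#'
#' @param ped a [pedigree()].
#' @return A dense symmetric matrix with dimnames set to animal ids and an
#'   attribute `"inbreeding"` holding `diag(A) - 1`.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  A <- .tabular_A_cpp(ped$sire, ped$dam)
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "inbreeding") <- diag(A) - 1
  A
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F, computed by the same tabular
#' recursion that defines the additive relationship matrix, so that
#' `inbreeding(ped)` equals `diag(relationship_matrix(ped)) - 1` exactly.
#' Founders (and any animal with an unknown parent) have F = 0.
#'
#' @param ped a [pedigree()].
#' @return Named numeric vector of F values in `[0, 1)`, in code order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(.tabular_F_cpp(ped$sire, ped$dam), ped$id)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles the inverse of A directly from the pedigree by Henderson's
#' rules, with Mendelian-sampling variances that account for parental
#' inbreeding: animal j with both parents known contributes with weight
#' `1 / (0.5 - 0.25 (F_s + F_d))`, with one parent known
#' `1 / (0.75 - 0.25 F_p)`, and with no known parent `1`.
#'
#' @param ped a [pedigree()].
#' @param f inbreeding coefficients in code order; computed with
#'   [inbreeding()] if omitted.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with dimnames set
#'   to animal ids.
#' @export
relationship_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(f)) f <- inbreeding(ped)
  n <- nrow(ped)
  stopifnot(length(f) == n)
  s <- ped$sire
  d <- ped$dam

  both <- s > 0L & d > 0L
  one_s <- s > 0L & d == 0L
  one_d <- d > 0L & s == 0L
  msv <- rep(1, n)
  msv[both] <- 0.5 - 0.25 * (f[s[both]] + f[d[both]])
  msv[one_s] <- 0.75 - 0.25 * f[s[one_s]]
  msv[one_d] <- 0.75 - 0.25 * f[d[one_d]]
  alpha <- 1 / msv

  j <- seq_len(n)
  hs <- s > 0L   # has known sire
  hd <- d > 0L
  ii <- c(j,                               # (j, j)
          s[hs], j[hs],                    # (s, j) and (j, s)
          d[hd], j[hd],                    # (d, j) and (j, d)
          s[hs], d[hd],                    # (s, s), (d, d)
          s[both], d[both])                # (s, d) and (d, s)
  jj <- c(j,
          j[hs], s[hs],
          j[hd], d[hd],
          s[hs], d[hd],
          d[both], s[both])
  xx <- c(alpha,
          rep(-0.5 * alpha[hs], 2L),
          rep(-0.5 * alpha[hd], 2L),
          0.25 * alpha[hs], 0.25 * alpha[hd],
          rep(0.25 * alpha[both], 2L))
  ## duplicated (i, j) pairs are summed by sparseMatrix
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv, uplo = "U")
}
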