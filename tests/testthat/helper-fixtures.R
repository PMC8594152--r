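## small pedigree and record builders used across tests

## random acyclic pedigree: first nf animals are founders, later animals
## draw parents among earlier animals of the right sex
random_pedigree <- function(n, nf = 20) {
  id <- paste0("X", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female")
  for (j in (nf + 1):n) {
    males <- which(sex[seq_len(j - 1)] == "male")
    females <- which(sex[seq_len(j - 1)] == "female")
    sire[j] <- id[if (length(males) == 1) males else sample(males, 1)]
    dam[j] <- id[if (length(females) == 1) females else sample(females, 1)]
  }
  pedigree(id, sire, dam, sex = sex)
}

## trio A, B -> C
trio_pedigree <- function() {
  pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
           dam = c(NA, NA, "B"), sex = c("male", "female", "female"))
}

## minimal clean-ready records for a pedigree with birth dates
simple_records <- function(animal, exam_date, diagnosis, grade = NULL) {
  exam_records(animal = animal, exam_date = exam_date,
               diagnosis = diagnosis, grade = grade)
}

## dense-matrix restricted log-likelihood oracle for the univariate animal
## model (direct V-based evaluation, independent of the MME code path)
dense_reml_loglik <- function(y, X, Arec, s2a, s2e) {
  n <- length(y)
  V <- s2a * Arec + s2e * diag(n)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  -0.5 * (as.numeric(determinant(V)$modulus) +
          as.numeric(determinant(XVX)$modulus) +
          drop(t(y) %*% P %*% y) + (n - ncol(X)) * log(2 * pi))
}

## balanced paternal half-sib design: ns sires, each with noff offspring
## from unknown dams; Gaussian trait with heritability h2
half_sib_data <- function(ns, noff, h2, mu = 10) {
  sires <- paste0("S", seq_len(ns))
  offspring <- paste0("O", seq_len(ns * noff))
  ped <- pedigree(id = c(sires, offspring),
                  sire = c(rep(NA, ns), rep(sires, each = noff)),
                  dam = rep(NA, ns + ns * noff),
                  sex = c(rep("male", ns),
                          rep(c("male", "female"), length.out = ns * noff)))
  s2a <- h2; s2e <- 1 - h2
  a_s <- rnorm(ns, 0, sqrt(s2a))
  a_o <- 0.5 * rep(a_s, each = noff) + rnorm(ns * noff, 0, sqrt(0.75 * s2a))
  y <- mu + a_o + rnorm(ns * noff, 0, sqrt(s2e))
  sire_of <- rep(seq_len(ns), each = noff)
  list(ped = ped, animal = offspring, y = y, sire = sire_of)
}

## ANOVA sire-model heritability for a balanced half-sib design
anova_h2 <- function(y, sire) {
  noff <- length(y) / length(unique(sire))
  msb <- noff * var(tapply(y, sire, mean))
  msw <- mean(tapply(y, sire, var))
  s2s <- (msb - msw) / noff
  4 * s2s / (s2s + msw)
}

## fit the REML core directly on arbitrary y/X/pedigree (bypassing the
## cleaning step) - thin wrapper used by oracle tests
fit_animal_raw <- function(y, X, animal, ped, ...) {
  des_anim <- match(animal, ped$id)
  stopifnot(!anyNA(des_anim))
  liabped:::reml_ai_core(y, X, des_anim, relationship_inverse(ped), ...)
}
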