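## Synthetic pedigree + examination-record generator. Emulates a
## kennel-club screening registry: a multi-generation, litter-structured
## pedigree; a Gaussian liability with additive genetic effects a ~
## N(0, sigma2_a * A) and fixed sex/age/year effects; binary diagnoses from
## a threshold placed at the prevalence quantile; repeated examinations with
## occasional conflicting results; sporadic missing dates.

#' Configuration for the registry simulator
#'
#' Defaults emulate the scale and structure of a national toy-breed
#' screening registry over ~15 years: a few hundred founders' descendants
#' across 4 generations (~800 litters, pedigree of ~2700 animals, ~1150
#' examined), trait frequency near 0.145, and a liability-scale
#' heritability of 0.65.
#'
#' @param n_founders founder animals (generation 0).
#' @param n_generations number of offspring generations.
#' @param imports_per_generation unrelated founder animals entering the
#'   parent pool at each later generation (defaults to `n_founders`).
#'   Registries of small breeds are continuously topped up with imported
#'   or previously unregistered ancestors; without them the pedigree
#'   collapses onto a handful of founder lineages and the realized genetic
#'   variance drifts far more between replicates than registry data show
#'   (the emulated registry has ~2.9 pedigree ancestors per examined dog).
#' @param litters_per_generation litters produced per generation.
#' @param litter_size_mean mean litter size (sizes are 1 + Poisson(mean-1)).
#' @param prop_sires_used fraction of available males used as sires per
#'   generation (smaller values give larger paternal half-sib families).
#' @param sex_ratio probability an offspring is male.
#' @param h2_liability true liability-scale heritability in [0, 1).
#' @param prevalence target trait frequency in (0, 1).
#' @param sex_effect liability difference male - female (liability SD units).
#' @param age_slope liability change per year of age at first examination.
#' @param year_sd SD of i.i.d. calendar-year effects on the liability.
#' @param exam_prob probability a non-founder is ever examined.
#' @param re_exam_prob per-dog probability parameter of the geometric number
#'   of re-examinations (expected extra exams = re_exam_prob /
#'   (1 - re_exam_prob)).
#' @param conflict_prob probability that an affected, multiply-examined dog
#'   reads unaffected at its earliest examination(s) (missed early or
#'   late-developing cases; drives unaffected-to-affected transitions).
#' @param reverse_error_prob probability that an affected, multiply-examined
#'   dog's last examination is recorded unaffected (certificate error;
#'   drives the rarer affected-to-unaffected transitions).
#' @param missing_exam_date_prob per-exam probability of a missing date.
#' @param missing_birth_date_prob per-dog probability of a missing birth
#'   date.
#' @param grade_probs probabilities of (mild, moderate, severe, ungraded)
#'   for an affected dog's recorded grade.
#' @param base_year first birth year of the founders.
#' @param seed integer seed used by [simulate_population()].
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 4,
                       imports_per_generation = NULL,
                       litters_per_generation = 200,
                       litter_size_mean = 3.2,
                       prop_sires_used = 0.3,
                       sex_ratio = 0.5,
                       h2_liability = 0.65,
                       prevalence = 0.145,
                       sex_effect = 0.1,
                       age_slope = 0.05,
                       year_sd = 0.1,
                       exam_prob = 0.45,
                       re_exam_prob = 0.48,
                       conflict_prob = 0.3,
                       reverse_error_prob = 0.02,
                       missing_exam_date_prob = 0.003,
                       missing_birth_date_prob = 0.003,
                       grade_probs = c(mild = 0.869, moderate = 0.024,
                                       severe = 0.006, ungraded = 0.101),
                       base_year = 2005,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$imports_per_generation))
    cfg$imports_per_generation <- cfg$n_founders
  if (cfg$imports_per_generation < 0) stop("imports must be non-negative")
  probs <- c(cfg$sex_ratio, cfg$prevalence, cfg$exam_prob, cfg$re_exam_prob,
             cfg$conflict_prob, cfg$reverse_error_prob,
             cfg$missing_exam_date_prob, cfg$missing_birth_date_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  if (cfg$h2_liability < 0 || cfg$h2_liability >= 1)
    stop("h2_liability must be in [0, 1)")
  if (cfg$n_founders < 2) stop("need at least 2 founders")
  if (cfg$n_generations < 1) stop("need at least 1 offspring generation")
  if (abs(sum(cfg$grade_probs) - 1) > 1e-8)
    stop("grade_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

## breeding values along an ordered pedigree: founders ~ N(0, s2a);
## non-founders get the parental average plus a Mendelian-sampling deviation
## whose variance accounts for parental inbreeding, so that cov(bv) = s2a * A
draw_breeding_values <- function(ped, s2a) {
  n <- nrow(ped)
  if (s2a == 0) return(numeric(n))
  f <- inbreeding(ped)
  bv <- numeric(n)
  for (j in seq_len(n)) {
    sj <- ped$sire[j]; dj <- ped$dam[j]
    if (sj == 0L && dj == 0L) {
      bv[j] <- stats::rnorm(1L, 0, sqrt(s2a))
    } else {
      if (sj > 0L && dj > 0L) {
        pa <- (bv[sj] + bv[dj]) / 2
        msv <- 0.5 * (1 - (f[sj] + f[dj]) / 2)
      } else if (sj > 0L) {
        pa <- bv[sj] / 2; msv <- 0.75 - 0.25 * f[sj]
      } else {
        pa <- bv[dj] / 2; msv <- 0.75 - 0.25 * f[dj]
      }
      bv[j] <- pa + stats::rnorm(1L, 0, sqrt(s2a * msv))
    }
  }
  bv
}

#' Simulate a screened population
#'
#' Generates a litter-structured pedigree, true breeding values and
#' liabilities under the additive threshold model, and examination records
#' with repeated, occasionally conflicting diagnoses and sporadic missing
#' dates. Founders draw breeding values from N(0, sigma2_a); a non-founder
#' draws the parental average plus a Mendelian-sampling deviation
#' N(0, sigma2_a/2 * (1 - (F_s + F_d)/2)), the same genetic model the
#' relationship-matrix machinery assumes. The threshold is the Gaussian
#' quantile of the target prevalence at covariate means, so the realized
#' prevalence is random around the target, as in real registries.
#'
#' @param cfg a [sim_config()].
#' @return List of class `"sim_population"`: `pedigree` (a [pedigree()]),
#'   `records` (an [exam_records()] data frame), `truth` (data frame with
#'   `animal`, `bv`, `liability`, `status`, `examined`), `threshold`,
#'   `realized_prevalence` (among examined dogs' true status) and `config`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## ---- pedigree structure ----
  id <- paste0("D", seq_len(cfg$n_founders))
  sire <- dam <- rep(NA_character_, cfg$n_founders)
  sex <- ifelse(stats::runif(cfg$n_founders) < cfg$sex_ratio,
                "male", "female")
  ## guarantee both sexes among founders
  sex[1:2] <- c("male", "female")
  gen <- rep(0L, cfg$n_founders)
  litter <- rep(NA_integer_, cfg$n_founders)
  n_litters <- 0L

  for (g in seq_len(cfg$n_generations)) {
    ## imported / previously unregistered ancestors join the parent pool
    if (g > 1L && cfg$imports_per_generation > 0) {
      ni <- cfg$imports_per_generation
      id <- c(id, paste0("D", length(id) + seq_len(ni)))
      sire <- c(sire, rep(NA_character_, ni))
      dam <- c(dam, rep(NA_character_, ni))
      sex <- c(sex, ifelse(stats::runif(ni) < cfg$sex_ratio,
                           "male", "female"))
      gen <- c(gen, rep(g - 1L, ni))
      litter <- c(litter, rep(NA_integer_, ni))
    }
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (!length(males) || !length(females))
      stop("a generation ran out of one sex; increase n_founders")
    n_sires <- max(1L, round(cfg$prop_sires_used * length(males)))
    sires_pool <- sample(males, n_sires)
    for (l in seq_len(cfg$litters_per_generation)) {
      n_litters <- n_litters + 1L
      s <- if (length(sires_pool) == 1L) sires_pool else
        sample(sires_pool, 1L)
      d <- if (length(females) == 1L) females else sample(females, 1L)
      size <- 1L + stats::rpois(1L, max(0, cfg$litter_size_mean - 1))
      new_ids <- paste0("D", length(id) + seq_len(size))
      id <- c(id, new_ids)
      sire <- c(sire, rep(id[s], size))
      dam <- c(dam, rep(id[d], size))
      sex <- c(sex, ifelse(stats::runif(size) < cfg$sex_ratio,
                           "male", "female"))
      gen <- c(gen, rep(g, size))
      litter <- c(litter, rep(n_litters, size))
    }
  }
  n <- length(id)
  birth_year <- cfg$base_year + 3L * gen
  birth <- as.Date(paste0(birth_year, "-01-01")) +
    sample.int(330L, n, replace = TRUE)

  ped <- pedigree(id, sire, dam, sex = sex, birth = birth)
  ord <- match(ped$id, id)              # pedigree row -> simulation index

  ## ---- breeding values along the pedigree (code order) ----
  s2a <- cfg$h2_liability
  bv <- draw_breeding_values(ped, s2a)

  ## ---- examinations and liabilities ----
  is_founder <- ped$sire == 0L & ped$dam == 0L
  examined <- !is_founder & stats::runif(n) < cfg$exam_prob
  age_first <- stats::runif(n, 1, 6)
  n_extra <- stats::rgeom(n, 1 - cfg$re_exam_prob)
  exam_year_first <- as.integer(format(ped$birth, "%Y")) +
    floor(age_first)

  all_years <- seq(min(exam_year_first, na.rm = TRUE) - 1L,
                   max(exam_year_first + n_extra + 2L, na.rm = TRUE))
  year_eff <- stats::setNames(stats::rnorm(length(all_years), 0,
                                           cfg$year_sd), all_years)

  mu_sex <- ifelse(ped$sex == "male", cfg$sex_effect, 0) -
    cfg$sex_ratio * cfg$sex_effect
  mean_age <- mean(age_first)
  liability <- mu_sex +
    cfg$age_slope * (age_first - mean_age) +
    year_eff[as.character(exam_year_first)] +
    bv + stats::rnorm(n, 0, sqrt(1 - s2a))
  threshold <- stats::qnorm(1 - cfg$prevalence)
  status <- liability > threshold

  rec_animal <- character(0); rec_date <- as.Date(character(0))
  rec_diag <- character(0); rec_grade <- character(0)
  grade_lv <- c("mild", "moderate", "severe", "none")
  for (j in which(examined)) {
    k <- 1L + n_extra[j]
    dates <- ped$birth[j] + round(age_first[j] * 365.25) +
      round(c(0, cumsum(stats::runif(k - 1L, 0.8, 1.5) * 365.25)))
    diag <- rep(if (status[j]) "affected" else "unaffected", k)
    if (status[j] && k >= 2L) {
      if (stats::runif(1L) < cfg$conflict_prob) {
        cp <- sample.int(k - 1L, 1L)       # exams 1..cp read unaffected
        diag[seq_len(cp)] <- "unaffected"
      }
      if (stats::runif(1L) < cfg$reverse_error_prob)
        diag[k] <- "unaffected"
    }
    grade <- rep("none", k)
    if (status[j]) {
      g <- sample(grade_lv, 1L, prob = cfg$grade_probs)
      grade[diag == "affected"] <- g
    }
    drop_date <- stats::runif(k) < cfg$missing_exam_date_prob
    dates[drop_date] <- NA
    rec_animal <- c(rec_animal, rep(ped$id[j], k))
    rec_date <- c(rec_date, dates)
    rec_diag <- c(rec_diag, diag)
    rec_grade <- c(rec_grade, grade)
  }

  records <- exam_records(rec_animal, rec_date, rec_diag, rec_grade)
  truth <- data.frame(animal = ped$id, bv = bv, liability = liability,
                      status = status, examined = examined,
                      litter = litter[ord], stringsAsFactors = FALSE)

  ## sporadic missing birth dates (re-build pedigree with the NA dates;
  ## truth and records are keyed by animal id, so re-coding is harmless)
  drop_birth <- stats::runif(n) < cfg$missing_birth_date_prob
  if (any(drop_birth & examined)) {
    b2 <- ped$birth
    b2[drop_birth & examined] <- NA
    ped <- pedigree(ped$id, ped$sire_id, ped$dam_id, sex = ped$sex,
                    birth = b2)
  }

  structure(list(pedigree = ped, records = records, truth = truth,
                 threshold = threshold,
                 realized_prevalence = mean(status[examined]),
                 config = cfg),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated screened population\n")
  cat(sprintf("  pedigree: %d animals; examined: %d; records: %d\n",
              nrow(x$pedigree), sum(x$truth$examined), nrow(x$records)))
  cat(sprintf("  true liability h2 = %.2f; realized prevalence = %.3f (target %.3f)\n",
              x$config$h2_liability, x$realized_prevalence,
              x$config$prevalence))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (simulate, clean, linear AI-REML with
#' Dempster-Lerner conversion and, optionally, the threshold-model Gibbs
#' sampler) over independent replicates, returning one row per replicate.
#' Replicate r uses seed `cfg$seed + r - 1`.
#'
#' @param cfg a [sim_config()]; its `h2_liability` is the recovery truth.
#' @param n_replicates number of independent replicates.
#' @param model fixed-effects model (1, 2 or 3).
#' @param run_gibbs also run the Gibbs sampler per replicate (slower).
#' @param gibbs_rounds,gibbs_burn_in,gibbs_thin chain configuration used
#'   when `run_gibbs = TRUE` (desk-scale defaults 55,000 / 5,000 / 10).
#' @param hpd_level HPD probability content.
#' @param merge_min passed to [build_design()] (default 5: with one age
#'   class per integer year, small synthetic samples otherwise produce
#'   near-empty classes).
#' @return Data frame with one row per replicate: realized prevalence and
#'   sample size, observed-scale REML estimate and SE, its liability-scale
#'   conversion, and (if run) the Gibbs posterior mean, HPD bounds, ESS and
#'   EBV correlations between the two model families.
#' @export
recovery_experiment <- function(cfg, n_replicates = 10, model = 1,
                                run_gibbs = FALSE,
                                gibbs_rounds = 55000, gibbs_burn_in = 5000,
                                gibbs_thin = 10, hpd_level = 0.95,
                                merge_min = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- vector("list", n_replicates)
  warm <- NULL        # previous replicate's estimates speed up convergence
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    pop <- simulate_population(cfg_r)
    clean <- clean_records(pop$records, pop$pedigree)
    ## as in registry practice: restrict to examined animals + ancestors
    ped <- trace_ancestors(pop$pedigree, clean$animal)
    A_inv <- relationship_inverse(ped)
    fit <- reml_animal(clean, ped, model = model, A_inv = A_inv,
                       merge_min = merge_min, start = warm)
    if (fit$converged && !fit$boundary &&
        fit$h2_obs > 0.02 && fit$h2_obs < 0.9)
      warm <- unname(fit$sigma2)
    p_hat <- mean(clean$y)
    conv <- dempster_lerner(fit$h2_obs, fit$se_h2, p = p_hat)
    row <- data.frame(
      replicate = r, seed = cfg_r$seed,
      true_h2_liability = cfg$h2_liability,
      n_records = nrow(clean), prevalence = p_hat,
      h2_obs = fit$h2_obs, se_h2_obs = fit$se_h2,
      h2_liab_converted = conv$h2_liab, se_h2_liab = conv$se_liab,
      reml_converged = fit$converged
    )
    if (run_gibbs) {
      gb <- threshold_gibbs(clean, ped, model = model,
                            n_rounds = gibbs_rounds,
                            burn_in = gibbs_burn_in, thin = gibbs_thin,
                            seed = cfg_r$seed, A_inv = A_inv,
                            merge_min = merge_min)
      sm <- summarize_chain(gb, level = hpd_level)
      h2row <- sm[sm$parameter == "h2", ]
      cmp <- compare_ebv(ebv(fit), ebv(gb))
      row$h2_gibbs_mean <- h2row$mean
      row$h2_hpd_low <- h2row$hpd_low
      row$h2_hpd_high <- h2row$hpd_high
      row$h2_ess <- h2row$ess
      row$ebv_pearson <- cmp$pearson
      row$ebv_spearman <- cmp$spearman
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
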