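---
title: "Heritability of a binary threshold trait on a pedigree: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of a binary threshold trait on a pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabped)
```

## The problem

Veterinary screening registries record binary diagnoses (affected /
unaffected) on pedigreed animals, often with repeated examinations per
animal and incomplete metadata. `liabped` estimates how heritable such a
trait is, using the two model families that are standard in animal
breeding, and makes their results comparable on a single scale:

1. a **linear animal model** fitted by REML directly on the 0/1 diagnosis
   (the "observed scale"), and
2. a **Bayesian threshold (liability) model** fitted by Gibbs sampling, in
   which a latent Gaussian liability determines the phenotype through a
   fixed threshold.

The observed-scale heritability depends on the trait frequency, so the
linear estimate is translated to the liability scale with the classical
Dempster–Lerner formula before comparison.

## Models

### Linear animal model

For animal \(i\) with diagnosis \(y_i \in \{0,1\}\):

\[ y = Xb + Za + e, \qquad a \sim N(0, \sigma^2_a A), \quad
   e \sim N(0, \sigma^2_e I), \]

where \(A\) is the additive (numerator) relationship matrix derived from
the pedigree. Three fixed-effect formulations are supported, matching
common registry practice: model 1 uses sex and age-in-years classes;
model 2 adds diagnosis-year classes; model 3 replaces the age classes with
a centred linear age covariate. The observed-scale heritability is
\(h^2_o = \sigma^2_a / (\sigma^2_a + \sigma^2_e)\).

Treating a Bernoulli response as Gaussian is a deliberate, classical
choice: the linear animal model is fast, its breeding values are BLUPs,
and its estimate moves to the liability scale by the Dempster–Lerner
conversion

\[ h^2_l = \frac{h^2_o\, p (1 - p)}{z^2}, \]

with \(p\) the trait frequency and \(z\) the standard-normal density at the
threshold \(\Phi^{-1}(1-p)\). The same factor scales the standard error.
`dempster_lerner()` uses the full-precision ordinate by default; a
`z_override` argument exists because published tables are sometimes
computed with a truncated ordinate (e.g. 0.227 instead of 0.22792 at
\(p = 0.145\)), and reproducing such a table requires using the same value.

It is worth knowing that this formula is a *linearization*. Under the
threshold model, relatives with additive relationship \(r\) have
observed-scale covariance \(\Phi_2(t, t; r h^2_l) - p^2\), which is convex
in the liability correlation: for first-degree relatives at \(p = 0.145\)
and \(h^2_l \approx 0.65\) the exact covariance exceeds the linear value
\(z^2 r h^2_l\) by about 19%. Variance-component estimators whose
information comes mostly from parent–offspring and full-sib pairs
therefore converge to a somewhat larger observed-scale heritability than
the Dempster–Lerner value. `observed_h2_exact()` computes the exact
pair-implied observed-scale heritability (by one-dimensional quadrature of
the bivariate normal tail) and `liability_h2_for_observed()` inverts it;
the package's own recovery experiments calibrate their simulations through
this exact mapping, while the analysis pipeline reports the classical
Dempster–Lerner conversion, as registry studies do.

### Threshold model

The Bayesian threshold model assumes a latent liability
\(l = X\beta + a + e\) with \(e \sim N(0, I)\) and declares an animal
affected when \(l > 0\). Fixing the residual variance at 1 and the
threshold at 0 is required for identifiability — only the ratio of
variances is determined by binary data — and the per-sample heritability is
\(h^2 = \sigma^2_a / (\sigma^2_a + 1)\).

`threshold_gibbs()` cycles through four blocks per round: truncated-normal
draws of the liabilities, a joint Gaussian draw of the fixed effects,
single-site Gaussian updates of the breeding values over the sparse
\(A^{-1}\) neighbourhood (in pedigree code order, which is fixed, so chains
are reproducible), and a scaled inverse chi-square draw of \(\sigma^2_a\).

**Parents-only variance update.** With a single binary record per animal,
threshold animal models are known to mix poorly and can drift towards the
"extreme category" regime where \(\sigma^2_a\) grows without bound. The
default variance update therefore restricts the quadratic form to the
animals that have offspring: \(\sigma^2_a \sim (a_P' (A_{PP})^{-1} a_P +
\nu S^2) / \chi^2_{n_P + \nu}\), where \(A_{PP}\) is the relationship
matrix of the parental subset. Because every ancestor of a parent is
itself a parent, that subset is ancestrally closed, and \(A_{PP}\) is
computed exactly as the relationship matrix of the subset pedigree (then
inverted densely once — the subset is small). An `all_animals` option
retains the textbook update; on deep pedigrees with few founders it shows
visibly higher autocorrelation in \(\sigma^2_a\), which the test suite
asserts as an effective-sample-size ordering on a fixed benchmark.

**Prior.** The default prior on \(\sigma^2_a\) is the improper flat prior
on \((0, \infty)\) (\(\nu = -2\), \(S^2 = 0\)), a common default in animal
breeding software; a proper scaled-inverse-chi-square can be configured.
With very small or weakly structured datasets the flat prior lets the
chain wander to large \(\sigma^2_a\) — this is a property of the posterior,
not of the sampler, and is the regime the parents-only update mitigates.
The sampler should be used on datasets of at least several hundred
genetically linked records.

**Numerics.** Truncated normals are drawn by inverse CDF; for location
parameters beyond \(\pm 6\) the computation moves to log-space
complementary CDFs, so tail draws neither underflow nor return infinite
values. The sampler consumes R's RNG stream, so `set.seed()` (or the
`seed` argument) makes runs bit-reproducible.

### Bivariate sex model

To test for a sex-specific genetic basis, the diagnosis in males and
females can be treated as two traits measured on disjoint sets of animals
(`bivariate_sex_reml()`). The residual covariance is structurally missing
(no animal has records on both traits) and is fixed at 0 — the only
identifiable choice. This five-parameter REML problem is maximised
directly on the restricted log-likelihood (BFGS on log-variances and
\(\mathrm{atanh}\, r_g\)), with the standard error of the genetic
correlation obtained from the numerical Hessian by the delta method. At
registry scale (a few thousand records) a dense-covariance evaluation is
immediate; an average-information scheme would add complexity without
benefit here, which is why the univariate and bivariate fitters differ in
strategy.

## Algorithms and numerical choices

**Pedigree core.** Pedigrees are validated (duplicates, cycles — including
self-parenting — and parents added as founders when they lack rows of
their own) and topologically ordered; ties are broken by birth date and
then input order, so ordering is deterministic. Inbreeding coefficients
and \(A\) use the tabular method (exactly the same recursion, so
`inbreeding(ped)` equals `diag(relationship_matrix(ped)) - 1`
identically); \(A^{-1}\) is assembled sparsely by Henderson's rules with
Mendelian-sampling variances that account for parental inbreeding. The
tabular method is quadratic in memory, which is acceptable at the few
thousand-animal scale this package targets; both recursions are
implemented in compiled code.

**AI-REML.** The restricted likelihood is evaluated through the mixed
model equations (one Cholesky factorisation of the coefficient matrix per
iteration), never through an \(n \times n\) inverse of \(V\). Updates are
average-information steps with step-halving; whenever a step would leave
the parameter space the iteration falls back to EM-REML, and a persistent
push of \(\sigma^2_a\) against zero is resolved by pinning the component
at a small floor and reporting a boundary fit. Convergence requires a
relative parameter change below `1e-8` and a gradient norm below `1e-6`
(the free-gradient criterion is waived on the boundary). Starting values
split `var(y)` evenly. Standard errors come from the inverse AI matrix;
the heritability SE uses the delta method. One caveat worth knowing: with
no pedigree structure at all (founders only, one record each),
\(\sigma^2_a\) and \(\sigma^2_e\) are confounded and the likelihood is
flat along their sum — the fit then reports the starting split. Family
structure is what identifies the decomposition.

**Fixed-effect designs.** Class effects enter as full-rank treatment
contrasts; aliased columns are dropped by QR pivoting; factors with one
observed level are dropped with a warning. Age classes are raw integer
years by default (`merge_min = 1`); on small simulated datasets
near-empty year classes make designs fragile, so the simulation pipeline
uses `merge_min = 5`, merging age classes with fewer than 5 records into
the nearest class.

**MCMC diagnostics.** The effective sample size uses the initial positive
sequence rule on pairwise autocorrelation sums (autocovariances via FFT),
and HPD regions use the empirical shortest-interval construction
(`ceiling(level * n)` order statistics, leftmost window on ties). Both are
validated against analytic truths — white noise, AR(1) chains with known
\(\mathrm{ESS} = n(1-\rho)/(1+\rho)\), and Gaussian/uniform quantiles.
Degenerate (constant) chains report the nominal size with a flag rather
than failing.

## The synthetic registry

Because real kennel-club data cannot be shipped, `simulate_population()`
generates populations with the structure the analysis assumes: a
multi-generation, litter-structured pedigree (founders, then litters whose
sires are drawn from a restricted pool to create paternal half-sib
families); breeding values drawn along the pedigree with
Mendelian-sampling variances that account for parental inbreeding (so the
simulator and the estimators share one genetic model, and simulated
\(\mathrm{cov}(a) = \sigma^2_a A\) exactly); a liability built from sex,
age and calendar-year effects plus \(a\) and a residual scaled so the
liability-scale heritability equals the configured value; and a threshold
at the Gaussian quantile of the target prevalence.

Defaults emulate a national toy-breed screening registry: ~800 litters
over 4 generations with fresh unrelated founders entering the parent pool
each generation (imported or previously unregistered ancestors — without
them the pedigree collapses onto a few founder lineages and the realized
genetic variance drifts between replicates far more than registry data
show), giving ~3,400 pedigree animals of which ~1,150 are examined
(~2.9 pedigree ancestors per examined dog, the ratio seen in small-breed
registries), target prevalence 0.145, liability heritability 0.65, mean
litter size 3.2 with ~45% of non-founders examined (~1.4 examined dogs
per litter), re-examination roughly doubling the certificate count, and
sporadic missing dates (~0.3%). Conflicting results are generated asymmetrically,
as in real registries: an affected dog's earliest examinations may read
unaffected (missed mild cases or late onset; probability 0.3 among
multiply-examined affected dogs), while the reverse — an affected dog
whose final certificate reads unaffected — is rare (0.02) and represents
recording error. Sex, age and year effects default to 0.1, 0.05/year and
SD 0.1 on the liability scale: small but non-zero, as screening data
usually show.

What the simulator does **not** emulate: selection or assortative mating
(parents are drawn at random, so there is no trend in breeding values
beyond drift), genotype data, maternal/litter environmental effects, and
examiner effects. Passing recovery tests therefore show that the
estimators recover the parameters of this generating model at registry
scale — not that any particular real dataset satisfies those assumptions.
Two consequences of the design are worth noting. First, the threshold is
placed at the Gaussian quantile at covariate means, so the realized
prevalence is random around the target, and genetic drift (real, since
sire pools are finite) adds between-replicate variance. Second, because
conflicting examinations only hide an affected dog's early results, the
cleaning rule "once affected = affected" recovers the true status of every
multiply-examined dog; single-examination false negatives are not
simulated.

## Problem sizes used in the test suite

Checks that exercise the full pipeline run at a deliberately moderate
scale chosen to mirror the registry setting while keeping the suite
practical: REML parameter recovery uses 50 replicates of ~1,000 examined
dogs (observed-scale truth 0.28); Gibbs calibration uses 20 replicates of
~1,500 examined dogs (liability truth 0.65) with 55,000-round chains
(5,000 burn-in, thinning 10). The paper-scale chain configuration
(1,100,000 / 100,000 / 10) is the function default and is what an analysis
of real registry data should use.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
pop <- simulate_population(cfg)
clean <- clean_records(pop$records, pop$pedigree)
ped <- trace_ancestors(pop$pedigree, clean$animal)

fit <- reml_animal(clean, ped, model = 1, merge_min = 5)
conv <- dempster_lerner(fit$h2_obs, fit$se_h2, p = mean(clean$y))

gb <- threshold_gibbs(clean, ped, model = 1, n_rounds = 55000,
                      burn_in = 5000, thin = 10, seed = 1, merge_min = 5)
summary(gb)
compare_ebv(ebv(fit), ebv(gb))
```

## Known limitations

* The tabular relationship matrix is dense; beyond ~10,000 animals a
  path-counting inbreeding algorithm and sparse-factor REML would be
  needed.
* The linear model on 0/1 data inherits the Dempster–Lerner approximation
  when moved to the liability scale; with covariates the mapping between
  scales is only approximate.
* The flat variance prior can behave poorly on very small datasets (see
  above); supply a proper prior there.
* Single-chain diagnostics only; no multi-chain convergence statistic is
  provided, and trace inspection is left to the analyst (`plot()` on the
  chain object).
* At registry scale (~1,500 binary records), internal uncertainty
  measures understate replicate-to-replicate variation for both model
  families: REML's information-based standard errors are smaller than the
  spread of its estimates across simulated registries, and the
  threshold-model HPD regions — while centred correctly — cover a fixed
  simulation truth less often than their nominal level (the acceptance
  tier of the test suite measures exactly this). Point estimates,
  conversions and breeding-value rankings are reliable at this scale;
  interval statements should be read conservatively.
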