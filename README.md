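# liabped

Heritability of binary (threshold) traits recorded on pedigreed
populations — built for veterinary screening registries, where a diagnosis
(affected / unaffected) is recorded at clinical examinations, animals may
be examined several times with occasionally conflicting results, and the
pedigree is the only source of genetic information.

The package implements the complete analysis chain:

* **Pedigree core** — validation, topological coding, inbreeding
  coefficients, the additive relationship matrix `A` (tabular method,
  compiled) and its sparse inverse by Henderson's rules with inbreeding.
* **Record cleaning** — the registry rules: duplicates collapsed keeping
  the worst diagnosis ("once affected = affected"), worst grade retained,
  dogs with missing examination/birth dates removed and counted,
  first-vs-last examination transition counts.
* **Descriptives** — prevalence with Wald/Wilson intervals, sex
  chi-squared test (no continuity correction), grading distribution,
  screening-coverage percentages.
* **Linear animal model** — AI-REML with EM fallback on the observed 0/1
  scale: variance components, `h2_o = s2a/(s2a+s2e)` with delta-method SE,
  and BLUP breeding values for all pedigree animals. Three fixed-effect
  formulations (sex + age classes; + diagnosis-year; year + linear age).
* **Bayesian threshold model** — Gibbs sampler (compiled) for the latent
  liability model with residual variance fixed at 1, threshold at 0, and —
  key for single-record binary data — the genetic variance sampled from
  the parental subset, `sigma2_a ~ (a_P' A_PP^-1 a_P) / chisq(n_P - 2)`.
  Per-sample heritability `h2 = s2a/(s2a+1)`.
* **MCMC diagnostics** — effective sample size (initial-positive-sequence
  rule) and shortest-interval HPD regions.
* **Scale conversion** — Dempster–Lerner: `h2_l = h2_o * p(1-p) / z^2`,
  with the SE scaled by the same factor; also the exact (non-linearized)
  threshold-model mapping between the two scales
  (`observed_h2_exact()` / `liability_h2_for_observed()`); EBV comparison
  across model families (Pearson + Spearman).
* **Synthetic registry** — a litter-structured pedigree and
  examination-record simulator whose generating model is exactly the
  additive threshold model above, plus `recovery_experiment()` to run the
  whole pipeline over replicates.

## Worked example

Simulate a registry-scale population (~1,500 examined dogs, liability
heritability 0.65, prevalence target 0.145), clean it, and fit both model
families:

```r
library(liabped)

cfg   <- sim_config(litters_per_generation = 260, seed = 3)
pop   <- simulate_population(cfg)
clean <- clean_records(pop$records, pop$pedigree)
ped   <- trace_ancestors(pop$pedigree, clean$animal)  # examined + ancestors

fit <- reml_animal(clean, ped, model = 1, merge_min = 5)
fit
#> Linear animal model (AI-REML) - model 1
#>   records: 1471, pedigree animals: 1998
#>   sigma2_a = 0.0309 (SE 0.0065)
#>   sigma2_e = 0.0789 (SE 0.0054)
#>   h2 (observed scale) = 0.281 (SE 0.053)
#>   REML log-likelihood -435.968 after 8 iterations (converged)

dempster_lerner(fit$h2_obs, fit$se_h2, p = mean(clean$y))
#> Dempster-Lerner conversion (p = 0.1305, z = 0.2121, factor = 2.522)
#>   observed scale: h2 = 0.281 (SE 0.053)
#>   liability scale: h2 = 0.709 (SE 0.134)

gb <- threshold_gibbs(clean, ped, model = 1, n_rounds = 55000,
                      burn_in = 5000, thin = 10, seed = 5, merge_min = 5)
summary(gb)
#> Posterior summaries (mean, HPD region, effective sample size):
#>   parameter   mean hpd_low hpd_high   ess
#> 1  sigma2_a 1.4441  0.6038   2.3008 201.8
#> 2        h2 0.5770  0.4276   0.7177 195.7

compare_ebv(ebv(fit), ebv(gb))
#> EBV comparison over 1998 animals: Pearson 0.986, Spearman 0.993
```

Reading the output: the linear model sees heritability 0.28 on the 0/1
scale; converted to the liability scale (0.71) it agrees with the
threshold model's posterior (mean 0.58, 95% HPD 0.43–0.72) — both bracket
the simulated truth of 0.65 — and the two model families rank animals
almost identically (rank correlation 0.99), so for selection decisions the
cheap linear model is an adequate substitute for the Gibbs sampler at this
prevalence. For real registry analyses use the chain defaults
(1,100,000 rounds, 100,000 burn-in, thinning 10); the short chain above is
for illustration.

`plot(gb)` draws the trace plots used to inspect mixing, and
`attr(clean, "report")` prints the cleaning audit (removals and
unaffected-to-affected transition counts).

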