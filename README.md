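# micromacro

Regression tools for **micro-macro data**: a quantitative outcome
observed once per group — a hospital unit's yearly nurse turnover rate,
a ward's hand-hygiene compliance, a team's error rate — explained by
covariates measured both on the groups and on the individuals inside
them. This is the mirror image of the usual multilevel design (where
the outcome is individual-level), and it needs its own estimator.

## The problem and the method

For group *g* with *n<sub>g</sub>* individuals,

```
y_g  = b0 + b1' z_g + b2' xi_g + eps_g        (outcome model)
x_ig = xi_g + ups_ig                          (measurement model)
```

the individual measurements `x_ig` are noisy indicators of a latent
group score `xi_g`. Regressing `y_g` on the observed group means
`xbar_g` attenuates `b2` by the reliability factor
`Sigma_xi / (Sigma_xi + Sigma_ups / n_g)`. The package removes this
aggregation bias by substituting the **adjusted group mean** — the best
linear predictor of `xi_g` given `(z_g, xbar_g)`:

```
xtilde_g = mu_x + [Sigma_xiz  Sigma_xi] * V_g^-1 * ( z_g - mu_z ,
                                                     xbar_g - mu_x )
```

with all moments estimated from the one-way ANOVA decomposition of the
individual data. Around this core the package provides:

* mixed quantitative/qualitative predictors via reference-omitted dummy
  coding;
* heteroscedasticity-consistent (sandwich, HC3 default) standard
  errors with a small-sample *t* reference — group sizes differ, so the
  group-level regression is heteroscedastic by construction;
* two-stage variable selection: hierarchical clustering of mixed-type
  variables (homogeneity = leading eigenvalue of the cluster's
  standardized block) with bootstrap-stability choice of the cluster
  count, then exhaustive best-subset search by
  `AIC = G*ln(RSS/G) + 2(k+1)` with factor dummy blocks moving as one;
* a simulation-based restricted likelihood-ratio test of zero
  between-group variance, the gatekeeper for aggregating an
  individual-level variable at all;
* a Monte-Carlo harness (`run_bias_study()`) comparing the naive and
  adjusted estimators for bias and coverage, and a calibrated synthetic
  ICU-turnover fixture (`generate_icu_fixture()`).

## Worked example

The synthetic fixture mimics a 30-unit ICU staffing study (526-ish
nurses, 19 individual and 7 unit covariates, turnover mean ≈ 0.19):

```r
library(micromacro)
fx <- generate_icu_fixture(seed = 1)
td <- fx$data

# is aggregating colleague support to unit level meaningful?
zero_variance_test(td$micro$support_colleagues, td$micro$group_id,
                   n_sim = 999, seed = 1)
#> Restricted LRT of zero between-group variance
#>   RLRT = 23.434,  simulated p = 0.001  (999 null draws)
#>   sigma2_u = 0.3034, sigma2_e = 2.74, ICC = 0.0997

sp_i <- Filter(function(s) s$level == "individual" && s$name %in%
               c("support_colleagues", "experience_profession",
                 "n_children", "skip_break"), fx$specs)
sp_g <- Filter(function(s) s$level == "group" && s$name %in%
               c("n_beds", "intermediate_care", "ratio_overall"),
               fx$specs)

menc <- encode(td$micro, sp_i)                       # dummy-coded X
zenc <- encode(td$macro, sp_g)                       # dummy-coded Z
gs   <- group_summaries(menc, td$micro$group_id, td$macro$group_id)
mom  <- estimate_moments(gs, menc, td$micro$group_id, macro_z = zenc)
adj  <- adjust_means(mom, gs, macro_z = zenc)        # latent-adjusted means
fit  <- fit_micro_macro(td$macro$outcome, zenc, adj) # robust group-level OLS
fit
#> Micro-macro group-level regression (30 groups, HC3 corrected SEs, t reference)
#>
#>                  factor       level     beta ci_lower ci_upper      p     se se_corr
#> 1           (Intercept) (intercept)  1.73137  -1.1505   4.6132 0.2259 1.4577  1.3896
#> 2                n_beds       group  0.00574  -0.0169   0.0284 0.6044 0.0104  0.0109
#> 3     intermediate_care       group  0.10857   0.0153   0.2018 0.0245 0.0613  0.0449
#> 4         ratio_overall       group -0.58478  -2.7596   1.5901 0.5827 1.1392  1.0487
#> 5 experience_profession  individual -0.00450  -0.0401   0.0311 0.7958 0.0210  0.0172
#> 6    support_colleagues  individual -0.12396  -0.2922   0.0443 0.1407 0.0847  0.0811
#> 7            n_children  individual -0.01409  -0.3763   0.3482 0.9364 0.2210  0.1747
#> 8            skip_break  individual  0.00956  -0.8439   0.8631 0.9817 0.4821  0.4116
#>
#> Residual variance 0.00375 on 22 df;  R-squared 0.695
```

Each row gives the coefficient on a unit-level covariate (`group`) or
on the latent-adjusted unit mean of an individual covariate
(`individual`), with 95% CI and p-value from the corrected (sandwich)
standard errors; `se` vs `se_corr` shows what the heteroscedasticity
correction changed. One run on one 30-unit dataset is deliberately
noisy — the Monte-Carlo harness, not a single fit, is what validates
the estimator.

The whole workflow (clustering → stability → representatives →
adjustment → best-subset → robust fit) is one call:
`run_pipeline(td, fx$specs)`; `write_reports()` emits the coefficient,
selection, cluster and stability tables as CSV. A thin command-line
front end with `analyze` / `simulate` / `make-fixture` / `cluster`
subcommands lives in `inst/cli/micromacro.R`.

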