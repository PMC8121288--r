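---
title: "Micro-macro regression with latent-adjusted group means: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-macro regression with latent-adjusted group means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromacro)
```

## The micro-macro problem

Most multilevel analyses explain an individual-level outcome with
individual- and group-level predictors. This package addresses the
reverse ("micro-macro") design: the outcome exists once per group — for
instance the yearly turnover rate of the nursing staff of an intensive
care unit — while predictors are measured both on the groups and on the
individuals inside them.

The model for group $g = 1, \dots, G$ with $n_g$ individuals is

$$y_g = \beta_0 + \beta_1' z_g + \beta_2' \xi_g + \varepsilon_g,
\qquad x_{ig} = \xi_g + \upsilon_{ig},$$

where $z_g$ are observed group-level covariates, $\xi_g$ is a latent
group-level score of which the individual measurements $x_{ig}$ are
noisy indicators, $\varepsilon_g$ has constant variance
$\sigma^2_\varepsilon$, and the disturbances $\upsilon_{ig}$ have
constant covariance $\Sigma_\upsilon$, independent of $\varepsilon$ and
$\xi$.

Regressing $y_g$ on the observed group means $\bar x_g$ is the obvious
("naive") estimator, and it is biased: $\bar x_g$ carries sampling noise
$\bar\upsilon_g$ with variance $\Sigma_\upsilon / n_g$, so the
coefficient of a single individual-level predictor is attenuated toward
zero by the reliability factor
$\Sigma_\xi / (\Sigma_\xi + \Sigma_\upsilon / n_g)$.
With $\Sigma_\xi = 1$, $\Sigma_\upsilon = 9$, $n_g = 10$ the naive slope
converges to $1/1.9 \approx 0.53$ of the truth — the package's test
suite verifies exactly this attenuation and its removal.

## Adjusted group means

The correction replaces $\bar x_g$ by the best linear predictor of
$\xi_g$ given everything observed about group $g$:

$$\tilde x_g = \hat\mu_x + [\hat\Sigma_{\xi z} \;\; \hat\Sigma_\xi]
  \, V_g^{-1}
  \begin{pmatrix} z_g - \hat\mu_z \\ \bar x_g - \hat\mu_x \end{pmatrix},
\qquad
V_g = \begin{pmatrix} \hat\Sigma_z & \hat\Sigma_{z\xi} \\
\hat\Sigma_{\xi z} & \hat\Sigma_\xi + \hat\Sigma_\upsilon / n_g
\end{pmatrix}.$$

With no $z$, this is shrinkage of $\bar x_g$ toward the grand mean with
weight $W_g = \hat\Sigma_\xi (\hat\Sigma_\xi +
\hat\Sigma_\upsilon/n_g)^{-1}$: small or noisy groups are shrunk more.
The moments come from the classical one-way (M)ANOVA decomposition
(`estimate_moments()`):

* $\hat\Sigma_\upsilon$ — pooled within-group covariance on $N - G$
  degrees of freedom;
* $\hat\Sigma_\xi = (S_B - \hat\Sigma_\upsilon) / c$ with
  $S_B = \sum_g n_g (\bar x_g - \hat\mu_x)(\bar x_g - \hat\mu_x)' /
  (G-1)$ and the unbalanced-design constant
  $c = (N - \sum_g n_g^2/N)/(G-1)$;
* $\hat\Sigma_{z\xi}$ — the group-level sample covariance of $z_g$ with
  $\bar x_g$, each group counting once (valid because $\upsilon$ is
  independent of $z$; $n_g$-weighting is available as an option).

The grand mean $\hat\mu_x$ is individual-weighted ($\sum x_{ig}/N$),
matching those moment identities. Qualitative predictors enter through
reference-omitted dummy coding (`encode()`): one 0/1 column for a
binary variable, $m - 1$ columns for an $m$-modality factor; the same
adjustment machinery then applies to the dummy columns, whose latent
group scores are within-group category probabilities.

The final fit (`fit_micro_macro()`) is OLS of $y_g$ on the intercept,
$z_g$ and $\tilde x_g$.

### Numerical choices

* **Indefinite moment differences.** $(S_B - \hat\Sigma_\upsilon)/c$
  can have negative eigenvalues in small samples; `psd_truncate()`
  repairs it by truncating negative eigenvalues at zero, leaving the
  eigenvectors untouched.
* **Singular $V_g$.** If inversion fails, a ridge
  $\epsilon I$ with $\epsilon = 10^{-8}\,\mathrm{tr}(V_g)/\dim(V_g)$ is
  added and a warning raised.
* **Inference.** Group sizes differ, so the final regression is
  heteroscedastic even when the structural error is not; standard
  errors come from a sandwich (heteroscedasticity-consistent) covariance
  via the sandwich package, HC3 by default (HC0-HC2 available; HC3's
  leverage correction is the conservative choice at $G \approx 30$).
  Confidence intervals and p-values use a $t$ reference with
  $G - k - 1$ degrees of freedom — appropriate for few groups — with a
  normal reference as an option.
* **Ties and determinism.** All selection procedures break ties toward
  the smallest index / fewest variables / smallest $K$; rerunning any
  step with the same seed reproduces its output bit for bit.

## Variable selection

Study datasets of this kind carry ~20 individual-level and ~7
group-level covariates for only ~30 groups, so selection happens in two
stages.

**Stage 1 — clustering of variables** (`cluster_variables()`).
Variables (not observations) are agglomerated so that strongly related
variables share a cluster. A cluster's homogeneity is the leading
eigenvalue of its standardized mixed-encoded block — equivalently the
sum over members of the squared correlation (quantitative) or
correlation ratio $\eta^2$ (qualitative) with the cluster's first
principal component. Quantitative columns are standardized; qualitative
ones are expanded to centered indicators scaled by the inverse square
root of the category frequency (the mixed-PCA convention), so a lone
variable of either kind has homogeneity exactly 1. Each merge sacrifices
the least homogeneity. The number of clusters is chosen by bootstrap
stability (`stability()`): observations are resampled, the tree is
rebuilt, and partitions are compared to the original with the adjusted
Rand index; the most stable $K$ wins, smallest-$K$ on ties. $K = 1$ is
trivially stable, so the scored range starts at 2. One representative
per cluster is kept (`pick_representatives()`) — by default the member
loading highest on the cluster component, but substantive overrides
(e.g. the variable most actionable as an intervention lever) take
precedence, which is how a published analysis's judgment-based choices
are reproduced.

**Stage 2 — exhaustive subset search** (`best_subset()`). All subsets
of the candidate design (group covariates plus adjusted means) are
fitted by OLS and scored with
$\mathrm{AIC} = G \ln(\mathrm{RSS}/G) + 2(k+1)$, constants dropped
consistently. Dummy blocks of one source variable enter and leave
together, so a factor is selected as a whole. Subsets with no residual
degree of freedom ($k + 1 \ge G - 1$) are never examined — their RSS is
degenerate and their AIC meaningless. The pipeline caps subset size at
about $G/3$ (and a bounded number of examined subsets) by default;
models near saturation on 30 groups are not interpretable anyway, and
the cap is a plain argument for callers who disagree.

**Aggregation diagnostic** (`zero_variance_test()`). Aggregating an
individual-level variable is only meaningful if its group means carry
real between-group signal. The test fits the one-way random-intercept
model by REML — profiled analytically over the variance ratio, so one
fit costs $O(G)$ — and refers the restricted likelihood-ratio statistic
for $H_0: \sigma^2_u = 0$ to a parametric simulation under the null,
because the boundary null defeats the chi-squared approximation. The
statistic is location-scale invariant, so unit normals suffice for the
null draws; the p-value is the finite-sample exceedance proportion
$(1 + \#\{T^{sim} \ge T\})/(n_{sim}+1)$.

## The simulation harness

`simulate_dataset()` draws data from the model above:
latent standardized group scores for every predictor are jointly
Gaussian with cross-level correlation $\rho$; quantitative individual
predictors add $N(0, \sigma^2_\upsilon)$ within-group noise to
$\xi_g = \sigma_\xi \cdot$latent; binary predictors are produced by
probit-style thresholding at prevalence 1/2. For a binary individual
predictor the group-level success probability is
$p_g = \Phi(\gamma u_g)$ with $\gamma$ solved in closed form
($\gamma^2/(1+\gamma^2) = \sin(\pi \cdot \mathrm{ICC}/2)$) so that the
observed 0/1 responses have intraclass correlation exactly equal to the
scenario's ICC; $p_g$ itself is the latent score entering the outcome,
and the Bernoulli residual plays the role of $\upsilon$.

`run_bias_study()` compares the naive and adjusted estimators over a
scenario grid. The default grid (`default_scenario_grid()`) crosses
$G \in \{30, 50, 100\}$, group sizes fixed at 10 or uniform on 7-32,
ICC $\in \{0.1, 0.3, 0.5\}$ and $\rho \in \{0, 0.3\}$, with one
quantitative and one binary predictor per level and true coefficients
$(0.2, 0.1, -0.1, 0.1, -0.05)$ — 36 scenarios at $R = 200$ replicates,
about two minutes on one core. Design choices worth stating:

* **Outcome noise.** $\sigma_\varepsilon = 0.02$ by default. The
  group-level disturbance enters the OLS coefficients additively with
  mean zero, so it contributes no bias — only Monte-Carlo variance. A
  small $\sigma_\varepsilon$ therefore isolates the quantity the study
  measures (aggregation-induced bias) at a fixed replicate budget;
  coverage checks, which do need realistic noise, set their own value.
* **Mean versus median bias.** The report carries both. In weak-signal
  corners (few groups, ICC = 0.1) the adjusted estimator's replicate
  distribution is heavy-tailed: $\hat\Sigma_\xi$ can land near zero,
  the adjusted means then collapse toward the grand mean, and single
  replicates produce arbitrarily large coefficients. A mean over 200
  replicates then reports a few tail draws rather than central
  accuracy, so `max_rel_bias()` summarizes by the median estimate by
  default and keeps the classical mean-based column alongside.
* **What this shows — and does not.** Group-level coefficients are
  estimated essentially without bias across the whole grid. For
  individual-level coefficients the adjustment removes the attenuation
  (which reaches ~50% for the naive estimator) wherever the latent
  signal is estimable, and the package reproduces the known closed-form
  attenuation exactly at large $G$. But at the weakest corners — 30
  groups, ICC 0.1, a binary predictor with a small true coefficient —
  the moment plug-in itself is too noisy for accurate correction:
  re-running those corners with the true moment matrices substituted
  removes nearly all the excess bias, which identifies estimation noise
  in $\hat\Sigma_\xi$, not the formula, as the cause. Users with few
  groups and weakly clustered predictors should read individual-level
  coefficients with corresponding caution, and the
  `zero_variance_test()` diagnostic is the gatekeeper for exactly this
  situation.

`generate_icu_fixture()` emits a synthetic dataset with the shape of a
30-unit ICU turnover study: 30 units of 7-32 staff, 19 individual
covariates (support, strain, workload, demographic and schedule blocks,
mixed quantitative/ordinal/binary), 7 unit covariates including a
3-level unit-type factor, and an outcome generated from the latent
group scores of five individual and four unit covariates with
coefficients of the magnitude seen in observational turnover models,
calibrated so the outcome mean and SD sit near 0.19 and 0.09. A truth
sidecar records the generating coefficients for recovery checks. The
fixture emulates realistic marginal scales and correlation blocks; it
does **not** emulate missing data, informative cluster sizes,
measurement instruments' discrete artifacts beyond rounding, or any
causal structure — passing tests on it demonstrate the estimation
machinery, not robustness to those features of real data.

## Problem sizes

The shipped validation uses the 36-scenario grid at $R = 200$ (~7200
fits), an attenuation scenario at $G = 500$, 500 outer replicates with
99 null simulations each for the size of the zero-variance test, 100
regenerated fixtures for parameter recovery, and 100 random instances
against a brute-force subset-selection oracle. These sizes resolve the
quantities of interest to the tolerances asserted in the test suite;
all are plain arguments, so larger studies are one call away.

## Limitations

* Random slopes, three-level designs, and non-Gaussian outcomes are out
  of scope; the outcome model is linear-Gaussian, so a simulated rate
  can fall slightly outside $[0, 1]$.
* The adjustment assumes homoscedastic $\upsilon$ across groups; a
  binary individual predictor violates this mildly (variance
  $p_g(1-p_g)$), which the simulation study shows to be a second-order
  effect.
* Moment noise at $G \lesssim 30$ with ICC $\lesssim 0.1$ limits the
  achievable accuracy of individual-level coefficients, as quantified
  by the bias study.
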