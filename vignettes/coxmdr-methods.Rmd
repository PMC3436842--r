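---
title: "Cox-MDR: martingale-residual multifactor dimensionality reduction for survival phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cox-MDR: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxmdr)
```

## The problem

Genome-wide association analyses of prospective cohorts ask whether SNPs —
singly or through gene–gene interaction — are associated with a censored
survival time. Classical multifactor dimensionality reduction (MDR) pools
the $3^k$ genotype cells of a $k$-SNP combination into a one-dimensional
high/low-risk attribute using case–control ratios, and selects combinations
by cross-validated balanced accuracy. Neither case–control ratios nor the
log-rank-based Surv-MDR variant can adjust for covariates such as age, sex
or disease stage, and covariate confounding is exactly what plagues
survival cohorts.

Cox-MDR replaces the case–control ratio with a quantity that already has
the covariates integrated out: the martingale residual of a covariate-only
Cox model.

## The model and the classifier

For subject $i$ let $T_i$ be the observed time, $\delta_i$ the event
indicator and $Z_i$ the covariates. The hazard model is
$\lambda(t \mid X_i, Z_i) = \lambda_0(t)\exp(\beta X_i + \gamma' Z_i)$,
where $X_i$ is the (unknown) genetic attribute. Under the null model
$\beta = 0$ we fit $\gamma$ by Cox partial likelihood and form

$$M_i = \delta_i - \hat\Lambda_0(T_i)\, e^{\hat\gamma' Z_i},$$

the difference between observed and expected events: positive residuals
are subjects who died earlier than their covariates explain. The Cox-MDR
cell classifier sums the residuals of the training subjects in each
genotype cell and labels the cell **high risk when the sum is $\ge 0$**,
low risk otherwise. Subjects with $M_i > 0$ are "cases", the rest
"controls", and a combination is scored by the balanced accuracy
$\tfrac12(\mathrm{sens} + \mathrm{spec})$ of the cell labels against this
case status, under repeated stratified cross-validation. The best model is
the combination with the highest mean testing balanced accuracy.

Because $\sum_i M_i = 0$ for a Breslow-baseline fit, the zero threshold is
the natural centre of the score — precisely the property that makes the
residual a drop-in replacement for MDR's case–control ratio.

The Surv-MDR comparator labels each cell by a two-sample log-rank test of
the in-cell subjects against everyone else (high when observed minus
expected deaths $> 0$) and scores models by the signed log-rank statistic
between predicted-high and predicted-low subjects. Every subject enters
the "without" group of every cell it does not occupy, so information is
reused across cells, and no covariate can enter anywhere — the two
drawbacks that motivate the residual-based classifier.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `folds`, `repeats` | 10, 10 | simulation-study CV geometry; `folds = 2, repeats = 100` is the small-sample (n = 97) real-data configuration |
| `ties` | `"breslow"` | keeps $\sum_i M_i = 0$ exactly; Efron available for sensitivity only (coefficients change, the baseline stays Breslow) |
| `covariates` | cohort's | `character(0)` gives the unadjusted analysis (Nelson–Aalen baseline) |
| `B` (permutations) | 1000 | add-one p-value, lower bound $1/(B+1)$ |
| `n_high`, `n_low` | 200, 200 | cohort quotas per simulated dataset |
| `beta`, `gamma` | 1, 0/1/2 | log hazard ratios of risk status and covariate |
| `covariate_sd` | $\sqrt{0.5}$ | the benchmark covariate is $z \sim N(0, 0.5)$, read as **variance** 0.5; the sd reading would raise unadjusted power somewhat (see limitations) |
| `weibull_shape`, `weibull_scale` | 5, 2 | baseline $\Lambda_0(t) = (t/\text{scale})^{\text{shape}}$; any monotone reparameterisation only rescales time |
| `censor_upper` | 4 | censoring $C \sim U(0, 4)$, giving roughly 40% censoring at these settings |

## The synthetic world

`penetrance_model()` draws a $3\times3$ penetrance function $f$ with a
prescribed heritability
$h^2 = \sum_g P(g)\,(f(g)-K)^2 \,/\, K(1-K)$ (HWE cell probabilities
$P(g)$, prevalence $K = \sum_g P(g) f(g)$) and **no marginal effects at
either locus**. Instead of a perturbation walk we sample the constraint
null space directly: matrices $E = U C U'$, with $U$ a basis of the
HWE-weight-orthogonal complement and $C$ a random $2\times2$ coefficient
matrix, have weighted row and column sums of zero, so
$f = K + cE$ holds both marginal penetrances constant while $c$ is solved
in closed form to hit $h^2$ exactly. Random restarts only reject draws
leaving $[0,1]$; accepted models meet the tolerance to floating-point
accuracy. The prevalence floats uniformly in $[0.01, 0.5]$ per draw.

`simulate_cohort()` rejection-samples genotypes and risk status until 200
high-risk and 200 low-risk subjects accumulate, adds 8 null SNPs at the
same MAF, places the two causal loci at seeded random positions among the
10 columns, and draws Weibull survival times by inverse transform with
uniform censoring.

**What the generator does not emulate.** The benchmark it mirrors was
built on 40 unpublished penetrance tables. Those tables demonstrably
carried real marginal effects — a univariate Cox screen has power up to
0.86 against them, whereas under *strictly* pure epistasis each causal SNP
is marginally independent of survival and the two-SNP univariate success
rate collapses to $\alpha^2 = 0.0025$. Consequently, in this package's
world (i) the univariate-Cox comparator is essentially powerless by
construction, and (ii) MDR power levels run some 10–25% below the
published averages while preserving the published orderings (power
increasing in $h^2$; adjustment recovering power lost to an omitted
covariate; Surv-MDR strongest at MAF 0.4). A green power test therefore
establishes correct machinery and qualitative behaviour, not agreement
with the unpublished tables.

## Numerical and design choices

* **Ties.** Breslow approximation in the partial likelihood and the
  baseline; convergence at a relative log-likelihood change of $10^{-10}$
  with a 50-iteration cap, non-convergence, monotone likelihood and
  collinearity reported as distinct errors.
* **Thresholds.** Residual exactly 0 → control; cell sum exactly 0 → high
  (both stated by the method); Surv-MDR cell with $O-E = 0$ → low (tie
  rule is unstated there; zero evidence defaults conservatively, mirroring
  the empty-cell rule).
* **Empty cells.** Training-empty cells are labelled low risk so every
  test subject stays classifiable; folds whose balanced accuracy is
  undefined are recorded as missing, never dropped silently.
* **Residual computation.** Once on the full cohort before
  cross-validation (the GMDR-style score; the method computes residuals
  "for a given dataset" before the combination search); a per-training-fold
  refit is available behind `recompute_residuals = TRUE` for sensitivity
  analysis.
* **Fold assignment.** Stratified by event status, so heavy censoring
  cannot produce event-free folds; leave-one-out is deterministic.
* **Selection.** Mean testing score ranks models; ties break by CV
  consistency (fold-best-by-training-score tally, the MDR convention),
  then mean training score, then lexicographic order.
* **Missing genotypes.** A subject is excluded only from combinations
  involving the missing SNP.
* **Permutation p-values.** The construction behind the published
  permutation columns is not described; this package permutes the
  phenotype block (time, status, covariates) jointly against the genotype
  rows — preserving the covariate–survival association while destroying
  any genotype–survival one — re-deriving cell labels each time, and uses
  the Wald chi-square of the high/low attribute in a covariate-adjusted
  Cox model as the statistic. This is a documented choice, not a
  reconstruction.
* **Type-I criterion.** The published null experiment "removes the two
  causal SNPs" and then checks whether they are "included", which cannot
  be implemented as written. We measure the rate at which a fixed,
  pre-designated null pair is returned as the best model: by
  exchangeability this is $1/\binom{M}{2}$ — 1/45 ≈ 0.022 in the 10-SNP
  geometry (matching the published 0.02) and 1/28 in the 8-SNP one; both
  geometries are exposed.

## Known limitations

* Time-varying covariates, stratified and frailty Cox models are out of
  scope; covariates are time-fixed.
* $k > 3$ interactions are guarded by an explicit combination cap.
* The $N(0, 0.5)$ covariate is read as variance 0.5; under the sd reading
  the unadjusted powers at $\gamma > 0$ rise mildly. The choice is fixed,
  not data-driven.
* Power comparisons against the published averages inherit the
  penetrance-table caveat above; exact reproduction is not possible
  without the original tables.

## A small worked run

```{r example, eval = FALSE}
model <- penetrance_model(maf = 0.2, h2 = 0.3, seed = 1)
ch <- simulate_cohort(model, seed = 1)
search <- mdr_search(ch, k = 2, repeats = 2, covariates = character(0), seed = 1)
tidy(search)[1:3, ]
km <- km_curves(ch, mdr_attribute(ch, search))
autoplot(km)
```
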