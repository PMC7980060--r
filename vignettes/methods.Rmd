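---
title: "Weighted marginal structural models for childcare and developmental inequalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted marginal structural models for childcare and developmental inequalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Socio-economic inequalities in early child development are visible well
before school age.  One candidate lever is pre-school childcare: if
centre-based care benefits children from disadvantaged families more than
others, universal take-up would narrow developmental gaps, and removing
access (as under pandemic lockdowns) would widen them.  `ipwcde`
implements the estimation machinery for this question as a reusable,
tested pipeline: a binary social exposure $X$ (e.g. low parental
education, or lone parenthood), a three-level childcare mediator $M \in
\{\text{parental}, \text{non-centre}, \text{centre}\}$ measured over a
fixed age window, continuous developmental outcomes $Y$ in SD units, and
a confounder set split into *pre-exposure* confounders $C$ (common causes
of $X$, $M$, $Y$) and *post-exposure* confounders $L$ (mediator--outcome
confounders possibly caused by $X$).

Three estimands drive the analysis:

1. **ATE of the mediator** (question 1): the population-average effect of
   each childcare level versus parental care, had childcare been
   randomized.  Estimated with stabilized inverse-probability weights
   $w_i = \hat P(M = m_i)\,/\,\hat P(M = m_i \mid X, C, L)$ and a
   weighted regression of $Y$ on mediator indicators.
2. **Total effect of the exposure** (questions 2--3 baseline):
   $w_i = \hat P(X = x_i)\,/\,\hat P(X = x_i \mid C)$, adjusting *only*
   $C$ — pathways through $M$ and $L$ are part of the effect.
3. **Controlled direct effects** CDE$(m)$: the exposure effect when
   childcare is fixed at level $m$ for everyone.  Product weights
   $$w_i = \frac{\hat P(X = x_i)}{\hat P(X = x_i \mid C)} \times
     \frac{\hat P(M = m_i \mid X)}{\hat P(M = m_i \mid X, C, L)}$$
   feed a marginal structural model
   $E[Y] = \beta_0 + \beta_X x + \beta_m' \mathbf{1}[M = m] +
   \beta_{Xm}' x \, \mathbf{1}[M = m]$, whence
   $\mathrm{CDE}(m) = \beta_X + \beta_{Xm}$.  Because only *differences in
   $L$ not due to $X$* are adjusted away, the $X \to L \to Y$ pathway
   remains inside the CDE — this is what distinguishes the weighting
   approach from naive regression adjustment for $L$.  Scenario 1 fixes
   $m = \text{centre}$ (universal take-up), scenario 2 fixes
   $m = \text{parental}$ (care at home only).

The exposure-by-mediator interaction is the substantive heart: if centre
care benefits exposed children more, CDE(centre) < CDE(parental) on a
symptom scale, and universal centre care compresses the inequality.

## The synthetic world

Real cohort data for this design (a national birth cohort with a
stratified--clustered sample and attrition weighting) are
restricted-access, so the package carries a generator whose defaults
*are* the documented study conditions, with truths known by
construction:

* $n = 14{,}376$ children; exposure prevalence 0.54.
* Mediator marginals calibrated to 39.6% parental / 33.0% non-centre /
  27.4% centre (intercepts solved once at 2M draws and frozen; the
  calibration residual is below $10^{-9}$ on the solver's own scale).
* Confounders: two binary and one continuous $C$; one binary and one
  continuous $L$.  This compact set exercises every code path (binary,
  categorical and continuous models in weighting and imputation); a
  30-variable set would add bulk, not coverage.
* $L$ depends on $X$ but not $C$.  This is a deliberate simplification:
  it keeps every CDE available in closed form (the $X \to L \to Y$
  contribution is $\sum_\ell \beta_\ell\,[E(\ell \mid X=1) -
  E(\ell \mid X=0)]$, analytic for the logistic and linear $L$
  equations), while $L$ still confounds $M$--$Y$ through its own
  variation.
* Outcomes have unit marginal SD (noise SDs solved at calibration), so
  structural coefficients are directly SD-unit effects.  Outcome `y1` is
  an externalising-symptom analogue with CDE(parental) = 0.15 SD and
  CDE(centre) = 0.02 SD — the exposed-by-centre interaction (−0.13)
  attenuates the exposure effect under universal centre care.  Outcome
  `y2` is a school-readiness analogue with a +0.10 SD centre effect and
  no direct exposure effect.
* Missingness is masked MAR at 5% per column, with probability depending
  only on the always-observed exposure; the missingness-model intercept
  is solved so the realized rate matches the target.
* The survey design has 4 strata (membership tilted toward the
  disadvantage indicator), 100 clusters per stratum formed by sorting on
  the continuous confounder (geographic-style sorting, which induces
  intra-cluster correlation without touching the outcome equations),
  relative oversampling (1, 1.5, 1.5, 2), and a follow-up response model
  with mean response ≈ 0.76.  The inverse response probability folds
  into the design weight, which is scaled to mean 1.

`true_estimands()` returns the implied ATE (closed form given the exact
marginal exposure prevalence, obtained by quadrature), every CDE (closed
form as above), and the total effect (exact enumeration for discrete
configs; otherwise a $10^6$-draw Monte Carlo evaluation with common
random numbers across exposure arms, Monte Carlo error well below
0.005 SD).

What a green test does **not** establish: the generator's conditional
models match the fitted propensity forms by construction, so recovery
tests certify the estimation machinery, not robustness to
misspecification; attrition follows a single-indicator response model,
not a real cohort's wave structure; and instrument-level measurement
(scale scoring, age-standardization) is out of scope.

## Numerical and design choices

* **Propensity models.** Main-effects logistic / multinomial-logistic by
  default; RHS formulas are overridable per model (saturated models are
  used in the enumeration-oracle tests).  The multinomial fitter is an
  in-package Newton--Raphson (this stack has no `nnet`): convergence at
  gradient $10^{-10}$, loud failure when coefficients pass ±30
  (separation) with an optional ridge penalty — off by default, since
  the defensible default is to fail rather than silently shrink.
* **Stabilization numerators.** Marginal for mediator-ATE weights,
  $X$-conditional for the mediator factor of CDE weights.  An
  $X$-conditional ATE numerator is available via `numerator =
  "conditional_on_X"`; the marginal choice is the package default since
  the target is a marginal contrast.
* **Truncation** is available (`truncate_weights`, winsorizing at
  percentiles) but default-off, with bounds recorded in the weight set's
  provenance.
* **Design weights** enter every propensity fit as case weights and
  multiply into the analysis weight via `combine_weights()` before
  estimation and balance checks.
* **Balance** uses the standardized mean difference with a pooled
  *unweighted* SD denominator so before/after are comparable; 0.1 is the
  reporting threshold (a convention, not a test criterion).  For product
  weights, mediator balance is also reported within exposure strata —
  the diagnostic that catches residual imbalance confined to one
  exposure group (e.g. lone parents).
* **Variance.** Stratified cluster-sandwich (scores summed within PSU,
  centred within stratum, $g_h/(g_h-1)$ per stratum; df = clusters −
  strata).  With singleton clusters and one stratum this reduces exactly
  to the heteroskedasticity-robust sandwich.  A within-stratum cluster
  bootstrap is the cross-check.  Propensity-estimation uncertainty is
  ignored (standard MSM practice; in the replicate study empirical
  coverage sits inside [92%, 98%], mildly conservative as expected).
* **Multiple imputation.** In-package chained equations (no `mice`
  here): Bayesian logistic draws for binary, multinomial draws for the
  mediator, type-1 predictive mean matching (5 donors) for continuous
  variables (preserving support; a normal draw is available).  Default
  $m = 25$, 10 sweeps, fixed visit order, observed cells untouched,
  fully deterministic given the seed.  Weights are re-estimated within
  each completed dataset and results pooled by Rubin's rules
  ($T = W + (1 + 1/m)B$) with Barnard--Rubin degrees of freedom against
  the design df; imputing-then-weighting is the package's ordering.
  The acceptance script uses 5 sweeps to stay inside its runtime
  budget; sweep count is a convergence knob, not an estimand input.
* **Standardization.** Outcomes divide by their design-weighted SD
  (centring on); `scale_factor = 100` reproduces the convention of
  quoting SD differences ×100 (the generator's unit-SD outcomes make
  this a display choice only).
* **Degenerate inputs.** Zero-SD outcomes, empty exposure-by-mediator
  cells, absent mediator levels, single-cluster strata, nonpositive
  weights and >95%-missing columns all fail with named errors rather
  than propagating NaNs.

## Known limitations

Estimates are only as causal as the no-unmeasured-confounding and
correct-model assumptions; the generator cannot test sensitivity to
either.  Attrition weights are treated as supplied inputs (their
derivation is cohort-specific).  Natural direct/indirect effect
decompositions, doubly-robust/TMLE estimators and replicate-weight
variance systems are deliberately out of scope.

## A worked example

```{r, eval = FALSE}
library(ipwcde)

cfg  <- generator_config(n = 14376)
co   <- assign_design(generate_cohort(cfg), cfg)
co   <- apply_missingness(co, cfg)
spec <- default_causal_spec(cfg)

res <- run_pipeline(run_config(
  generator = cfg, causal = spec,
  imputation = imputation_config(m = 25, iterations = 10),
  questions = 1:3, seed = 20210312
))
res$results$main$q2     # total effects + CDE under universal centre care
true_estimands(cfg)     # the generator's ground truth for comparison
```
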