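---
title: "Methods: comparing ITT, per-protocol and CACE estimands in IPD meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing ITT, per-protocol and CACE estimands in IPD meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacemeta)
```

# Estimands and identifying assumptions

A two-arm trial with one-sided non-adherence has two latent principal
strata: *compliers*, who take the intervention if and only if offered it,
and *never-takers*, who do not take it even when offered. Because control
participants cannot access the intervention, there are no always-takers or
defiers — monotonicity holds by design. Three estimands are compared:

- **ITT**: the effect of assignment, E[Y(assigned) − Y(control)]. Valid
  under randomisation alone; it averages the complier effect with the
  (null, under the exclusion restriction) never-taker effect, so
  ITT = π~c~ · CACE when assignment does not affect never-takers.
- **PP**: the contrast between the control arm and the adherent subset of
  the intervention arm. Adherence is post-randomisation, so whenever
  complier status is associated with prognosis the PP contrast confounds
  the treatment effect with the selection effect.
- **CACE**: the complier-stratum effect, identified with randomisation as
  an instrument under (i) randomisation, (ii) monotonicity, and (iii) the
  exclusion restriction (assignment affects outcomes only through receipt).

## Per-trial estimators

*Continuous outcomes.* ITT and PP are baseline-adjusted linear models of
the follow-up symptom score (lower = better); the arm coefficient is the
unstandardised mean difference B. The CACE is just-identified two-stage
least squares with receipt instrumented by assignment and baseline (plus
any stratification covariates) exogenous in both stages; standard errors
use the heteroskedasticity-robust IV sandwich. Without covariates the 2SLS
estimate equals the Wald ratio ITT/π̂~c~ exactly, which the test suite
asserts against an independent ratio computation.

*Binary outcomes.* ITT and PP are logistic models of treatment response
(response defined per trial: ≥50% reduction, score < 10, or score < 10
with reduction ≥ 5). The binary CACE uses the principal-stratification
mixture likelihood: π~c~ and the complier/never-taker response rates under
intervention are estimated directly, and the complier response rate under
control is recovered from the control-arm mixture
p~ctl~ = π~c~ p~c0~ + (1 − π~c~) p~n~. The model is just-identified, so the
ML solution coincides with the closed-form moment estimator; the tests
confirm agreement with a numerically maximised four-parameter likelihood to
below 10^-3^. The reported effect is the complier log odds ratio, with a
seeded nonparametric bootstrap percentile interval (999 resamples by
default). When the recovered p~c0~ falls outside (0, 1) it is clamped just
inside the boundary and the record is flagged.

Covariate adjustment enters the continuous CACE as exogenous regressors in
both stages. The binary mixture estimator is deliberately unadjusted —
covariates are accepted but ignored with a warning — because the mixture
moments are defined on marginal response rates; this is a documented
simplification rather than an omission.

*Missing data.* All estimators are complete-case on the outcome, matching
an ITT population defined as "randomised with observed outcome".
Intervention-arm participants with missing adherence cannot be classified:
they are dropped from PP, and dropped from CACE by default with a
`missing_adherence = "non_complier"` sensitivity switch.

*Effect-size conversion.* Hedges' g = J·B/SD~pooled~ with
J = 1 − 3/(4(n₁+n₂−2) − 1), using the pooled follow-up SD across arms as
the denominator (this choice reproduces the published per-trial g values,
e.g. B = −5.68 with follow-up SDs 13/14 gives g ≈ −0.42).

# Two-stage meta-analysis

Stage two is a random-effects model y~i~ ~ N(μ, v~i~ + τ²) with τ²
estimated by REML (convergence threshold 10^-10^, at most 100 iterations,
floored at zero), inverse-variance weights 1/(v~i~ + τ²), and normal-theory
two-sided inference. I² follows the τ²/(τ² + s̃²) convention with s̃² the
typical within-study variance; a Knapp–Hartung t-interval is available but
off by default, consistent with the normal-theory intervals the pooled
results imply. REML estimation is delegated to `metafor::rma.uni()`; the
test suite checks it against an independent grid-plus-golden-section
maximiser of the restricted likelihood to 10^-6^.

## Correlated method differences

ITT, PP and CACE estimates within a trial come from the same participants
on the same outcome, so their differences are far more precise than
independence would suggest. Per-trial differences
δ~i~ = y~b,i~ − y~a,i~ are assigned
var(δ~i~) = v~a~ + v~b~ − 2r√(v~a~v~b~) under an assumed within-study
correlation r, then REML-pooled. On the SMD scale the default orientation
is the difference of magnitudes |y~b~| − |y~a~| (positive = method b claims
the larger benefit, robust to the occasional sign-flipped trial); on the
log-OR scale the signed difference is the log ratio of odds ratios.

Design choices here, each genuinely open:

- **Base-case r = 1.** Only "strong" correlation is defensible a priori for
  estimates sharing participants; r = 1 is the conservative extreme for
  the difference variance and reproduces the published pooled intervals.
  The 0.50–1.00 grid (`sensitivity_r_grid()`) is always reported alongside,
  and the variance-ratio test of ITT-vs-PP outcome spreads supports the
  strong-correlation assumption on simulated data.
- **Degenerate variances.** At r = 1 with v~a~ = v~b~ the difference
  variance collapses to zero; it is floored at 10^-8^ and flagged, letting
  the REML τ² absorb the dispersion — which is why the difference models
  show extreme I² with tiny τ², exactly the pattern the pooled comparisons
  display.

# Replay of the published pooled comparisons

The participant-level data of the seven-trial Dep-GP collaboration are not
redistributable, but the per-trial summaries (B, g, OR, 95% CIs, arm sizes,
complier and missing-adherence counts) are published. The replay pipeline
treats them as stage-one output. Standard errors must be back-derived:

- **Odds ratios**: se(log OR) = (ln upper − ln lower)/(2·z~0.975~) from the
  printed CIs — unambiguous.
- **Hedges' g**: the printed g values carry no CIs. Two derivations are
  implemented. The default (`smd_se = "sample_size"`) is the standard
  analytic SMD variance (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂)) on the analysed
  per-arm sample sizes, which are recoverable exactly from the published
  responder counts; for PP rows the intervention n is scaled by the
  complier fraction, since only adherers are analysed. The alternative
  (`"ci_ratio"`) rescales the printed B interval width by |g/B|. Both
  reproduce the pooled point estimates to well within ±0.02 SMD, but the
  analytic variance also reproduces the published *inference* — the
  CACE-vs-ITT divergence of 0.10 with p = 0.047, the non-significant
  PP-vs-ITT divergence across the whole correlation grid, and I² collapsing
  to ~0 by r = 0.7 — whereas the |g/B| rescaling inherits the 2-decimal
  rounding of the printed g and B and flips the PP-vs-ITT significance
  classification near r = 1. The analytic derivation is therefore the
  default.
- The replay pools g directly (rather than pooling B and standardising the
  pooled value); with trial-specific instruments (BDI-II and PHQ-9) only
  the standardised scale is poolable.

# The synthetic-trial generator

`simulate_trial()` emulates the structure of a primary-care depression
trial; `depgp_scenario()` instantiates seven configurations matching the
published arm sizes (3,467 participants in total), complier fractions
(0.57–0.94), outcome scales, baseline means/SDs, control-arm change,
follow-up retention (≈85%) and missing-adherence counts, with the true
complier effect set to each trial's published CACE point estimate.

Generative model, per participant:

1. latent prognosis U ~ N(0, 1);
2. complier membership ~ Bernoulli(logit^-1^(α + 2·γ·U)), with γ the
   `confounding_strength` knob and α calibrated by numerical integration so
   the marginal complier fraction equals `compliance_prob`;
3. baseline ~ N(μ~b~, σ~b~), rounded and clamped to the instrument range
   (BDI-II 0–63, PHQ-9 0–27);
4. follow-up = μ~b~ + Δ~ctl~ + ρ(baseline − μ~b~) + receipt·CACE +
   assigned-never-taker·η − γσ~e~·U + ε, ε ~ N(0, σ~e~), rounded and
   clamped. ρ is the baseline–follow-up anchoring (default 0.5 — the
   within-trial correlation is not published, so it is an exposed parameter
   rather than an asserted value); η = 0 by default (exclusion restriction
   holds); γ > 0 gives compliers better prognosis, so the PP contrast
   overstates benefit by −γσ~e~·E[U | complier] (recorded analytically in
   the truth ledger) while 2SLS remains consistent;
5. MCAR missingness on outcomes (and, intervention-arm only, adherence).

What it does **not** emulate: measurement error in adherence, MAR/MNAR
dropout, active-control adherence thresholds, multi-arm designs,
time-to-event outcomes, or floor/ceiling pile-up beyond simple clamping.
Passing validation on these data therefore demonstrates estimator
correctness under the identifying assumptions, not robustness to their
violation in real trials.

Clamping note: effect-recovery and coverage simulations are configured so
score distributions stay well inside the instrument range (e.g. control
change −4 with residual SD 6–8 on BDI-II); with large effects stacked near
the floor, clamping attenuates all estimators — a floor effect, visible in
the generator if deliberately provoked, not an estimator defect.

# One-stage analyses

The one-stage models stack participants across trials: a linear mixed
model of the within-trial z-standardised follow-up (adjusted for
z-baseline) or a logistic mixed model of response, with a random trial
intercept and an uncorrelated random treatment effect. Standardisation is
computed on the full trial population before any PP restriction. A fit
whose treatment-effect variance degenerates to zero is refitted as
intercept-only and flagged (`attr(fit, "downgraded")`); z-scored outcomes
routinely have no between-trial intercept variance, which alone does not
trigger the downgrade. Stratification covariates are excluded, as they are
not common across trials.

The exact one-stage machinery behind the published secondary comparisons
is not fully specified in the main text, so two components are explicit
reconstructions: (i) the one-stage CACE is stacked 2SLS with trial fixed
effects and a trial-cluster-robust sandwich (continuous), or two-stage
predictor substitution inside the logistic mixed model (binary, an
approximate IV estimator subject to noncollapsibility); (ii) the one-stage
method comparison duplicates each method's analysis population, stacks
them with a method indicator, and estimates the arm-by-method interaction
with trial-cluster-robust variance — the shared participants are what the
clustering honours. These are validated by simulation (null differences
for identical methods, recovery of injected PP bias, concordance with the
two-stage divergence within 0.02 SMD on a common-effect collaboration),
not against the published one-stage numbers, which require the restricted
participant-level data.

# Numerical and interface choices

- Two-sided 5% significance everywhere; no multiplicity adjustment.
- Normal-theory Wald 95% intervals except the bootstrap percentile
  interval for the binary CACE.
- Outcome direction: lower score = improvement; ingestion of trials that
  test a worsening hypothesis is expected to pre-flip the intervention
  sign.
- Degenerate inputs fail loudly with named errors: empty arms, collinear
  covariates, separation in logistic fits, zero-variance standardisation,
  zero instrument strength, all-missing adherence, duplicate trial ids,
  rank-deficient meta-regression, constant-precision funnel regression.
- Seeds: every stochastic component (generation, missingness, bootstrap)
  takes an explicit seed and restores the caller's RNG state; the pipeline
  writes the seed into the run manifest.
- The command surface is the exported functions plus `run_pipeline()`,
  whose manifest makes every emitted number re-derivable.

## Validation problem sizes

The packaged validation uses: 500-replicate coverage simulations at 300
participants per arm (band 93–97% for ITT and CACE intervals),
500-replicate bias-ordering simulations (π~c~ = 0.6, complier effect −8
BDI points, confounding 0.5), 5,000–50,000-participant single trials for
the estimand-algebra identities, and the seven-trial replay for the pooled
comparisons. These sizes give Monte-Carlo error comfortably below the
tolerances being asserted while keeping the default test run fast.

# Known limitations

- The binary CACE is unadjusted; adjusted principal-stratification models
  (e.g. covariate-specific mixtures) are out of scope.
- Adherence is binary; dose-response or partial-adherence modelling is not
  attempted, and the "acceptable adherence" threshold is taken as given.
- The replay works from published 2-decimal summaries; agreement with the
  published pooled results is bounded by that rounding.
- One-stage CACE estimators are reconstructions (see above) and their
  standard errors rely on a 7-cluster robust variance, which is noisy.
- No as-treated analysis: reclassifying by treatment received discards the
  randomisation and answers no well-defined causal question.
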