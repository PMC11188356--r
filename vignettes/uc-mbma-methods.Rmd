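---
title: "Longitudinal model-based meta-analysis of targeted agents in ulcerative colitis: models, assumptions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal MBMA of targeted agents in ulcerative colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucmbma)
```

## The problem

Randomised trials of targeted agents in moderate-to-severe ulcerative
colitis (UC) report binary efficacy endpoints — clinical remission,
clinical response, endoscopic improvement — at different visits, under
different dose regimens, against placebo groups whose response rates
themselves drift over the trial. A single-timepoint network meta-analysis
discards the time dimension and cannot separate placebo drift from drug
effect. Model-based meta-analysis (MBMA) instead fits one longitudinal
dose–response model to all arm-level aggregate data at once, so that
treatments observed at different visits and doses become comparable on a
common scale.

`ucmbma` implements such an MBMA for twelve targeted agents (five TNF-α,
integrin and interleukin biologics classes plus JAK inhibitors and S1PR
modulators) against placebo, one model per endpoint.

## The observation model

Responder counts in arm $j$ of trial $i$ at week $t$ are binomial,

$$N_{\text{resp},ijt} \sim \mathrm{Binomial}\!\left(N_{ij},\,
P_{ijt}\right), \qquad
P_{ijt} = \mathrm{logit}^{-1}\!\left(E_0(t) + E_{\text{drug}}(t, d) +
\eta_{ij}\right),$$

with $\eta_{ij} \sim N(0, \omega^2)$ a between-arm random effect on the
logit scale capturing residual trial heterogeneity. The additive placement
of $\eta$ on the linear predictor keeps probabilities in $(0,1)$ for any
draw, and makes the arm the exchangeability unit — which is also why the
bootstrap resamples arms (stratified placebo/active) and why simulation
bands optionally include an $\eta$ draw.

An alternative *weighted-normal* objective treats the observed proportion
as Gaussian with standard deviation $\sigma\sqrt{P(1-P)/N}$ — the binomial
standard error scaled by a free residual parameter — optionally with AR1 or
compound-symmetry correlation across visits within an arm
(`objective_config(likelihood = "weighted_normal")`). The exact binomial
likelihood is the default: it is self-weighting and remains well defined at
the extreme proportions that occur at early visits. AR2 and
autoregressive-moving-average residual structures are a documented
limitation: they are not implemented.

## Placebo time-course

Three functional forms are available for the placebo logit $E_0(t)$:

* **exponential**: $E_0 = B + A\,(1 - e^{-k_\text{pbo} t})$, used for the
  clinical remission model ($B=-39.26$, $A=37.04$, $k_\text{pbo}=0.66$
  per week in the packaged parameter set). Note that $B$ and $A$ are
  individually ill-determined (their published CIs span hundreds of logit
  units) while $B+A$ — the asymptotic placebo logit, here $-2.22$, i.e.
  9.8 % remission — and $k_\text{pbo}$ are well identified. The fitted
  model behaves accordingly: refits recover $k_\text{pbo}$ and $B+A$
  tightly while $B$ and $A$ wander along their ridge.
* **restricted cubic spline** in time (Harrell truncated-power basis,
  linear beyond the boundary knots, `rcs_basis()`), used for the clinical
  response and endoscopic improvement models, whose placebo curves rise,
  plateau and then decline (secondary loss of response) — a shape the
  monotone exponential cannot produce.
* **polynomial** (degree ≤ 3), shipped as a candidate form only; it was
  never selected in the packaged final models.

The packaged spline *coefficients* are not printed in any source table.
They are a package calibration, fixed once: knots at weeks 2/6/16, with
the response placebo rising to ≈ 43 % at week 12 and declining to ≈ 20 %
by week 60, and the endoscopic placebo peaking near 24 % — the typical
magnitudes of induction-trial placebo response and endoscopic improvement
in this population. All conclusions that depend on the *drug* parameters
are insensitive to this choice because drug effects are estimated relative
to the concurrent placebo within the same likelihood.

## Drug effect

$$E_{\text{drug}}(t, d) = \underbrace{\left(1 -
e^{-k\,t}\right)}_{\text{onset, if }k\text{ present}} \times f(d),$$

where $f(d)$ is one of

* `emax_flat` — a dose-independent maximum $E_\max$ (the Hill equation
  with $\text{ED}_{50}$ fixed to 0): used for most drugs, for which the
  trials' narrow dose ranges identify no dose–response;
* `emax` — $E_\max d^\gamma / (d^\gamma + \text{ED}_{50}^\gamma)$ with
  $\gamma = 1$ by convention (the dose information in the database cannot
  support a free Hill coefficient);
* `linear` — $S \cdot d$ logit units per mg (filgotinib and etrasimod in
  the response model; upadacitinib and etrasimod in the endoscopic model).

Doses are per-administration milligrams; mg/kg regimens are normalised at
a 70 kg reference weight (`normalize_dose()`, configurable). Onset rates
$k$ may be drug-specific (adalimumab, filgotinib, ozanimod in the
remission model) or shared across a class (one JAK-inhibitor rate in the
response model). Regimen-specific overrides allow one regimen to carry its
own $E_\max$ — the 45 mg upadacitinib induction regimen in the response
model, whose efficacy clearly exceeds the 7.5–30 mg regimens.

The time at which a component reaches 90 % of its maximal effect, ET90, is
exposed on two scales (`et90()`): the onset-factor scale $\ln(10)/k$, and
the probability scale (the root of $P(t) = 0.9\,P(\infty)$, bisection to
$10^{-6}$ weeks). Both are provided because published onset times mix the
two definitions and neither alone reproduces every printed value; for the
remission placebo the probability-scale definition gives 8.7 weeks from
the rounded parameters, matching the published 8.9 weeks to within the
slack of the printed two-decimal rounding.

## Covariate model

Arm-level covariate effects adjust a structural parameter relative to a
reference mean, either additively,
$P_i = P_\text{pop} + (\text{COV} - \overline{\text{COV}})\,\theta$, or as
a power function, $P_i = P_\text{pop} (\text{COV}/\overline{\text{COV}})^\theta$
(`apply_covariate()`). Placebo-targeted effects act on the exponential
asymptote $A$, or on the whole spline $E_0(t)$ level; drug-targeted
effects act on $E_\max$ (or on the slope of a linear dose model).

The source table flags each coefficient as "power function" or
"proportional" but the flag-to-coefficient mapping cannot be resolved
unambiguously, so both forms are implemented and the packaged
specification records an explicit per-effect choice, made once on
dimensional-sanity grounds:

* additive where $\theta$ is per-unit and small (disease duration on the
  remission placebo asymptote and remission $E_\max$; prior-TNF %, age,
  and the endoscopic small-magnitude effects);
* power where an additive reading would be absurd — e.g. the concomitant-
  corticosteroid effect on response $E_\max$ ($\theta = -0.759$) read
  additively *per percentage point* would swing $E_\max$ by tens of logit
  units across observed arms, while the power form gives the plausible
  ±10 % adjustment.

For the same reason the packaged O(1) additive/power drug effects apply
only to Emax-type drugs (a `dose_models` filter in
`covariate_effect()`): an O(1) logit shift added to a slope of
$7\times10^{-3}$ logit/mg has no meaningful interpretation. Because of
this ambiguity the published *simulated absolute percentages* are not a
reproduction target of this package; qualitative treatment ranking is
(and is tested).

Missing covariates are mean-imputed across arms (unweighted by default,
optionally patient-weighted), per endpoint dataset, with imputation flags
retained (`impute_covariates()`).

## Estimation

`fit_model()` maximises the marginal likelihood, integrating $\eta$ out
arm-by-arm with adaptive Gauss–Hermite quadrature (9 nodes by default;
each arm's integrand is re-centred at its posterior mode with curvature
scaling, so even 5–7 nodes are accurate — the packaged test suite checks
that 7 vs 15 nodes agree to $10^{-4}$). $\omega^2 = 0$ reduces exactly to
the conditional likelihood. Numerical choices:

* probabilities are floored at $10^{-8}$ inside logs — the remission
  placebo intercept $B \approx -39$ drives week-0 predictions into
  underflow by design;
* bounded L-BFGS-B with onset-type rates constrained to $(10^{-4}, 10)$
  per week, 5 jittered restarts by default (onset likelihoods can be
  multimodal in $k$), a forward-difference gradient and parameter
  scaling;
* Wald 95 % intervals from the inverse Hessian when it is positive
  semi-definite; bootstrap percentile intervals (`bootstrap_model()`)
  override them when computed.

Model development tools mirror standard practice: likelihood-ratio tests
and AIC for nested comparisons (`compare_models()`), and forward stepwise
covariate selection accepting the smallest-p candidate at $p < 0.05$ when
the AIC also improves (`stepwise_covariates()`).

## Validation and simulation

* `bootstrap_model()` resamples **arms** with replacement, stratified
  placebo/active. The resampling unit is an assumption (the source reports
  only "repeated sampling"); the arm is chosen because it is the model's
  exchangeability unit, and the choice is recorded in the result object.
  Non-converged replicates are dropped and counted, not retried.
* `vpc()` simulates responder counts per design point ($\eta$ plus
  binomial noise), summarising 2.5/50/97.5 percentile bands by exact
  design time (visit schedules are few and shared; no binning). On data
  simulated from the model itself the 95 % band covers ≈ 95 % of
  observations.
* `residual_diagnostics()` tabulates
  $(obs - pred)/\sqrt{P(1-P)/N}$ against time and prediction.
* `simulate_efficacy()` propagates parameter uncertainty by multivariate-
  normal draws from the fit covariance (or bootstrap-row resampling),
  optionally adds one $\eta$ per draw, and evaluates every treatment and
  placebo from the *same* draw so that the placebo-corrected response is a
  within-draw difference before the median is taken. The reference
  scenario is a hypothetical population with 7 years disease duration,
  age 40, 50 % prior anti-TNF exposure and 50 % concomitant
  corticosteroids, weeks 1–60, with the headline comparison at week 12.
  `rank_treatments()` orders treatments by placebo-corrected median with
  deterministic tie-breaks (narrower band, then name).

## The synthetic database

No individual-level or arm-level data are redistributable, so
`paper_design()` encodes the *structure* of the source database: 35
trials, 95 arms, 15,585 patients, 32 placebo arms (4,081 patients), with
per-drug trial/arm/patient counts and covariate medians and ranges
matching the published summary table. Because per-drug trial counts sum
to 39 over 35 distinct trials, four trials host two drugs each
(vedolizumab/adalimumab and etrolizumab/comparator head-to-heads, two of
them without placebo arms) — mirroring the head-to-head designs that the
database actually contains. Visit schedules are not published per trial;
the packaged default gives induction trials visits at weeks 2–12 and
flags the last trial of each multi-trial drug as a maintenance study with
visits at weeks 24–60, which identifies the slow onset rates.

`generate_dataset()` draws arm covariates from truncated normals (median
as centre, range/4 as spread, clipped to the range — the source reports
only median and range), one $\eta$ per arm, and binomial responder
counts. What this emulates — and what it does not: the generator
reproduces marginal design structure and the fitted model's stochastic
components, but real extracted data add digitisation error, correlated
covariates within trials, non-random dose assignment and reporting
selection. Passing the recovery tests therefore demonstrates that the
estimator is consistent for its own data-generating process at the
published design size, not that the published estimates are correct.

The stochastic components the source does not print are calibrated once:
$\omega^2 = 0.09$ (between-arm SD 0.3 logit, consistent with the width of
the published confidence intervals given the per-drug arm counts) and
$\sigma = 1$ for the weighted-normal alternative.

## Problem sizes used in the packaged checks

Replicate refit studies (parameter recovery) use the packaged design at
50 % arm sizes with 20 replicates per endpoint, initialising each refit at
the generating values with a single optimizer start and no Hessian — the
standard parametric-bootstrap protocol, which keeps a full two-endpoint
study within minutes while leaving the estimator's stochastic behaviour
untouched. Unit tests use a 6-trial single-drug design. The pipeline
defaults mirror the reference analysis (bootstrap 1,000, VPC 1,000,
simulation 10,000 draws).

## Known limitations

* Dose is the only exposure metric; no pharmacokinetic modelling.
* AR2/ARMA residual correlation is not implemented.
* The binomial and weighted-normal objectives are alternatives, never
  combined in one fit.
* Power-form covariate effects are undefined at covariate value 0, which
  is why zero-capable covariates (prior-TNF %) are always additive in the
  packaged specs.
* Published simulated absolute percentages are not reproduced (covariate
  form and uncertainty-mechanism ambiguity); ranking agreement is the
  supported claim.

## A worked example

```{r example, eval = FALSE}
library(ucmbma)

spec <- uc_model_spec("remission")
design <- perturb_design(paper_design(), 0.5)
data <- generate_dataset(design, spec, seed = 1)

cfg <- objective_config(n_restarts = 1, compute_vcov = TRUE)
fit <- fit_model(data$records, data$arms, spec, cfg)
print(fit)

boot <- bootstrap_model(data$records, data$arms, fit, cfg,
                        n = 100, seed = 2)
v <- vpc(data$records, data$arms, fit, n_sim = 1000, seed = 3)
plot(v)

sim <- simulate_efficacy(fit, pop = population_profile(),
                         weeks = 1:60, n_draws = 10000, seed = 4)
rank_treatments(sim, week = 12)
```
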