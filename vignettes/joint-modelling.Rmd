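---
title: "Joint modelling of mixed, multilevel, sequential IVF outcomes"
author: "ivfjm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of mixed, multilevel, sequential IVF outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivfjm)
```

## The model

A cycle of in vitro fertilisation is a multistage treatment: ovarian
stimulation yields oocytes, oocytes mixed or injected with sperm yield
embryos, embryos are graded, one or two are transferred, and the transfer
may or may not result in a live birth.  Treatment can fail at any stage, in
which case the downstream stages are never undertaken and their outcomes are
undefined — not zero.  The responses are of mixed type and live on two
levels: per cycle, a count of oocytes $y^O_j$, a count of fertilised embryos
$y^M_j$, a double-embryo-transfer indicator $y^D_j$ and a live-birth
indicator $y^L_j$; per embryo $i$ within cycle $j$, two ordinal 1–4 quality
grades, cell evenness $y^E_{ij}$ and fragmentation $y^F_{ij}$.

`ivfjm` fits six submodels linked by a 6-dimensional multivariate-normal
latent vector $z_j = (z^O, z^M, z^E, z^F, z^D, z^L)_j$:

* **Oocyte count** — Poisson with $\log \lambda^O_j = x_j'\beta^O + z^O_j$;
  the latent term captures between-patient overdispersion.  Fitted to all
  cycles.
* **Fertilisation count** — Poisson with
  $\log \lambda^M_j = \log y^O_j + x_j'\beta^M + z^M_j$.  The offset treats
  every retrieved oocyte as a fertilisation opportunity (oocytes that are
  not mixed are assumed incapable of successful fertilisation, which is why
  the offset uses the full oocyte count).  Fitted to cycles with mixing.
* **Embryo grades** — proportional-odds cumulative-logit models
  $\mathrm{logit}\,\gamma^E_{kij} = \alpha^E_k - x_{ij}'\beta^E - z^E_j$
  (and likewise for fragmentation), $k = 1, 2, 3$, where $\gamma_k$ is the
  probability of grade $\le k$.  The negative signs make positive
  coefficients increase the grade.  The patient-level latents are identified
  by the clustering of embryos within patients.  Category-specific (non
  proportional) coefficients are out of scope.
* **DET and LBE** — latent-variable probits: $y^D_j = 1$ iff
  $x_j'\beta^D + z^D_j \ge 0$ with $z^D_j$ of unit variance (and likewise
  for live birth), fitted to transferred cycles.  Fixing the variance at 1
  makes each submodel marginally an ordinary probit regression while letting
  $z^D, z^L$ correlate with the other latents.

The latent vector is $z_j \sim \mathrm{MVN}(0, \Sigma(\theta, \eta))$ with
$\Sigma$ assembled from four free standard deviations
$\theta = (\theta_O, \theta_M, \theta_E, \theta_F)$, unit variances for the
two probit components, and 15 correlations $\eta_1, \dots, \eta_{15}$ (the
row-wise upper triangle in outcome order).  Once a patient drops out of the
cycle, she contributes nothing to the downstream submodels; the
corresponding latent components are simply unobserved and carry their
conditional prior.

Priors follow the weakly-informative convention for this model family:
normal(0, 1000²) on the count/ordinal coefficients and thresholds,
normal(0, 2²) on the probit coefficients (whose latent scale is fixed),
half-Cauchy(0, 2.5) on $\theta$, and an LKJ(1) prior — uniform over valid
correlation matrices — on the 6×6 latent correlation matrix.

Two covariate settings are supported.  *Pre-treatment* uses only baseline
covariates (age, partner age, attempt number, fertilisation method), so the
model can be deployed before a cycle starts.  *Dynamic* additionally feeds
observed upstream outcomes into downstream submodels — oocyte count and
fertilisation rate ($y^M / y^O$) into the grade, DET and LBE submodels, the
patient-mean grades and DET into the transfer-stage submodels — enabling
mid-cycle prediction.  The stage ordering O < M < {E, F} < D < L is
enforced; evenness and fragmentation are coincident and may not predict each
other.

## Sampler

No general-purpose MCMC backend in this toolchain expresses the fixed-unit-
variance covariance with an LKJ prior, so the package ships its own
adaptive Metropolis-within-Gibbs sampler, vectorised across patients:

* latent columns: vectorised random-walk Metropolis against the
  Poisson/ordinal likelihoods, exact conditional-normal draws where a
  patient has no likelihood term, and exact truncated-normal draws for the
  probit components (the sign rule);
* count and ordinal coefficient blocks: full-covariance adaptive Metropolis
  (Haario-type), with threshold ordering enforced through the prior support;
* probit coefficients: conjugate Gibbs via the $w = x'\beta + z$
  augmentation, plus a collapsed Metropolis step against the
  $z$-marginalised likelihood (partially collapsed Gibbs), which mixes far
  better for weakly identified coefficients;
* translation moves that shift a coefficient and absorb the shift in its
  latent column (likelihood-invariant, accepted on the latent prior ratio),
  and scale moves that rescale a latent SD together with its column —
  together these remove the classic hierarchical-funnel coupling;
* covariance parameters: scalar Metropolis on $\log\theta$ and on the
  atanh canonical partial correlations of a C-vine representation of the
  correlation matrix.  Under LKJ(1) the level-$i$ partial correlation is
  scaled-Beta with shape $1 + (5 - i)/2$, which gives a tractable prior
  density and automatic positive definiteness.

Proposal scales adapt during warmup only (diminishing adaptation, frozen
afterwards), targeting acceptance rates of 0.44 for scalars and 0.234 for
blocks.  Convergence is monitored by split-$\widehat R$ with a default
flagging threshold of 1.05 (the diagnostic convention; the threshold itself
is a package choice), and a fit that trips it warns rather than fails.
Defaults are 3 chains × 2000 iterations with the first half as warmup.

The separate-model baselines (`mode = "separate"`) are deliberately
independent code: standalone samplers for the Poisson-lognormal,
offset-Poisson-lognormal, random-intercept cumulative-logit and plain
probit (Albert–Chib plus a collapsed step) models.  With all correlations
fixed at zero the joint posterior factorises into exactly these six models,
which the test suite exploits as a cross-validation of both samplers.

Probit likelihood contributions can be evaluated two ways and
`joint_log_likelihood()` implements both: the deterministic sign-rule
indicator given sampled $z^D, z^L$ (the sampler's internal mode), and
analytic marginalisation of the two probit latents given the other four via
their conditional bivariate normal.  `marginal_loglik_gh()` integrates a
single patient's likelihood over the latent vector by tensor-product
Gauss–Hermite quadrature, as a numerical reference for tests.

## Synthetic cohorts

The data the methodology was developed on are not publicly available, so
the package is exercised end to end on synthetic cohorts drawn from the
full generative chain (`simulate_cohort()`).  The default coefficients are
the pre-treatment joint point estimates reported for a large routine
clinical cohort (oocyte intercept 2.10, age −0.04 per year, fertilisation
intercept −0.95, evenness thresholds −4.35/−1.38/1.33, fragmentation
thresholds −5.11/−2.44/−0.33, DET intercept 0.13, LBE intercept −0.49,
etc.), with age and partner age centred at 33 and 36 years.  The covariate
generator matches that cohort's baseline table: age median 33 (IQR 30–36),
partner age median 35, attempt frequencies 72/22/5/1%, ICSI probability 0.5
(no rate is reported; fertilisation method is decided prospectively per
cycle, so the flag is cycle-level).

The latent SDs and correlations are **not** estimates from that cohort
(they were published only in an unavailable supplement).  The defaults
θ = (0.5, 0.3, 0.8, 0.9) and η = 0 except a D–L correlation of 0.2 were
chosen once to give realistic overdispersion — e.g. they imply a mean
oocyte yield of ≈ 9.3 and a marginal live-birth rate per transfer of ≈ 32%,
both matching the reference cohort — and are documented as package
defaults, not estimates.

Generator-side conventions that the fitted model does not share, both
documented realism rules:

* $y^M$ is drawn from the offset Poisson *truncated at* $y^O$ (embryos
  cannot outnumber oocytes).  The fitted likelihood is untruncated, as in
  the reference analysis; at the default rates
  $P(y^M > y^O) < 10^{-3}$, so the mismatch is negligible.
* DET is forced to 0 when only one embryo exists.

Transfer defaults to the deterministic rule (transfer iff at least one
embryo); optional thinning probabilities for the mixing and transfer
transitions reproduce the funnel gaps seen in routine data
(2962 → 2861 → 2501 in the reference cohort), transitions the model itself
does not describe.

What the generator does *not* emulate: multiple cycles per woman,
non-linear age effects, informative dropout, miscarriage versus
implantation failure, twin births, frozen-embryo cycles, between-clinic
grading differences, and within-cycle heterogeneity of the ICSI flag.
Passing tests therefore demonstrate self-consistency of the machinery
(estimation, prediction, calibration under the model's own assumptions),
not clinical validity on real data.

## Sequential prediction

`predict_pretreatment()` simulates whole cycles forward, one per posterior
draw, with deterministic failure propagation: no oocytes ⇒ no embryos, no
grades, no transfer, no live birth.  Two latent modes are first-class, and
the caller must choose: `latents = "zero"` sets the four free latents to
zero and draws the probit outcomes with their marginal probabilities
$\Phi(x'\beta)$ (marginal prediction for a new patient at the latent
centre), while `latents = "included"` draws a fresh latent vector per
simulated cycle from $\mathrm{MVN}(0, \Sigma)$, which is the mode needed
for calibrated predictive intervals.

`predict_dynamic()` conditions on a stage-consistent observed prefix
(oocytes; then embryos; then mean grades; then DET), plugging observed
values into downstream linear predictors and simulating only the remaining
stages.  Latents for the remaining stages are drawn from their
unconditional prior (or set to zero); a filtering update of the latents
given the observed outcomes is deliberately *not* performed — the dynamic
models condition through covariates only.

Denominators are explicit throughout.  "Per cycle started" counts upstream
failure as zero embryos / no transfer / no live birth (the treatment-policy
accounting); "per stage reached" restricts to simulated cycles reaching the
stage.  Embryo grades are always summarised conditional on at least one
embryo existing, because a grade is undefined otherwise.  Grade predictions
for a new patient are reported per hypothetical embryo (one grade draw per
simulated cycle) plus the patient-mean grade used as a downstream
covariate.

`joint_event_probability()` evaluates predicates such as "fewer than 15
oocytes *and* a live birth" across draws; failed stages evaluate as
non-events.  Its 95% interval is formed from percentiles, across posterior
draws, of the predicted cohort proportion — not a draw-level binomial
interval.

## Evaluation

`evaluate_predictions()` reports RMSE for the counts and grades (point
predictor: posterior-predictive median, switchable to the mean; grades
treated as equally spaced integers 1–4) and Brier score plus rank-based
AUC with a DeLong 95% interval for DET and LBE.  Following the submodels'
fitting population the binary metrics use the per-transfer denominator, and
the report records it.  In-sample evaluation is permitted but always
labelled — agreement of a model with its own training data does not
constitute validation.  `calibration_data()` produces
interval-versus-observed tables; `plot_calibration()` renders a minimal
figure.

## Numerical choices and scales

* Ordinal probabilities are exact inverse-logit differences; normalisation
  holds to 1e-12 and is asserted in tests.
* Positive definiteness is checked by Cholesky with no jitter; failure is
  an error, never silently repaired (the 15 correlations are not free of
  joint constraints).
* Covariate standardisation: ages are standardised by cohort mean/SD, and
  dynamic outcome covariates likewise by the statistics of the cycles for
  which they are defined.  Whether the reference analysis standardised the
  outcome covariates is unstated; we do, for sampler stability, and record
  the scaling in the fit so reports are converted back to per-unit values.
* Bivariate-normal rectangle probabilities use 1-d adaptive quadrature of
  $\phi(x)\Phi(\cdot)$; Gauss–Hermite reference integration uses 40+ nodes
  per dimension.
* Desk-scale problem sizes: the test suite and the acceptance pipeline fit
  cohorts of n = 300 cycles (≈ 1200 embryos) with 3 chains × 2000
  iterations, the scale at which parameter recovery and factorisation are
  demonstrably stable; the reference analysis itself used thousands of
  cycles and correspondingly longer runs.

## Known limitations

* One cycle per woman; no three-level (woman/cycle/embryo) extension.
* No embryo-level residual correlation between the two grading scales
  beyond the shared patient latents, so the evenness–fragmentation
  relationship within an embryo equals that between embryos of the same
  patient.
* The dynamic joint model's outcome-covariate coefficients are markedly
  less precise than the separate fits' — expected behaviour for this model
  class, surfaced by `check_precision()` as a warning rather than an error.
* The mechanism by which cycles with embryos fail to reach transfer is not
  modelled; the data model permits it and the generator can thin to match
  observed rates.
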