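---
title: "Measuring and modelling visual working memory precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling visual working memory precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwmprecision)
```

## The measurement problem

In delayed-reproduction (continuous-report) experiments, a participant
reproduces a remembered stimulus feature — here the orientation of a coloured
bar — by adjusting a probe continuously. The error on each trial is the
angular deviation between response and target on a circular feature space;
orientation is π-periodic. Performance is summarised as *precision*, the
reciprocal of the circular standard deviation of the error distribution,
corrected so that random responding scores zero. This package implements
that measurement layer, a three-component probabilistic model of the error
distribution, a synthetic cohort generator emulating an age-structured
developmental study, and the cohort-level statistical pipeline.

## Circular statistics

All circular computation is performed after doubling angles onto the
standard 2π-periodic circle, the usual device for axial (π-periodic) data
and the convention of the widely used mixture-model code for this task
family. Circular SDs, precisions and concentrations quoted anywhere in the
package are therefore on the doubled scale.

The dispersion measure is Fisher's circular standard deviation,

$$\mathrm{SD} = \sqrt{-2\,\ln \bar R},$$

where $\bar R$ is the mean resultant length of unit vectors at the (doubled)
error angles. Two numerical guards matter in practice:

* **Resolution cap.** In finite samples of diffuse data $\bar R$ can be
  arbitrarily close to 0, sending the SD to infinity. `circular_sd()` floors
  $\bar R$ at $1/n$ — the resolution limit of $n$ unit vectors — capping the
  SD at $\sqrt{2\ln n}$. The floor is configurable (`rbar_floor`).
* **Zero-dispersion floor.** If all errors coincide, SD = 0; `precision()`
  floors the SD at $10^{-6}$ rad before inverting, so precision is large but
  finite.

**Chance correction.** The expected value of $1/\mathrm{SD}$ for uniform
random responding is strictly positive at finite $n$ and decreases with $n$.
`chance_precision(n)` estimates it by Monte Carlo (default $10^4$ replicates,
fixed seed, cached per trial count) and the pipeline subtracts the estimate
matched to each participant's usable trial count. Uniform responding then
scores zero in expectation, which also licenses one-sample t-tests against
zero as tests of above-chance performance.

**Sensorimotor correction.** Dial adjustment itself contributes error. Under
independence of sensorimotor and memory noise, variances add, so memory
precision is recovered as

$$\text{corrected precision} = \frac{1}{\sqrt{\mathrm{SD}_\mathrm{task}^2 -
\mathrm{SD}_\mathrm{sensorimotor}^2}} - \text{chance}(n).$$

When the memory-task SD does not exceed the sensorimotor SD the subtraction
is undefined; the estimate is returned as `NA`, logged, and excluded from
the affected dependent variable only — never silently dropped. The same
variance-subtraction construction yields *precision differences* between
memory loads and between serial positions. Mean three-item precision is
always computed by averaging error *variance* across serial positions and
then inverting — never by averaging precisions, which is not variance-stable.

## The mixture model

Response error in the three-item task is modelled as a three-component
mixture: with probability $\alpha$ the response is a von Mises deviate about
the target orientation; with probability $\beta$ about one of the $m$
non-target orientations from the same trial (a misbinding, or swap, error,
split uniformly across the non-targets); with probability
$\gamma = 1-\alpha-\beta$ it is uniform (guessing):

$$p(\hat\theta) = \alpha\,\varphi_\kappa(\hat\theta-\theta) +
\frac{\beta}{m}\sum_{k=1}^{m}\varphi_\kappa(\hat\theta-\phi_k) +
\frac{\gamma}{2\pi},$$

with $\varphi_\kappa$ the von Mises density with mean zero and concentration
$\kappa$ (evaluated with exponentially scaled Bessel functions; $\kappa$ is
bounded at 700 to avoid overflow). A single $\kappa$ is shared by the target
and non-target components. With $m=0$ (one-item data) the model reduces
exactly to a two-component target + uniform mixture and $\beta$ is forced
to zero.

### Fitting

`fit_em()` obtains maximum-likelihood estimates by expectation-maximization.
The E-step computes per-trial component responsibilities; the M-step updates
the weights as mean responsibilities and $\kappa$ by inverting the Bessel
ratio $A_1(\kappa) = I_1(\kappa)/I_0(\kappa)$ against the
responsibility-weighted mean cosine of the component-aligned errors. Because
the component means are *fixed* (at the target and non-target orientations),
the sufficient statistic is the resultant component along each component's
axis — the weighted mean cosine — not the free-mean resultant magnitude;
using the magnitude overshoots $\kappa$ and destroys the EM monotonicity
guarantee, which the fitter asserts at every iteration. The inversion uses
the standard two-regime closed-form approximation refined by Newton steps.

Initialisation is a method-of-moments start ($\kappa$ from the resultant of
response−target errors as if all responses were target reports;
weights 0.6/0.2/0.2) plus random restarts (9 by default), best
log-likelihood winning. Convergence is declared when the log-likelihood
changes by less than $10^{-6}$ (at most $10^4$ iterations). In our
convergence checks on 90-trial datasets across the generative range the
random restarts never improved on the moment start, so the cohort pipeline
uses 3 restarts by default (`fit_settings$n_restarts`) to keep full-cohort
analyses fast; `fit_em()` itself keeps the conservative 9.

**Identifiability.** When the data are uniform, the likelihood is flat
along the $\kappa \to 0$ ridge where the von Mises components coincide with
the uniform component, so the fitted weight split is arbitrary. Fits are
flagged `kappa_identifiable = FALSE` when the log-likelihood margin over the
pure-uniform model is below the 95% chi-square bar (2 df), or when
essentially no responsibility mass lands on the von Mises components.

**Serial-position-specific concentration.** The sequential three-item design
produces a strong recency effect: the most recent item is stored with much
higher concentration. A pooled fit with one shared $\kappa$ is then
misspecified, and the misfit is absorbed asymmetrically — the broad tails of
the earlier serial positions read as extra uniform mass, more so the lower
$\kappa$ is. In cohorts where $\kappa$ grows with age this induces a
*spurious negative age trend in the fitted guessing rate* (and a positive
one in the target weight). The pipeline therefore fits shared weights with a
serial-position-specific $\kappa$ (`fit_em(groups = probed_index)`) and
reports $\kappa$ as the trial-count-weighted mean across serial positions.
Simulation with constant generative weights confirms this removes the
spurious weight trends while leaving $\kappa$'s age effect intact. The
pooled single-$\kappa$ fit remains available
(`fit_settings$kappa_by_sp = FALSE`).

`grid_oracle_fit()` provides an independent brute-force check: exhaustive
evaluation of the likelihood over a parameter grid on small datasets. The
test suite requires the EM solution never to fall below the grid optimum.

## The synthetic cohort generator

No participant-level data are deposited for the study design this package
targets, so the generator produces cohorts with the design's statistical
structure, making every downstream stage testable. It emulates:

* 87 participants aged 7.9–13.6 years (uniform), mapped to school year
  groups by age cut points (years 3 and 4 collapsed);
* an estimated-IQ covariate with the reported weak age correlation
  ($r \approx 0.26$);
* per participant: 25 sensorimotor trials (target visible; response = target
  + motor noise), 30 one-item trials, and 90 three-item sequential trials
  with 5 colours drawn without replacement, orientations uniform on π rad
  under a 0.175 rad minimum pairwise separation (batch rejection sampling),
  and the probed item uniform among the three;
* responses drawn from per-participant mixture parameters, composed with
  independent von Mises motor noise whose SD equals the participant's
  sensorimotor SD — so the variance-additivity assumption of the
  sensorimotor correction holds by construction. Exact von Mises
  convolution is not closed-form; wrapped addition of independent deviates
  is used, an excellent approximation at the concentrations involved;
* a recency effect, modelled as a multiplicative concentration boost
  (default ×3) when the third serial position is probed;
* optionally, incomplete three-item sessions (`truncate_sessions()`),
  mirroring participants who ran out of time.

### Calibration of the generative defaults

Generative parameters follow linear age trends with participant-level
lognormal noise (CV 0.2 for concentrations, 0.15 for motor SD). The default
intercepts and slopes were derived by inverting the precision pipeline
against published year-group mean precisions for this design (sensorimotor
≈ 8→12 rad⁻¹, one-item ≈ 2→3.9 rad⁻¹, three-item mean ≈ 0.4→1.15 rad⁻¹
across ages 9→13): given a target corrected precision, the chain
chance-correction → variance subtraction → mixture resultant
$\bar R = \alpha A_1(\kappa)$ is solved for $\kappa$. Two consequences are
worth noting. First, the published three-item magnitudes are only
attainable with a high target weight ($\alpha_3 = 0.92$; with, say,
$\alpha_3 = 0.75$ mixture dispersion caps three-item precision near
0.8 rad⁻¹, far below the published serial-position-3 values). Second,
misbinding and guessing rates are correspondingly low
($\beta_3 = 0.03$, $\gamma_3 = 0.05$), consistent with reports that
non-target responding is rare in this paradigm. Mixture weights are
age-constant by default, so the generator embodies the hypothesis that
development acts on representational precision ($\kappa$), not on guessing
or misbinding — the pattern the analysis pipeline is designed to detect.

What the generator does *not* emulate: reaction times, encoding-time
effects, colour-vision issues, attention lapses with temporal structure, or
any nonlinearity in the age trends. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real data share that structure.

## The analysis pipeline

`analyze_cohort()` stages the study's statistics:

1. **Per-participant measures** (`compute_measures()`): circular SD per
   condition and serial position; chance- and sensorimotor-corrected
   precisions; variance-subtraction precision differences (three-item vs
   one-item; third serial position vs the pooled mean variance of the first
   two); the mixture fit.
2. **Outlier rule** (`exclude_outliers()`): per dependent variable only,
   values more than 2.5 sample SDs from the sample mean (single pass,
   strict inequality) are removed; every exclusion, undefined variance
   subtraction and non-converged fit is enumerated in the exclusion log,
   which the tests reconcile exactly against the analysed counts.
3. **Age effects**: ordinary least-squares regression of each measure on
   continuous age (slope, adjusted r², p) and partial correlation
   controlling for the IQ covariate (Pearson on residuals by default;
   rank-based variant available), with `df = n − 3`.
4. **Above-chance tests**: two-tailed one-sample t-tests of corrected
   precision against zero per year group.
5. **Serial position**: one-way repeated-measures ANOVA across the three
   serial positions with Greenhouse–Geisser correction (epsilon from the
   eigenvalues of the double-centred covariance of the repeated measures;
   F cross-checked against `stats::aov`), plus all pairwise paired t-tests.
6. **Mixture parameters**: the regression/partial-correlation contract
   applied to κ, α, β, γ separately (the parameters are not independent,
   so no joint test is attempted), converged fits only.
7. **Response histograms**: response errors re-centred on the target and on
   each non-target, binned into nine equal bins across the π rad of
   response space.

No multiple-testing correction is applied by default, matching common
practice for this design; a Holm option exists on the p-value columns.

### Open choices, and how they were resolved

* *Composition of the two corrections*: chance is subtracted after the
  sensorimotor variance subtraction, with the chance estimate matched to
  the task's trial count.
* *Recency difference*: the pooled first/second serial-position variance is
  the arithmetic mean of the two error variances.
* *t-tests against chance*: run on chance-corrected, sensorimotor-corrected
  precision (raw chance-corrected precision for the sensorimotor task
  itself).
* *Truncated sessions*: all available trials are used; chance correction is
  matched to each participant's usable count.
* *Boundary convention*: a value at exactly 2.5 SD is retained.

## Problem sizes and runtime

The test suite exercises the full chain at the study's own scale: 87
participants × 145 trials, with 50 replicate cohorts for the
result-pattern checks (a few minutes of CPU). Parameter-recovery checks use
5,000-trial datasets; chance estimates use 10⁴ Monte Carlo replicates;
design-fidelity checks sample 10⁵ orientation triples. These sizes were
chosen so that Monte Carlo error is small relative to the tolerances being
asserted.

## Known limitations

* Precision values are tied to the doubled-angle convention; comparisons
  with analyses performed on the raw π scale require rescaling.
* The sensorimotor correction assumes independent, additive error sources;
  violations (e.g. strategy changes between tasks) bias corrected precision.
* The mixture model shares κ between target and non-target components and
  assumes swaps are uniform over non-targets; distance-dependent swap
  gradients and trial-to-trial κ variability are out of scope.
* At 90 trials per participant, weight estimates are noisy (SDs of a few
  percentage points); cohort-level inference on weights is correspondingly
  conservative.
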