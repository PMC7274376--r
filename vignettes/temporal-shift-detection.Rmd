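---
title: "Temporal-shift detection: models, stimuli and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-shift detection: models, stimuli and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempshift)
```

## The experiment this package models

A listener hears a sequence of *quintets* — groups of five 10 ms
narrowband sounds separated by 10 ms gaps (a 50 Hz inner rate, 90 ms
active span) — repeated at a slow outer rhythm, and reports whether any
quintet contained a *temporal shift* (TS): a displacement of the
quintet's third sound by a few milliseconds. The design manipulates

* the outer **rhythm** (periodic at 1, 2, 4 or 8 Hz),
* the **carrier frequency** of the narrowband sounds (200, 1100, 3100 Hz),
* the **temporal structure** (periodic, aperiodic with matched quintet
  count and duration, or a single temporal *cue* 500 ms before a probe
  quintet),
* and **task difficulty** (a fixed 6 ms shift, or a shift between 1.5 and
  7 ms held at each listener's ~70% detection threshold by an adaptive
  staircase).

Targets occur on 75% of trials; the remaining catch trials measure false
alarms. The package implements the full machinery — stimulus synthesis,
trial sequencing, adaptive tracking, a simulated observer, and the
signal-detection analysis — so every stage can be exercised and tested
without collecting human data.

## Sensitivity model

Analysis follows equal-variance Gaussian signal detection theory. The
classical estimator is

$$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{false-alarm rate}),$$

available as `dprime_classic()`, with an optional log-linear correction
$(\text{count}+0.5)/(N+1)$ that keeps perfect rates finite. The same
quantity is estimated by probit regression of the yes/no response on a
signal-presence indicator $X$:

$$\Phi^{-1}\!\big(\Pr(\text{yes})\big) = \beta_0 + \beta_1 X,$$

where $\beta_0$ is the z-transformed false-alarm rate and $\beta_1 = d'$.
`sdt_design()` builds this design with the intercept column coded $-1$
("Criterion", so its coefficient is directly interpretable as the
response criterion and correlates less with the other effects), dummy
codes the condition factors (reference levels 1 Hz, 1100 Hz, aperiodic),
and crosses them with `Target`; each `Target:condition` coefficient is a
d' difference. `fit_probit()` implements the maximum-likelihood fit by
iteratively reweighted least squares in this package (an established GLM
routine is used in the test suite only as an independent oracle), and on
any saturated design reproduces the classical closed form to $10^{-8}$ —
the module's central correctness property. `fit_probit_mixed()` adds a
normal subject random intercept via a Laplace approximation (inner
Newton profiling of the per-subject modes, outer quasi-Newton over fixed
effects and log SD); at zero estimated variance it reduces to the fixed
fit, and on heterogeneous cohorts it agrees with `lme4::glmer`'s Laplace
fit to ~$10^{-3}$.

Inference uses Wald-type F contrasts (`contrast()`), likelihood-ratio
tests of nested fits (`lr_test()`), and Bonferroni correction
(`bonferroni()`). Group d' figures use the traditional route: per-subject
classical d' per cell, with subject-level nonparametric bootstrap
(resample subjects with replacement, N = 1000 by default) percentile 95%
intervals (`bootstrap_dprime_ci()`). Reaction-time analysis takes natural
logs of correct-trial RTs measured from target onset, averages within
subject and cell (`logrt_summary()`), and fits ordinary linear models on
those means.

## Stimulus synthesis

A narrowband sound is the sum of 21 unit-amplitude sinusoids with
independent uniform random onset phases, linearly spaced (edges
inclusive) across a 4-ERB passband centred on the carrier, where one ERB
follows Glasberg & Moore: $\mathrm{ERB}(f) = 24.7\,(4.37 f/1000 + 1)$ Hz.
The summed waveform is peak-normalized to 1, then scaled by a per-carrier
`gain` that stands in for the study's subjective loudness equalization
(which is not reproducible in software). Audio renders at 44.1 kHz /
16 bit.

Choices the source design left open, fixed here once:

* **Component spacing / normalization** — linear spacing inclusive of the
  band edges; "amplitude normalized to 1" read as unit-amplitude
  components with the *sum* peak-normalized. Per-component energy
  normalization would change nothing detectable by the analyses here.
* **Shift direction** — a *delay* of the third sound by default
  (configurable), since the direction is not specified.
* **Gating** — 1 ms raised-cosine onset/offset ramps by default
  (`ramp_ms = 0` disables), to limit spectral splatter of the 10 ms
  gates.

A note on spectral containment: the invariant "≥ 90% of energy inside
the 4-ERB passband" is asserted on a 200 ms synthesis, where the
periodogram resolves the band. It cannot hold for the 10 ms gated sound
at the 200 Hz carrier: a 10 ms window smears each component by roughly
±100 Hz, which is comparable to that carrier's 185 Hz band. This is a
time-bandwidth limit of the experimental stimulus itself, not an
implementation artifact. With edge-inclusive spacing the long-duration
containment asymptotes near 95% (the two edge components place half
their energy outside the nominal band).

## Sequence and session construction

`periodic_timing()` places quintet $k$ at $(k-1)/\text{rate}$.
`aperiodic_timing()` draws onset-to-onset intervals independently and
with equal probability from two uniform distributions whose means
bracket the periodic interval (250/1500 ms at nominal 1 Hz, 100/733 ms
at 2 Hz; half-width half the mean), then rescales the interval vector so
the final onset coincides exactly with the periodic counterpart's —
guaranteeing the defining constraint, the same number of quintets in the
same total time. Draws that would bring onsets closer than the 90 ms
quintet span are rejected (bounded at 1000 redraws). The two-interval
mixture necessarily makes the *average* sampled interval (875 ms at
1 Hz) differ from the periodic one before rescaling; the rescaling
absorbs this, so the achieved rate equals the nominal rate exactly. The
source description's achieved averages (1.07/2.2 Hz) are not derivable
from the stated means under any simple mixing scheme and are treated as
descriptive. Aperiodic sequences exist only at nominal 1 and 2 Hz;
faster rates leave no room between quintets. Whether the source sampled
the short and long interval alternately or independently is unstated;
independent draws are used.

Target positions use labels 9, 10, 11: variant 1a keeps the ordinal
quintet index constant across rates, variant 1b keeps the *time*
constant (index = label × rate). `build_session()` lays out the full
designs — 480 trials (40 rate-blocks of 12) for the rate experiments,
432 trials (6 blocks × three 24-trial condition groups) for the
threshold experiment, 80 for the aperiodic pilot — with exactly 75%
target prevalence, every (position × carrier) cell appearing equally
often among a block's target trials, and block/group order
counterbalanced across subjects by Latin-square rotation. Trial order
within blocks is randomized reproducibly from the master seed; one
master seed deterministically spawns per-subject and per-stage
substreams so stages can be rerun independently.

## Adaptive staircase

The 2-down-1-up rule (`staircase_update()`) steps one level harder after
two consecutive correct responses and one level easier after any error,
over a ladder of 10 logarithmically spaced shifts from 7 ms down to
1.5 ms; tracks start at the easiest level and terminate after 200 trials
or 15 reversals. Its fixed point is the 70.7% correct level
($\sqrt{1/2}$), which the package treats as the source's "70% detection
threshold". Decisions left open and fixed here: boundary-clamped steps
do not move the track and do not count as reversals; the block threshold
is the geometric mean of the reversal levels after discarding the first
two (the estimator itself was unreported); catch trials do not drive the
staircase.

## The simulated observer (synthetic data)

`observer_params()` defines the generative twin of the analysis model:
cell sensitivity $d'(\Delta) = d_\mathrm{ref}\,(\Delta/6)^{\gamma}$ plus
additive offsets per rhythm, carrier, temporal condition and position,
floored at zero; responses follow
$\Pr(\text{yes}\mid\text{target}) = (1-\lambda)\,\Phi(d'/2 - c) +
\lambda/2$ and $\Pr(\text{yes}\mid\text{catch}) =
(1-\lambda)\,\Phi(-d'/2 - c) + \lambda/2$, with the catch-trial $d'$
taken from the cell's target shift; correct detections get log-normal
RTs with condition offsets, truncated to the response window (sequence
remainder plus 1 s); false-alarm RTs are uniform over the sequence (the
analysis never touches them). Between-subject heterogeneity is a normal
perturbation on $d_\mathrm{ref}$ and $c$ (SD 0.2 each), the generative
counterpart of the subject random intercept.

Defaults are the published effect sizes wherever the study reports one:
condition d' offsets +0.5903 (periodic) and +0.7154 (cue) versus
aperiodic; rhythm offsets +0.0750/−0.4874/−1.0152 (2/4/8 Hz vs 1 Hz);
carrier offsets +0.0983/−0.8381 (200/3100 Hz vs 1100 Hz); log-RT offsets
−0.3317 (periodic) and −0.6647 (cue) versus aperiodic and
−0.1078/+0.0631 for the 200/3100 Hz carriers. Where no value exists, a
value was fixed once: $d_\mathrm{ref} = 2$ at the 6 ms reference shift
(placing the threshold-experiment staircases mid-ladder, near 4.8 ms),
criterion $c = 0.25$ (conservative responding, false-alarm rates near
0.1–0.15 as is typical for yes/no detection), $\gamma = 1.3$ (any
monotone psychometric suffices; the exponent is configurable), lapse
$\lambda = 0$ (the generator emulates the statistical structure the
probit SDT analysis assumes, which has no lapse parameter), position
offsets 0 (unconstrained by the study), log-RT location $\log(0.75)$ s
and scale 0.35.

What the generator does *not* emulate: within-sequence per-quintet
decision dynamics (responses are trial-level yes/no, matching the
analysis grain, so position effects exist only through the position
offset), sequential dependencies, learning or fatigue, drift-diffusion
RT structure, and any neural entrainment process. A green
parameter-recovery test therefore establishes that the analysis recovers
the parameters of *this* observer class, not that the study's
substantive conclusions are correct.

## Numerical and testing choices

* Probit IRLS iterates to a relative deviance change below $10^{-12}$;
  fitted means are clamped to $[10^{-10}, 1-10^{-10}]$. Linear
  predictors beyond $\pm 7$ at convergence are diagnosed as perfect
  separation, with the advice to aggregate cells or use the corrected
  classical estimator.
* The Laplace outer optimization runs BFGS on $(\beta, \log\sigma)$;
  $\log\sigma$ keeps the SD positive, and a near-zero $\hat\sigma$
  simply reproduces the fixed fit.
* Staircase convergence is measured on trials after each track's first
  reversal (standard burn-in removal).
* The type-I calibration world sets all condition offsets *and* the
  between-subject SDs to zero, because the calibrated tests (ordinary
  probit Wald-F and LR) assume i.i.d. observations; with a random
  intercept in the generator those tests are anticonservative by
  construction and the mixed model is the appropriate tool.
* Parameter-recovery cohorts fix the shift at the mean observer's 70.7%
  point (≈4.85 ms, computed from the defaults at run time) instead of
  running per-block staircases, so the generating cell d' values are
  exact closed-form quantities and coverage has a well-defined estimand;
  the condition contrasts are additive offsets and therefore
  shift-invariant.

## Known limitations

* **Bootstrap coverage.** With the study's own design sizes (20
  subjects, 144 trials per cell, 25% catch), the subject-level
  percentile bootstrap around the corrected classical d' covers the
  generating value in about 89–91% of cohorts, not 95%: the corrected
  estimator carries a small negative bias (~0.026, about a third of the
  cohort-mean SE, dominated by the log-linear shrinkage of false-alarm
  rates estimated from 36 catch trials) and the n = 20 percentile
  interval is ~2% anticonservative. The acceptance test asserts the
  nominal 95% ± 2% band and is expected to fail there; the package
  reports the interval the study's method defines rather than widening
  it.
* Exact agreement with the study's MATLAB `fitGLME` fits (denominator
  degrees of freedom, third-decimal coefficients) is not guaranteed;
  Wald tests with matching numerator df are used, and the log-RT log
  base is natural log (unstated in the source).
* Reproducing the published coefficients exactly requires the deposited
  human trial data, which this package does not ship; `analyze_dataset()`
  accepts any trial log in the documented schema after column mapping.
* Loudness equalization is a per-carrier linear gain, not a model of
  perceived loudness.
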