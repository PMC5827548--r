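---
title: "Phase-binned target detection under 10-Hz stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-binned target detection under 10-Hz stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedetect)
```

## The scientific question

The phase of alpha-band (8–12 Hz) cortical oscillations covaries with
moment-to-moment visual awareness: targets arriving at one phase of the
cycle are detected more often than targets arriving half a cycle later. If
a 10-Hz oscillating transcranial current (otCS) entrains those
oscillations, detection of a masked visual target should become a periodic
function of the time between the most recent stimulation pulse and target
onset (the *pulse-to-target SOA*), in the otCS condition but not in a sham
condition. `phasedetect` implements the complete analysis chain for this
design, together with a generative simulator of the experiment, so the
chain's operating characteristics — type-I error, power against the
entrainment amplitude, parameter recovery — can be measured rather than
assumed.

## The experiment being modelled

One session per condition (sham, otCS; order counterbalanced across
participants): 3 blocks of 128 trials, 20% of trials target-absent
(catch), fixation for 400 ms, a blank of 200–408.33 ms (eight fixed tSOA
values), an 8.33-ms target, a backward mask at a constant 41.7-ms
target–mask SOA, and a 1000-ms response window. Stimulation pulses are
2.5 ms long every 100 ms. `session_plan()` carries these values as
defaults; `build_schedule()` derives each trial's pulse-to-target SOA from
the cumulative trial timeline.

Three scheduling conventions are deliberate choices where the design
description is silent:

* the per-block catch count is fixed at `round(0.2 * 128) = 26` rather
  than Bernoulli-drawn, which stabilizes detection-rate denominators;
* the pulse train is phase-locked to block onset (phase 0 at block start)
  and runs continuously through the block — the experiment's continuous
  pulse train makes any fixed origin equivalent for the modular SOA;
* SOA bins are half-open, `[10k, 10(k+1))`, so a target coincident with a
  pulse has SOA 0 and lands in bin 0.

tSOAs are drawn uniformly *with replacement* from the eight-value set;
balanced sampling was not stated and is not assumed. Because the eight
tSOAs spread over the 100-ms cycle and trial durations accumulate
non-commensurately, all ten 10-ms bins receive trials at realistic trial
counts (a tested invariant).

## The staircase

Target luminance is adapted by a 3-up/1-down transformed staircase: a hit
lowers luminance by `step_down`; three *consecutive* misses raise it by
`step_up`. The label "3-up/1-down" is ambiguous in the psychophysics
literature; this reading is forced here because, in a detection task,
misses must make the target easier. No fixed-step rule with equal steps
converges at exactly 50% detection, so the step *ratio* does the work. The
run counter is a three-state Markov chain whose stationary up-step rate is
$q^3/(1+q+q^2)$ with $q = 1-p$; balancing expected movement
$p\,\Delta_{down} = \frac{q^3}{1+q+q^2}\Delta_{up}$ at $p = 0.5$ requires
$\Delta_{up}/\Delta_{down} = 7$. The absolute step size is then calibrated
by simulation (`inst/scripts/calibrate_staircase.R`): large steps interact
with the curvature of the psychometric function and bias the asymptote
upward (+0.018 at `step_down = 0.4`), so the shipped default is
`step_down = 0.1`, `step_up = 0.7` (asymptotic rate 0.505 ± 0.006 for a
mid-slope logistic observer). Catch trials and no-response trials never
update the staircase. The converged level can be estimated from trailing
reversals or from a trailing trial window (the analogue of averaging
luminance over final blocks).

## The generative observer

`observer_params()` defines hit probability on target-present trials as a
lapse-adjusted logistic of a log-odds predictor

$$\eta = s\,(L-\theta) \;+\; A\,\sin(2\pi\,\mathrm{SOA}/T + \varphi)
  \;+\; \beta_{fat}\,(trial-1) \;+\; \beta_{seq}\,[second],$$
$$p = (1-\mathrm{lapse})\,\sigma(\eta).$$

The entrainment term lives on the log-odds scale so that $p$ stays in
(0, 1) for any amplitude $A$; the downstream sinusoid is nevertheless fit
on the standardized *rate* scale, exactly as the analysis it emulates.
That scale mismatch is intentional — the analysis under test does not get
to see the generative scale.

Defaults, chosen once from the phenomena the design is known to produce
(they are conditions, not dials):

* `lapse = 0.02`, false-alarm rate on catch trials `guess_fa = 0.05`,
  `no_response_rate = 0.02` — typical for trained observers in masked
  detection;
* `fatigue_slope = -0.003` log-odds/trial, resetting at each block start:
  over a 128-trial block this is a ≈ 0.38 log-odds decline, reproducing
  an observed within-block drop of detection rates from ≈ 0.57 to ≈ 0.46
  with worst performance at block ends;
* `condition_offset = +0.2` log-odds for the *second-performed* condition
  — the practice/sequence effect (≈ +0.05 in rate near the midpoint)
  that motivates the normalization step below;
* population spread: thresholds $N(50, 5)$, slopes log-normal (CV 0.2),
  and session luminance set to the participant's threshold plus a
  $N(0, 1)$ *calibration error*, emulating a staircase-set luminance near
  50% detection without re-running a staircase inside every simulated
  cohort.

`simulate_cohort()` assigns exactly half the (even-sized) cohort to each
condition order, keeps $A = 0$ in sham always, and is bit-reproducible
from one master seed.

What the generator does *not* emulate: trial-to-trial dependence beyond
the fatigue drift (no streaks, no criterion drift), biophysical
entrainment dynamics (onset transients, frequency mismatch against
individual alpha), and response times are schematic. Passing operating
characteristics therefore speak to the *analysis chain* under a clean
observer model, not to every property of real behavior.

## From trials to analysis units

`detection_rates()` excludes catch trials and trials without a valid
response, then computes hits/(hits+misses) per participant × condition in
each of the ten 10-ms bins. Empty bins carry `NA` (with count 0) and
propagate as missing into the sine fit, which requires ≥ 5 non-missing
bins. `standardize_rates()` z-scores the ten bins within each
participant × condition (mean 0, unit sample SD); "normalization" could
also be read as mean-centering only, so `method = "center"` is provided,
but the z-score is the default — it is what makes a "standardized
detection rate" axis meaningful and removes both the sequence offset and
scale differences. A constant rate profile cannot be z-scored and raises
an error advising exclusion. `timecourse_rates()` splits each condition's
384 trials, in presentation order, into 12 bins of 32; exclusions empty
the numerator/denominator but not the position count, so block boundaries
stay aligned after bins 4 and 8.

## The sinusoidal model

Per participant × condition the standardized rates $x(t)$ at the bin
centers $t = 5, 15, \dots, 95$ ms are fit with

$$x(t) = \alpha_0 + \alpha_1 \sin(\omega t + \varphi),
  \qquad \alpha_1 \ge 0,\; \varphi \in (-\pi, \pi],$$

with $\omega$ *fixed*. The source description of the frequency ("0.06
bins/cycle (100 Hz)") is internally inconsistent; this package fixes
$\omega = 2\pi/100 \approx 0.0628$ rad/ms — one full cycle per 100-ms
pulse period, i.e. 10 Hz, which matches both the printed 0.06 and the
logic of the design. $\omega$ remains a configurable argument.

Numerical choices:

* Multistart bounded nonlinear least squares (L-BFGS-B, analytic
  gradient), $\varphi$ explored on $[-2\pi, 2\pi]$ and wrapped into
  $(-\pi, \pi]$ afterward; $\alpha_1$ bounded at 0 — the bound is closed
  so the flat solution is admissible.
* One start is seeded from the exact linearization
  $\alpha_0 + b_1\sin\omega t + b_2\cos\omega t$ (ordinary least squares,
  then $\alpha_1 = \sqrt{b_1^2+b_2^2}$, $\varphi = \mathrm{atan2}(b_2,
  b_1)$); the remaining starts are random ($\alpha_0$ near the data mean,
  $\alpha_1 \sim U(0, 2\,\mathrm{SD})$, $\varphi \sim U(-\pi,\pi)$).
  Because the fixed-frequency model is linear in $(b_1, b_2)$, the seeded
  start already sits at the global optimum; the random multistart is kept
  as the fitting contract and as protection for degenerate inputs. Tests
  verify the fit against a $51^3$ grid search and the closed-form
  optimum, neither of which shares code with the optimizer.
* A constant input is degenerate: by convention $\alpha_1 = 0$,
  $\varphi = 0$, $R^2 = R^2_{adj} = 0$.
* $R^2_{adj}$ counts $p = 3$ free parameters ($\omega$ is fixed, not
  counted).

Conditions are compared with a paired t-test on $\alpha_1$ (with the JZS
Bayes factor attached) and a Wilcoxon signed-rank test on $R^2_{adj}$.

## The inferential toolbox

**Mixed ANOVA, two error models.** The published df pattern for the
condition × order interaction, $F(1, 646)$, is only obtainable when the
within-subject error strata are pooled into a single residual:
participants enter as an additive block and all remaining variation forms
one error term ($720 - 1 - 35 - 38 = 646$ df for 36 × 2 × 10 with two
order groups). The conventional split-plot analysis instead tests each
within effect against its own participant-interaction stratum (condition
× order on $F(1, 34)$). Both are provided — `error_mode = "stratified"`
(default, statistically conventional) and `"pooled"` (replication mode) —
because they answer subtly different questions and only together explain
the printed numbers.

**Sphericity.** Mauchly's $W$ and Greenhouse–Geisser $\varepsilon$ are
computed from the eigenvalues of the orthonormal-contrast covariance of
the within-subject scores (pooled within between-subject groups where
applicable); $W$'s p-value uses the standard first-order chi-square
approximation with the usual small-sample factor
$f = 1 - (2d^2+d+2)/(6d\,(n-g))$. Corrected dfs are $\varepsilon$ × raw
dfs on both sides of the ratio. Two-level effects have $W = \varepsilon =
1$ identically. Agreement with `stats::mauchly.test` (exact, for $W$) and
`car::Anova` (exact, for $\varepsilon$) is under test; the p-value
differs from `mauchly.test`'s higher-order expansion in the third
decimal.

**Wilcoxon signed-rank.** Conventions are pinned so the Z statistic is
bit-reproducible: zeros dropped, midranks for ties, tie-corrected
variance, *no* continuity correction, $Z = (W^+ - \mu)/\sigma$. For ≤ 12
non-zero differences an exact two-sided p from the full $2^n$ sign
enumeration is reported alongside.

**JZS Bayes factor.** The default-prior Bayes factor for the paired t
statistic places a Cauchy(0, 0.707) prior on the standardized effect
size, expanded as a normal scale mixture with
$g \sim \mathrm{InvGamma}(1/2, r^2/2)$, and integrates the resulting
one-dimensional marginal likelihood by adaptive quadrature (split at the
prior median; relative tolerance $10^{-9}$). An independent oracle — the
noncentral-t likelihood integrated against the Cauchy prior on a
trapezoid grid — agrees to $10^{-5}$ across a $(t, n)$ grid in tests. At
the published $t = 0.65$, $n = 36$ the integral gives $BF_{10} = 0.218$,
printing as 0.22.

**Dirichlet-process signed-rank.** The Bayesian counterpart of the
signed-rank test puts a DP prior on the distribution of the paired
differences and samples the posterior of $\theta = P(d > 0)$ by
Dirichlet-weighted resampling; `prior_strength = 0` (default) is the
Bayesian-bootstrap limit, and $s > 0$ adds a pseudo-observation at zero
contributing $\theta = 1/2$. Rank-based Bayesian tests natively report
dominance probabilities, not $P(H_0)$; the reported `posterior_p_h0` is
therefore an explicit interpretation — the posterior mass of $\theta$
inside the practical-equivalence region $0.5 \pm 0.05$ — and both the
region and $s$ are configurable.

**Paired t and Holm** are `stats::t.test` and `stats::p.adjust` behind
stable interfaces. A zero-variance difference vector is an error for the
bare `paired_t()` (the statistic is undefined); `compare_conditions()`
treats the one well-defined special case — literally identical amplitude
lists — as the exact null, $t = 0$.

## EEG cleaning

The described (ultimately unused, because stimulation artifacts proved
unremovable) EEG path is implemented and exercised purely on synthetic
fixtures: per-trial pre-target (−300–0 ms) baseline subtraction, rejection
of trials exceeding 1000 µV on any channel, epoching to −800…1000 ms,
regression-based ocular correction, a second baseline subtraction with the
same window, and a final 500-µV rejection. The narrative's unusual stage
*order* (baseline and first rejection before epoching) is preserved as
the default `mode = "narrative"`; since both operate on the same pre-target
window, a conventional ordering gives identical epochs and is available
behind the flag. The ocular correction is the simplest regression
variant: event-related averages are subtracted from EEG and EOG, one
propagation coefficient per (channel, EOG-channel) pair is estimated
jointly by least squares, and the scaled raw EOG is subtracted from every
trial; a blink/saccade-partitioned variant is an extension point, not
implemented. The synthetic generator (10-Hz signal with per-trial random
phase, optional 1/f noise, raised-cosine blink templates with known
propagation coefficients) is the ground truth for the recovery tests.

## Operating characteristics and problem sizes

`operating_characteristics()` sweeps the entrainment amplitude over
$A \in \{0, 0.1, 0.25, 0.5, 1.0\}$ on the log-odds scale — from the null
through saturating modulation (at $A = 1$ the hit probability swings
roughly 0.27–0.73 at midpoint luminance) — simulating full cohorts of 36
participants × 2 × 384 trials and recording the rejection rate of the
two-sided amplitude t-test at $\alpha = 0.05$. Inside these loops the
sine fits use `n_starts = 3` (the seeded linearization start reaches the
global optimum; the grid-oracle property licenses the reduction) and the
ANOVA/figure stages are skipped, since only the amplitude comparison
feeds the decision. The shipped test suite measures: type-I error over
1000 null cohorts (binomially compatible with 0.05 and
Kolmogorov–Smirnov-uniform p-values), monotone power in $A$ with > 95%
rejection at $A = 1$, phase recovery within ±0.2 rad (circular mean over
16 participants at $A = 1.5$), and EOG propagation recovery within
±0.02. These problem sizes — 1000 null replicates, 100 simulations per
amplitude point — were chosen as the smallest giving Monte-Carlo errors
clearly below the bands being checked.

## Known limitations

* The pooled-error ANOVA mode exists to reproduce a published df
  structure; for inference on real data the stratified mode is the
  defensible default.
* Mauchly's p uses the first-order chi-square approximation (documented
  above); at very small n it is less accurate than the higher-order
  expansion.
* The DP signed-rank's $P(H_0)$ depends on an explicit equivalence
  region; there is no canonical value, and conclusions should be checked
  against the reported posterior mean and interval of $\theta$.
* The observer model's independence assumptions (no serial dependence
  beyond fatigue) make simulated power an upper bound on what similarly
  sized real experiments would achieve.

## A worked example

```{r, eval = FALSE}
library(phasedetect)

trials <- simulate_cohort(36, session_plan(), observer_population(),
                          entrain_amp = 0, seed = 1)
res <- run_pipeline(trials, pipeline_config(n_starts = 10))
print(res)

oc <- operating_characteristics(amps = c(0, 0.5), n_sims = 100, seed = 1)
oc
```
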