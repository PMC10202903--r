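---
title: "Methods: analyzing elliptical drawing movements with ellipsekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing elliptical drawing movements with ellipsekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellipsekin)
```

## The problem

When people draw ellipses continuously with a pen, the instantaneous speed
of the pen and the curvature of its path covary lawfully: angular velocity
$V(t)$ and curvature $C(t)$ follow the empirical power law

$$V(t) = K\,C(t)^{1-\beta},$$

with $\beta \approx 1/3$ (the "one-third power law"; equivalently,
tangential velocity proportional to the radius of curvature to the power
$\beta$). `ellipsekin` turns raw pen trajectories — time-stamped $(x, y)$
positions in cm at around 200 samples/s, one recording per subject, hand
(dominant D / non-dominant ND) and speed condition (slow / normal / fast) —
into per-cycle kinematic, geometric and power-law features, and runs the
variability and factorial statistics used to compare hands and speeds:
intra-trial coefficients of variation, cross-hand accuracy and precision
correlations, Steiger tests between dependent correlations, and Aligned
Rank Transform (ART) factorial ANOVA.

The task the pipeline assumes: subjects trace a template ellipse with
semi-major axis $a = 8$ cm and semi-minor axis $b = 2$ cm (eccentricity
$e = \sqrt{1-(b/a)^2} = 0.968$), rotated $+45^\circ$ and traced
counterclockwise with the right hand, $-45^\circ$ and clockwise with the
left, ten ellipses per recording, at three paces around a spontaneous
~1.7 s cycle.

## Pipeline stages

`analyze_recording()` applies a fixed stage order.

**Filtering.** Positions are low-pass filtered with a zero-phase
(forward–backward) Butterworth filter, default cutoff 7 Hz, order 2. A
literal sub-hertz cutoff would obliterate a movement whose fundamental is
near 1 Hz; 7 Hz is the normalized reading 0.07 × Nyquist at 200 Hz, and is
the package default (configurable via `analysis_config()`). The bare
forward–backward pass of `signal::filtfilt` leaves edge transients, so the
signal is extended by odd reflection at both ends (six filter time
constants) and trimmed afterwards; a constant trajectory passes through
unchanged to better than $10^{-9}$.

**Differentiation.** Velocity and acceleration come from central
differences, with second-order one-sided formulas at the two end samples.
The one-sided ends matter: first-order endpoint derivatives leave
curvature outliers that bias the per-cycle log-log fit by several
thousandths.

**Cycle segmentation.** The protocol has subjects draw ten ellipses in
one continuous movement; where one ellipse ends is an analysis decision.
The package
unwraps the centroid angle $\theta(t) = \mathrm{atan2}(y-\bar y, x-\bar x)$
and accumulates $|\Delta\theta|$; a boundary falls at the sample nearest
each crossing of a multiple of $2\pi$. This is direction-agnostic (CW and
CCW segment identically) and robust to eccentricity. The final cycle may
fall short of $2\pi$ by up to 2% of a revolution (`revolution_tolerance`)
to absorb centroid drift and the sub-sample shortfall of the last
boundary; a trailing partial revolution is discarded.

**Exclusion rule.** The first and the two last cycles are dropped
(defaults `exclusion = c(1, 2)`), retaining seven of ten; recordings left
with fewer than `min_cycles_after_exclusion = 2` cycles fail with an
explicit error.

**Per-cycle features.** For each retained cycle:

* *Geometry.* A direct least-squares conic fit constrained to an ellipse
  (partitioned eigen-solution, data centered for conditioning) gives
  center, semi-axes, and orientation reported in $(-90^\circ, 90^\circ]$
  (an ellipse's axis is orientation-unsigned; circles report $0^\circ$ by
  convention). Eccentricity uses $e = \sqrt{1-(b/a)^2}$ on the fitted
  semi-axes. The perimeter is the polyline arc length of the cycle's
  samples closed over the cycle boundary; relative size divides it by the
  template perimeter computed by complete elliptic integral
  (34.3137 cm for 8 × 2 cm).
* *Kinematics.* Duration is the time from the cycle's first sample to the
  start of the next cycle; maximum velocity (vigor) and mean velocity are
  taken over the tangential speed $\sqrt{v_x^2+v_y^2}$.
* *Power law.* Curvature is the standard derivative form
  $C = |v_x a_y - v_y a_x| / v^3$ (an independent three-point Menger
  estimator is used as a test oracle only). Samples with speed below
  `speed_epsilon` or curvature below `curvature_epsilon` (both $10^{-6}$)
  are masked. The fit is ordinary least squares of $\log V$ on $\log C$
  (natural logs; $\beta$ and $r$ are base-invariant, $K$ is defined by the
  natural-log intercept) within each cycle — the per-cycle level of the
  two-level analysis — giving $\beta = 1 - \text{slope}$,
  $K = e^{\text{intercept}}$, and the Pearson correlation of the log-log
  cloud (reported signed). Near-circular cycles whose log-curvature spread
  falls below $10^{-3}$ raise an "uninformative curvature range" error
  rather than returning a meaningless slope.

## The synthetic generator

Human recordings are not required for testing: `generate_cohort()`
produces trajectories with the statistical structure the analysis assumes.

* `generate_harmonic_cycle()` is the exact $\beta = 1/3$ reference:
  harmonic motion along an ellipse satisfies the power law exactly, with
  $K = 2\pi f\,(ab)^{1/3}$.
* `generate_power_law_cycle()` produces any exponent $\beta \in (0,1)$ by
  integrating $dt/d\varphi = |r'(\varphi)|/v(\varphi)$ with
  $v = k R^\beta$ on an 8192-step parameter grid (a step-halving check
  guards the quadrature), scaling $k$ so one revolution takes the
  requested duration, and interpolating the inverse map at the uniform
  sample times. A closed form exists only for $\beta = 1/3$, which the
  generator reproduces to $10^{-4}$ cm.
* `generate_recording()` concatenates jittered cycles, continuous in
  position. Jitter on duration and semi-axes is multiplicative log-normal
  (mean 1, CV = `jitter_cv`) so parameters stay positive; the recordings
  report CVs, and the noise law behind them is not identified, so a
  positive-support law was chosen once. Isotropic Gaussian positional
  noise (`noise_sd`) emulates sensor noise.
* `draw_cohort_parameters()` draws the subject level: log-normal
  normal-pace durations (median 1.67 s, log-SD 0.35, spanning roughly the
  0.9–4 s inter-subject range seen in such tasks), speed multipliers 2.2
  (slow) and 0.63 (fast), a mild log-normal size factor standing in for
  idiosyncratic vigor, and $\beta \sim N(1/3, 0.01)$. Each parameter is
  shared across hands through a latent factor,
  $z_\text{hand} = \sqrt{\rho}\,z_\text{subject} +
  \sqrt{1-\rho}\,\varepsilon_\text{hand}$, with $\rho = 0.9$ by default —
  reproducing the high cross-hand accuracy correlations without modeling
  any neural mechanism. The non-dominant hand's aspect ratio $b/a$ is
  raised by 0.015 (more circular) and it traces clockwise.

Defaults are fixed study conditions, not tuning knobs: 40 subjects × 2
hands × 3 speeds, 10 cycles per recording, 200 Hz, `jitter_cv = 0.03`
(keeping the duration CV under 0.05 at reference pace), `noise_sd = 0.02`
cm.

What the generator does *not* emulate: pen lifts and multi-stroke
corrections, tablet quantization, drift of the drawn ellipse across the
page, within-cycle shape distortion, or any speed dependence of the
generating $\beta$. Passing recovery tests therefore show that the
pipeline measures what the generator injects — not that human data are
this clean.

## Numerical behavior worth knowing

* **$\beta$ recovery.** On noise-free generator output the fit recovers
  $\beta$ to better than 0.001 across the 0.25–0.45 grid at 1 Hz cycles.
  With 0.05 cm positional noise the error stays under 0.02 at 1 s cycles
  with the 7 Hz filter.
* **Slow movements and noise.** The downward bias of $\hat\beta$ grows
  with cycle duration at fixed noise: slower movements put the signal
  closer to the residual noise floor passed by the filter, and the
  noise-inflated curvature at the ellipse's flat segments flattens the
  log-log relation. On default-noise synthetic cohorts, slow-condition
  $\hat\beta$ runs visibly below the generating value while normal and
  fast conditions track it; real tablet recordings share this artifact,
  which is one reason slow-condition power-law estimates should be read
  with care.
* **Filter safety.** Filtering a harmonic cycle at 7 Hz changes
  $\hat\beta$ by under 0.002; the movement passband is essentially
  untouched (< 1% amplitude loss at 1 Hz, zero lag by construction).

## Statistics

`summarize_condition()` reduces each recording to per-parameter mean, SD
and CV (sample SD over retained cycles divided by the mean) — accuracy and
precision of the motor response. `correlation_accuracy()` and
`correlation_precision()` correlate subject-level means and CVs across
hands at each speed (Pearson, two-sided t-based p).

**ART ANOVA.** `art_anova()` implements the Aligned Rank Transform for
the 2 (hand) × 3 (speed) within-subject layout: for each effect the
response is aligned by removing all cell-mean estimates except the effect
of interest, midranked over all observations, and submitted to a
fixed-effects factorial ANOVA with subject as an additive blocking
factor; only the effect of interest is interpreted from each model. The
blocked decomposition gives error df $6n - 6 - (n-1)$ — 195 for 40
subjects — which is the inferential structure the design implies for one
observation per cell. Effect size is partial
$\eta^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$. Balance is
required (equal counts per subject × hand × speed cell): the closed-form
orthogonal sums of squares are then exact and identical to the
linear-model ANOVA, which a test verifies against `aov()`. Under a null
with subject heterogeneity the three effects hold their nominal 5% level
(checked over 2000 simulated cohorts). Tukey HSD post hocs
(`tukey_hsd()`) run on the effect's ranked responses via
`stats::TukeyHSD`.

**Steiger tests.** `steiger_test()` compares two dependent correlations
through Fisher-z transforms, with the covariance term from Dunn & Clark's
expression using the pooled correlation (Steiger's modification). The
package default is the non-overlapping variant — the cohort comparisons
share subjects but no variable (e.g. r(D, ND) at slow vs fast) — with the
six cross-correlations of the quadruple estimated from the data; the
overlapping, shared-variable variant is available. No multiplicity
correction is applied across the twelve parameters by default, matching
the analysis the pipeline reproduces; Holm adjustment can be applied by
the caller via `p.adjust`.

**Two open choices, decided here.** (1) The per-cycle correlation
coefficient is reported signed, not absolute: the sign is informative and
all well-formed cycles give $r$ near $+1$. (2) The cohort reader is
specified for the package's own delimited-text format only; column layouts
of third-party deposits vary and conversion is left to the user.

## Problem sizes in the tests

Tests generate everything they consume. The recovery grids use single 1 s
cycles and 10-cycle recordings; cohort-level tests use 4–8 subjects;
calibration studies use 2000 simulated response tables at 20 subjects
(ANOVA type-I error) and 200 parameter draws at 40 subjects (cross-hand
correlation recovery). These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the suite quick.

## Limitations

* Cycle delimitation and differentiation are analysis decisions of this
  package, not prescribed by the protocol it mirrors; both are flagged
  above and exposed as configuration.
* The supplementary "exact" curvature construction referenced by the
  original analysis is unpublished; the standard derivative estimator is
  used instead and validated against closed forms and a Menger oracle on
  dense samples. Equivalence with the unpublished method cannot be
  verified.
* The ART implementation assumes a balanced design; unbalanced cohorts
  must be completed or subsetted first (the statistics stage drops
  incomplete subjects listwise).
* `relative_size` compares drawn perimeter to the nominal template;
  it conflates shape and scale deviations by design.
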