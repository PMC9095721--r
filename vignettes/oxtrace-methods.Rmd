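---
title: "Methods: regressor-based calcium analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regressor-based calcium analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtrace)
```

## Scope and model

`oxtrace` implements the analysis chain used for pulsed-chemosensory
calcium-imaging experiments in tethered larval zebrafish — oxytocinergic
(OXT) and olfactory-bulb populations probed with conditioned-water cues and
optically gated TRPA1 (UV/optovin) nociceptive stimuli — together with a
synthetic-data generator that plants ground truth so every stage can be
scored against a known answer.  The pipeline starts at extracted ROI
fluorescence traces; registration and segmentation are upstream and out of
scope.

The measurement model for a neuron's fluorescence is

$$F(t) = F_0\,\bigl(1 + \Delta f/f(t)\bigr) + \beta t + \varepsilon(t),$$

with baseline $F_0$, optional linear dye drift $\beta t$, and i.i.d.
Gaussian frame noise $\varepsilon$.  $\Delta f/f$ is computed against the
per-neuron mean over all frames strictly before the first scheduled event
(`compute_dff()`); the paper trail behind each choice is given below.

### Indicator kernel

Neural events map to fluorescence through a delayed single-exponential
GCaMP6s kernel, $h(t) = 0$ for $t < \delta$ and
$h(t) = e^{-(t-\delta)/\tau}$ otherwise, with measured response delay
$\delta = 0.48$ s and decay $\tau = 3$ s, unit peak at the delay.  Only the
delay and decay are specified by the measurements this models; no rise time
is included.  The kernel is a swappable `kernel_params()` object.

### Regressors and tuning

Stimulus regressors are unit boxcars over each cue pulse (100-ms UV pulses
are shorter than any frame and are treated as impulses) convolved with the
kernel, resampled to the frame timebase and renormalized to unit peak.
Motor regressors are kernel-convolved impulse trains at bout onsets, split
into stimulus-associated bouts (onset within 5 s of a UV pulse,
`motor_stim`) and spontaneous bouts, the latter divided at 50° of peak
cumulative tail angle into `motor_spon_S` (≤ 50°) and `motor_spon_L`
(> 50°).  Tuning is scored by zero-lag Pearson correlation between each
smoothed ∆f/f trace and each regressor: the kernel already encodes the
indicator lag, so a lag search would be redundant.  Bouts are weighted as
unit impulses; amplitude weighting is a plausible alternative the source
analyses do not specify.

### Smoothing

Traces are smoothed before correlation with a 3-frame zero-phase filter: a
causal moving average run forward then backward, with reflect padding so
trace ends are not biased toward zero.  Peak positions of symmetric
transients are preserved exactly.

### Response classification

A neuron's response to a cue is the *mean* (not sum) ∆f/f over an epoch
window, averaged across repeats; using the mean keeps the classification
threshold in ∆f/f units across windows of different lengths (the source
text does not state mean vs. sum; this is the package's documented
choice).  The shipped windows are the 60-s post-stimulus window
(`post_cue_60s`), the 5-s post-UV and 30-s pre-UV windows of the TRPA1
paradigm, the 10 s + 30 s split of a 40-s optogenetic window, and the 90-s
behavioral pre-cue baseline.  With
$\Delta = \overline{r}_\text{cue} - \overline{r}_\text{control}$, a neuron
is *enhanced* if $\Delta > 0.05$, *suppressed* if $\Delta < -0.05$, else
*no change*; the boundary $|\Delta| = 0.05$ is deliberately `no_change`
because the rule is a strict "more than".  For UV-referenced windows,
trials are UV pulses grouped by the cue they follow (the schedule
alternates water and cue), which implements the pairing of each TRPA1
trial with its preceding-cue identity.  The same 0.05 threshold is applied
to every window; it is configurable, and `threshold_sweep()` shows that
suppressed/enhanced proportions are stable across a range of thresholds.

### Clustering and broad classes

Neuron × regressor correlation matrices are clustered with seeded,
multi-restart K-means (k = 12 for headline runs, matching the convention of
using one cluster count across datasets).  `select_k()` provides BIC/AIC
diagnostics under a hard-assignment spherical-Gaussian mixture
approximation: shared variance $\hat\sigma^2 = I/(nd)$, empirical mixing
proportions $n_j/n$,

$$\log L = \sum_j n_j \log(n_j/n) - \tfrac{nd}{2}\bigl(\log 2\pi\hat\sigma^2 + 1\bigr),
\qquad p = kd + 1,$$

$\mathrm{BIC} = -2\log L + p\log n$, $\mathrm{AIC} = -2\log L + 2p$.  The
mixing-proportion term is essential: without it the criterion rewards blob
splitting without bound.  Even with it, the criterion can prefer a small
k > 1 on a single homogeneous blob — model-order selection on hard
assignments is a diagnostic, not an inference, which is why `select_k()`
always returns the full table and the headline analyses fix k = 12.

Grouping clusters into broad activity classes (TRPA1-selective i_a–i_c,
stimulus-and-motor ii, motor-only iii, unresponsive iv, anticorrelated v)
was a by-inspection step in the original analyses; the package makes it
explicit and reproducible as an ordered rule list over centroid summaries
(`default_class_rules()`), with bands high ≥ 0.5, moderate 0.2–0.5, weak
0.05–0.2, anticorrelated ≤ −0.2.  The rules are ordered (anticorrelated,
then mixed, then stimulus bands, then motor, then a catch-all) so they are
mutually exclusive and exhaustive, and they ship as data so a user can
edit the subjective step.

### pERK quantification

Per-cell pERK intensities are normalized to the control-group mean, either
pooled over PO and PT or per region; "active cells" are those above the
control (1 − α) quantile with α = 0.10, so 10% of control cells are active
by construction.  The empirical quantile uses R's linear-interpolation
convention (type 7); with continuous intensities the realized control
active count is within one cell of α·n.  Active cells are defined on
normalized intensities (the 10% rule is stated on normalized values).  The
PO/PT split is a user-supplied anterior–posterior cutoff, not inferred.

### Behavior

Bouts are extracted from 200-fps cumulative tail-angle traces by peak
detection on the absolute, lightly smoothed angle (`pracma::findpeaks`)
with defaults prominence 10°, minimum separation 100 ms, rest band 5°, and
a 5-sample smoothing window — the original peak-finding parameters are not
stated, so these are documented package defaults, all configurable.  Peak
cumulative angle is read from the unsmoothed trace inside the bout span so
the 50° large/small boundary is exact (50.0° is small).  Kinematics are
finite-difference velocities; epoch frequencies count bouts in the 90-s
pre-cue, 30-s post-cue and 5-s post-UV windows with precedence
post-UV > post-cue > pre-cue when windows overlap.

### Statistics

Group comparisons delegate to `stats::wilcox.test` (signed-rank for paired
data, rank-sum otherwise, one-sided where a directional hypothesis is
declared) and `stats::kruskal.test`; multi-group follow-ups use
Tukey–Kramer comparison of mean ranks with tie correction, with p-values
from the studentized range distribution.  Exactness guarantees in the test
suite are for the pipeline's own computations, not re-derivations of these
standard routines.

## The synthetic generator

The generator is a forward model of exactly the structure the analyses
assume, so recovery is an honest inverse problem with a shared kernel.

* **Schedules** alternate control water with test cues (10-s pulses; ISI
  5 min for OXT-style runs, 2 min for olfactory-bulb-style runs), with an
  optional 100-ms UV pulse 30 s after every cue onset.
* **Tuning classes** are drawn from a configurable mixture.  Class
  amplitudes are gains times `effect_size`: strong/moderate/weak TRPA1
  gains 1.0/0.35/0.15, mixed stimulus-motor 0.35 (plus motor 0.2),
  motor-only 1.0, anticorrelated −0.5.  The gains were calibrated at design
  time so that, at the preset noise level (0.025 ∆f/f per frame), planted
  classes land near the centers of the correlation rule bands
  (≈ 0.75/0.35/0.15); this is what makes band-based class recovery a
  meaningful test.
* **Modulation labels** (suppressed/enhanced/none, per the cue-period and
  post-UV epochs) are planted as additive ±`effect_size` amplitude changes
  on test-cue trials, independently of tuning class.  Suppression is a
  negative amplitude on the tonic baseline, so ∆f/f can dip below zero.
* **Cue responses** are sustained boxcars of configurable
  `response_duration` convolved with the kernel (default 60 s; 20 s in the
  TRPA1 preset so the cue response decays before the UV pulse and the two
  integration windows report separable effects).  A response lasting only
  the 10-s pulse would dilute a 0.2 ∆f/f effect to ≈ 0.035 over a 60-s
  window — below the 0.05 threshold — so the sustained response is what
  makes threshold classification a solvable inverse problem at the stated
  effect size; slow, epoch-spanning responses are also characteristic of
  GCaMP6s recordings of these populations.
* **Tail bouts** are a Poisson process (default 0.05 Hz) with lognormal
  peak angles straddling 50°, plus large-angle stimulus-locked bouts after
  UV pulses; traces are half-sine envelopes at 200 fps with Gaussian
  tracking noise.
* **pERK tables** are lognormal per group with planted multiplicative
  shifts.
* **Noise** is i.i.d. Gaussian per frame.  The source recordings' noise
  statistics are not published, so `noise_sd` is a free parameter (default
  0.025 ∆f/f, the level used by the benchmark presets), and no temporal
  autocorrelation is modeled beyond the kernel.  All randomness flows from
  one seed through fixed per-stage child streams.

Presets `fig2-kin`, `fig2-nonkin`, `fig2-adult` and `fig6-trpa1` fix the
planted mixtures to the population structures the benchmarks target:
suppressed/enhanced 27.5%/10% (midpoints of the reported 25–30% and 9–11%
ranges), 18%/23%, and 14%/46% for the three conditioned-water presets, and
for the TRPA1 preset 54%/32% post-UV and 43%/30% post-cue modulation with
tuning-class fractions 3.2/25.2/8/31.2/12.8/12.8/6.8% (strong/moderate/weak
TRPA1, mixed, motor, unresponsive, anticorrelated).

### What passing tests do and do not show

The generator matches the analyses' assumptions by construction.  Passing
recovery tests therefore validates the *implementation* — windows, pairing,
thresholds, kernels, clustering — not the biological adequacy of those
assumptions.  Real recordings have correlated noise, slow baseline
wander beyond a single linear drift, desensitization across repeats, and
neurons that do not fall into discrete classes; none of that is emulated.

Two interactions discovered during design are worth knowing:

* *Modulation moves tuning.*  A planted additive modulation changes a
  neuron's mean UV response and hence its stimulus correlation (a
  suppressed, moderately TRPA1-tuned neuron can invert its mean response).
  Tuning-class recovery is therefore validated with modulation mixtures
  disabled; modulation recovery is validated through the classification
  path, which is also what the benchmarks measure.
* *Bout responses are signal, not noise.*  With spontaneous bouts planted,
  motor-tuned neurons carry real bout-driven ∆f/f into integration
  windows, so a handful of modulation calls can flip even at
  `noise_sd = 0`.  The noiseless-recovery check consequently disables the
  bout processes; at the presets' default bout rate the residual effect on
  population fractions is well under one percentage point.

## Numerical choices

* Event-to-frame alignment: nearest frame at or after the onset
  (conservative and causal; frames are 237–711 ms, so sub-frame onsets are
  unavoidable).  Windows are half-open `[start, end)`.
* Baseline: all frames strictly before the first event of any type (the
  convention is specified only as preceding the first stimulus, with no
  stated length).  Overridable.
* Regressor construction uses a 50-ms internal grid anchored at the first
  frame time, making it exactly invariant to shifting all times by a
  constant.
* K-means: `stats::kmeans` (Hartigan–Wong) with 50 seeded restarts rather
  than a hand-rolled Lloyd/k-means++ loop; on tiny instances the fit
  attains the enumeration optimum, and `k = n` is handled as the exact
  zero-inertia solution.  Empty clusters are reported, excluded from
  percentages, and logged.
* Degenerate inputs: constant traces correlate 0 with a degeneracy flag;
  all-tied paired comparisons return a flagged `NA` p-value; a constant
  timebase is an error for background fitting.
* Per-plane timebases are kept; `resample_traces()` provides explicit
  linear interpolation when cross-plane alignment is wanted.

## Problem sizes

The test suite validates oracle equivalence on dozens of small random
instances, recovery on presets of 150–2000 neurons, model-order selection
on 20-seed batches of 150-point mixtures, and bout detection on 20-seed
batches of ~13 spontaneous bouts at signal-to-noise 5.  The benchmark
(acceptance) runs use the presets at their default 1000 neurons
(40 fish × 25), effect size 0.2 ∆f/f and noise 0.025 ∆f/f, for which a
full preset run takes a few seconds.

## Known limitations

* The generator's class library is discrete; graded tuning strengths and
  mixed selectivities beyond the planted classes are not modeled.
* Background drift is strictly linear, matching the documented dye
  artifact but not arbitrary slow drift.
* BIC/AIC model-order selection on hard assignments is approximate (see
  above); it is shipped as a diagnostic.
* The statistics helper exposes only the nonparametric tests the pipeline
  uses; it is not a general testing framework.
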