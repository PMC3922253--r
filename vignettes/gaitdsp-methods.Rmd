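---
title: "gaitdsp: models, measurement chain and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gaitdsp: models, measurement chain and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdsp)
```

## What the package computes

`gaitdsp` implements two linked analyses for studies of diabetic
sensorimotor polyneuropathy (DSP) and gait:

1. **Severity grading.** Three routine clinical measurements — vibratory
   perception (128 Hz tuning fork), tactile sensitivity (10 g
   Semmes–Weinstein monofilament) and an MNSI-style symptom questionnaire,
   each encoded on a 0–10 scale — are combined by a Mamdani fuzzy
   inference system into a continuous *neuropathy degree score* on
   $[0, 10]$, then thresholded into four classes:
   absent ($x \le 2.5$), mild ($2.5 < x < 5$), moderate ($5 \le x < 8$)
   and severe ($x \ge 8$).

2. **Muscle activity during stance.** Surface EMG of vastus lateralis
   (VL), tibialis anterior (TA) and gastrocnemius medialis (GM), recorded
   synchronously with vertical ground reaction force (GRF) at 2 kHz, is
   reduced to nine variables per subject: times to peak activity, peak-to-
   minimum amplitude ratios (VL1/VL2, TA1/TA2, GM1/GM2, TA3/TA2) and two
   activation onsets (TA at push off, GM propulsion burst), all expressed
   in % of the stance phase. Groups are compared variable-by-variable with
   normality-gated parametric or rank tests.

Because no subject-level data ship with the package, a synthetic-cohort
generator produces clinical records and raw gait trials with *known ground
truth*, targeted at published group-level means and SDs, so that the
entire chain is testable end to end.

## The fuzzy classifier

**Universes and sets.** All three inputs and the output live on
$[0, 10]$. Vibration and tactile use three linguistic sets
(`mildly_altered`, `altered`, `very_altered`), symptoms four (`very_mild`
… `severe`). The output has five sets (`absent`, `mild`, `moderate`,
`high`, `severe`) as equal-width triangles centered at 1, 3, 5, 7, 9 with
shouldered ends.

**Why trapezoids with touching plateaus.** Input sets are overlapping
trapezoids whose plateaus touch, so at any crisp input at most one
membership value is in transition. The more common choice — triangles
crossing at membership 0.5 (a strong partition) — provably breaks global
monotonicity of the min–max/centroid chain: with 36 antecedent
combinations and 5 output sets, *any* total rule table maps some pair of
adjacent antecedent sets (along some axis) to the same output set, and at
that pair's 0.5-crossing the aggregated activation of that output dips
($\max(\mu_i, \mu_{i+1})$ has a V there), shifting centroid weight toward
other concurrently active sets. We measured score decreases up to 0.17
units on the evaluation lattice with triangular sets, across six
candidate monotone rule tables. With touching plateaus
$\max(\mu_i, \mu_{i+1}) \equiv 1$ and the dips vanish; the 21×21×21
lattice check passes to machine precision.

**Inference and defuzzification.** Rule strength is the *min* of the
three antecedent degrees; activations of rules sharing an output label
aggregate with *max*; the score is the center of area
$\sum_x x\,\mu(x) / \sum_x \mu(x)$ of the clipped-and-merged output sets
on a grid of $10^{-3}$ of the universe width (results agree with a
10× finer grid within 0.01 score units). An all-zero activation raises an
error rather than returning a default: input coverage makes it
unreachable, so reaching it indicates a broken system file.

**Rule base.** The 36-entry table maps each antecedent combination to the
output whose index is the rounded mean of the rescaled antecedent
severity indices. It ships as an explicit data frame (serializable to
editable JSON via `write_fuzzy_system()`), so domain experts can replace
individual rules; monotonicity should be re-checked after editing.

## The signal-processing chain

Per EMG channel: offset removal (subtract the sample mean, applied
unconditionally — idempotent on zero-mean signals); zero-lag 4th-order
Butterworth band-pass 20–500 Hz; full-wave rectification; zero-lag
4th-order Butterworth low-pass at 5 Hz (the *linear envelope*, with small
negative filter ripple clipped to zero). "Zero-lag" is implemented as
forward–backward application of the designed filter, giving zero net
phase and a squared magnitude response; filter design (analog prototype,
frequency transform with pre-warping, bilinear transform) is implemented
in the package and verified against independently computed reference
coefficients.

Stance is the longest contiguous run of vertical GRF above 20 N (a
conventional force-plate contact threshold, configurable) lasting at
least 0.1 s. The envelope is sliced to stance, divided by its mean over
the stance window (a whole-trial denominator is available as an option),
and linearly resampled to a closed 0–100 % grid of 101 points, so "%
stance" values are integers.

## Feature extraction

Windowed grid searches with earliest-time tie-breaking:

| variable | definition | default window (% stance) |
|---|---|---|
| VL1, vl_time | VL peak (value, time) | [0, 30] |
| TA1, ta_time | TA peak | [0, 20] |
| GM1, gm_time | GM peak | [30, 85] |
| TA3 | TA late-stance peak value | [75, 100] |
| VL2 / TA2 / GM2 | minima | [30, 100] / [20, 70] / [0, 25] |
| ta_onset (TAon) | TA push-off onset | baseline [42, 54], search [55, 100] |
| gm_onset (GMon) | GM propulsion onset | baseline [0, 15], search [15, 60] |

Ratios are plain peak/min (the published group values, e.g. 60.9 or 8.3,
are consistent with ratios, not ratios × 100; a ×100 output is a config
flag away). The TA push-off onset search window extends down to 55 %
stance: published severe-group means near 69 % (and diabetic-without-
neuropathy means near 73 %) cannot be produced by a detector restricted
to the last quarter of stance, so "terminal stance" is read as the
push-off burst region. All windows are configurable.

**Onset detector.** First grid time in the search window where the
envelope exceeds
$\mathrm{mean}(B) + \max\!\big(k\,\mathrm{SD}(B),\; 0.15\,\mathrm{mean}(B)\big)$
for at least 3 consecutive grid points, with $B$ the baseline-window
values and $k = 2$. The 15 % relative floor is a deliberate addition to
the classical mean + k·SD rule: as baseline noise tends to zero the
classical threshold tends to the baseline mean, which the baseline itself
crosses half the time — the floor keeps the criterion meaningful on
nearly noise-free envelopes. Because the grid step is 1 % stance,
reported onsets are quantized; onset recovery is accurate to one grid
step by construction.

Per-trial failures (e.g. no onset crossing) yield `NA` for that variable
and are skipped — with the skip count logged — by the subject-level
aggregation, which is the per-variable arithmetic mean over the (five)
trials.

## The synthetic world

**Clinical records.** For each diabetic subject an input triple is drawn
uniformly over the universes and accepted only if the classifier places
it in the subject's intended class (rejection sampling), so
class-conditional correctness holds by construction. Controls bypass the
classifier and receive low-range scores.

**Raw gait trials.** Per muscle, raw EMG is
$\mathrm{scale}\cdot m(t)\cdot c(t)$: a carrier $c$ — band-limited
Gaussian noise (20–450 Hz, inside the analysis band; the realistic
default) or a deterministic 150 Hz sinusoid (for noiseless convergence
checks) — amplitude-modulated by a profile $m$ of Gaussian activity
bursts on a constant quiet level. VL and TA carry an early burst at the
peak-time truth; TA adds a push-off burst; GM carries a single propulsion
burst at its peak-time truth. Burst widths are fixed in *time* (84 ms
early, 56 ms push-off; the GM width is solved per subject), because
burst durations do not scale with walking speed and because time-fixed
widths keep the measurement conditioning independent of stance duration.
The vertical GRF is a double-hump body-weight curve with steep (0.4 %
stance) contact edges and silent 200 ms swing pads on both sides.

**Calibration against the measurement chain.** The extractor does not see
$m$; it sees the 5 Hz envelope, which attenuates bursts, smears them
symmetrically (zero-phase), rings slightly beside them, and reports
onsets at a threshold that depends on the baseline window's mean and SD.
The generator therefore calibrates, per trial, the quiet level, burst
amplitudes and burst placements against a kernel model of that chain
(the filtered burst shape, cached per width), fixed-point iterating so
that the *expected measured* peak/min ratios equal the ratio truths and
the expected detector crossing falls half a grid step before the onset
truth (centering the quantized report on the truth). The expected
threshold model includes both the deterministic burst spill into the
baseline window and the carrier-ripple CV — a property of the chain
estimated once by filtering a long fixed-seed noise realization
(`envelope_ripple_cv()`, ≈ 0.077 at the default settings).

**Cohort structure.** Subject-level truths are drawn per group: normal
for times and onsets (clamped to the extractor windows with ~2 % margins),
moment-matched lognormal for ratios (the reference SDs approach their
means, so normal draws would put substantial mass below 1), clipped to
the chain's dynamic range $[1.3, 80]$ — quiet levels below roughly 1.5 %
of the burst peak are not resolvable through a 5 Hz envelope, and the
peak/min estimator becomes unstable beyond that. Each trial perturbs the
subject truth with within-subject jitter (SD = 20 % of the between-subject
SD, reflecting that five-trial averaging implies within < between
variability). Stance durations are N(0.70 s, 0.05 s), truncated at 0.4 s.
Everything is reproducible from one integer seed.

**What a green test does and does not establish.** Noiseless (sine
carrier) round trips recover times and onsets within 1 % stance and
ratios within 5 % across the documented feasible region: onset-to-peak
distances ≳ 16 % stance, ratios within the dynamic range, TA push-off
onsets in [62, 80] % for exact recovery (outside it, grid quantization
and the detector's own baseline window cost up to ~1.5 % stance). With
the noise carrier, times and onsets stay unbiased, but the peak/min
*estimator* is inflated by ripple (max-over-window up, min-over-window
down, Jensen's inequality on 1/min): cohort-level ratio means run ~5–15 %
above truth, well inside the 3-SEM recovery bands used for acceptance.
GM onsets are reliable for GM ratios up to roughly 20 in noise mode;
beyond that the burst's ring lobes exceed the detector threshold and
onsets fire early — GM onset is therefore the least trustworthy variable
on high-contrast envelopes, in the synthetic world as in real data. The
generator does not emulate motor-unit physiology, electrode artifacts,
inter-muscle crosstalk, kinematics beyond vertical GRF, or demographic
covariates.

## Group statistics

Each variable is routed by a normality gate: Lilliefors-corrected
Kolmogorov–Smirnov on every group (plain KS with fitted mean/SD is
anticonservative; p-values use the Dallal–Wilkinson/Stephens
approximation). Groups that are too small (n < 5) or degenerate route the
variable to the non-parametric branch. Normal variables get one-way
ANOVA; if the omnibus test rejects at α = 0.05, the Student–Newman–Keuls
stepwise procedure runs on the ordered group means with
studentized-range critical values depending on each comparison's span
(harmonic pairwise SE for unequal n) and the standard blocking rule — a
non-significant subset range blocks all pairs it contains. Non-normal
variables get Kruskal–Wallis with no post hoc. No multiplicity
correction is applied across the nine variables. Under a simulated
five-group null the omnibus rejection rate is within [3.5 %, 6.5 %] of
nominal (1000 replicates, fixed seed, checked in the acceptance suite).

## Numerical choices

- Forward–backward filtering uses odd-symmetric edge extension with pad
  lengths of ~1.5 carrier periods of the lowest frequency involved.
- Defuzzification grid step: $10^{-3}$ of the universe width;
  equal-area ties resolve through the centroid formula itself.
- Peak ties break to the earliest time, making extraction deterministic.
- Kernel cache rounds burst widths to 0.25 ms; calibration evaluates
  baseline statistics on the detector's own 1 % integer grid to avoid
  systematic half-grid onset shifts.
- Seeds: one master seed fans out to fixed per-stage substreams
  (`seed + stage * 1000003 mod 2^31-1`), so one stage's draws never shift
  another's.

## Known limitations

- The fuzzy system's membership breakpoints and rule table are defensible
  defaults, not clinically validated parameters; they are isolated in an
  editable JSON serialization for replacement.
- Ratio features inherit the peak/min estimator's noise-induced inflation;
  comparisons between groups are fair (same estimator everywhere), but
  absolute ratio values should be read with that in mind.
- Onsets are quantized to 1 % stance and depend on the baseline window
  being quiet; envelopes whose activity encroaches on the baseline window
  raise the threshold and can suppress detection (reported as `NA`,
  skipped by aggregation, and logged).
- The statistics module reports full pairwise SNK matrices; it does not
  emulate any particular table's significance-mark notation.
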