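# gaitdsp

Grading diabetic sensorimotor polyneuropathy (DSP) and analysing lower-limb
muscle activity during gait, in one tested R package.

DSP evolves continuously from the onset of diabetes, yet gait studies
usually split patients into hard categories with noisy clinical criteria —
one reason published EMG findings in this population are inconsistent.
`gaitdsp` addresses both halves of that problem:

* a **Mamdani fuzzy inference system** turns three routine clinical scores
  (vibratory perception by 128 Hz tuning fork, tactile sensitivity by 10 g
  monofilament, MNSI-style symptom questionnaire; each encoded on 0–10)
  into a continuous *neuropathy degree score*
  $x \in [0,10]$ via min–max inference and center-of-area defuzzification,
  thresholded into absent ($x \le 2.5$), mild ($2.5 < x < 5$), moderate
  ($5 \le x < 8$) and severe ($x \ge 8$) classes;
* a **surface-EMG pipeline** processes raw EMG + vertical ground reaction
  force recorded at 2 kHz during gait: zero-lag 4th-order Butterworth
  band-pass (20–500 Hz), full-wave rectification, zero-lag 5 Hz low-pass
  (linear envelope), stance-phase segmentation from the force signal,
  amplitude normalization by the envelope mean and time normalization to a
  0–100 % stance grid — then extracts nine variables per subject
  (times to peak of VL/TA/GM; relative magnitudes VL1/VL2, TA1/TA2,
  GM1/GM2, TA3/TA2; onsets TAon, GMon) and compares severity groups with
  normality-gated ANOVA + Student–Newman–Keuls or Kruskal–Wallis tests;
* a **synthetic-cohort generator** produces clinical records and raw gait
  trials with known ground truth, calibrated against the package's own
  measurement chain and targeted at published group-level means ± SDs, so
  the whole analysis is validated end to end without patient data.

## Worked example

Classify two clinical assessments:

```r
library(gaitdsp)
assessments <- data.frame(vibration = c(1.2, 8.5),
                          tactile   = c(0.5, 9.0),
                          symptoms  = c(2.0, 7.5))
classify_assessments(assessments)
#>   vibration tactile symptoms    score severity
#> 1       1.2     0.5      2.0 1.080623   absent
#> 2       8.5     9.0      7.5 8.919377   severe
```

The first subject's mild findings activate only the lowest output sets,
whose clipped centroid sits at 1.08 — below the 2.5 cut-off, so "absent".
The second subject's uniformly severe inputs defuzzify to 8.92, past the
8.0 cut-off.

Generate a small severe-neuropathy cohort, run the full raw-signal
pipeline and recover its feature targets:

```r
spec <- cohort_spec(groups = data.frame(label = "severe", n = 28), seed = 302)
cohort <- generate_cohort_trials(spec)          # 28 subjects x 5 raw trials
feats  <- extract_cohort_features(cohort)       # filter, envelope, 9 features
round(colMeans(feats[, c("ta_onset", "gm_time", "gm_mag")]), 2)
#> ta_onset  gm_time   gm_mag
#>    67.75    64.83    17.88
```

The generator was targeted at a severe-group TA push-off onset of
68.8 ± 4.9 % stance, GM time-to-peak 64.0 ± 5.6 % and GM1/GM2 16.0 ± 13.4;
the pipeline's cohort means land within the 3-SEM recovery bands
(± 2.8, ± 3.2 and ± 7.6 respectively).

One-command pipeline (clinical generation → classification → gait
synthesis → envelopes → features → group statistics):

```r
res <- run_pipeline(default_run_config(out_dir = "demo_run", seed = 3))
res$summary$table[1, c("control", "severe", "test", "p")]
#>      control     severe  test            p
#> 1  9.1 ± 3.3 14.1 ± 3.6 anova 2.199755e-09
```

(first row = VL time to peak: the severe group's delayed VL peak is
flagged by ANOVA with SNK pairs listed in `significant_pairs`.)

A command-line front end with subcommands `run`, `synth-cohort`,
`dsp-classify`, `emg-features` and `group-compare` is installed at
`system.file("cli/gaitdsp.R", package = "gaitdsp")`.

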