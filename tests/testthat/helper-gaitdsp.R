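# Shared fixtures for the gaitdsp test suite. Everything is generated in
# code; cohorts used by several acceptance tests are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A mid-range ground truth, overridable per test.
make_truth <- function(...) {
  tr <- list(vl_time = 10, vl_mag = 8, ta_time = 4, ta_mag = 20,
             ta_onset = 80, ta_mag_pushoff = 6, gm_time = 60, gm_mag = 8,
             gm_onset = 40, stance_duration = 0.7)
  utils::modifyList(tr, list(...))
}

# Random feasible truth for round-trip checks: times span the extractor
# windows; onset-to-peak distances and ratios stay inside the region the
# 5 Hz measurement chain can realize (see the methods vignette).
random_truth <- function() {
  gm_time <- runif(1, 40, 78)
  gm_onset <- min(max(gm_time - runif(1, 16, 26), 17), 52)
  make_truth(
    vl_time = runif(1, 3, 27), vl_mag = runif(1, 2, 15),
    ta_time = runif(1, 1, 12), ta_mag = runif(1, 3, 50),
    ta_onset = runif(1, 62, 80), ta_mag_pushoff = runif(1, 2.5, 9),
    gm_time = gm_time, gm_mag = runif(1, 3, 8),
    gm_onset = gm_onset,
    stance_duration = runif(1, 0.62, 0.78))
}

sine_spec <- function(seed = 1) cohort_spec(carrier = "sine", seed = seed)

# Group-targeted noise-mode cohort + extracted features, cached.
recovery_cohort <- function(group, n, seed) {
  cached(paste0("rec_", group, "_", n, "_", seed), {
    spec <- cohort_spec(groups = data.frame(label = group, n = n),
                        seed = seed)
    coh <- generate_cohort_trials(spec)
    list(cohort = coh, features = extract_cohort_features(coh))
  })
}

target_of <- function(group, feature) {
  tg <- default_feature_targets()
  row <- tg[tg$group == group, ]
  c(mean = row[[paste0(feature, "_mean")]],
    sd = row[[paste0(feature, "_sd")]], n = row$n)
}

three_sem <- function(group, feature) {
  t <- target_of(group, feature)
  3 * t[["sd"]] / sqrt(t[["n"]])
}
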