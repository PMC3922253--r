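# Feature extraction: peaks, minima, ratios, onsets, aggregation.

mk_env <- function(values, muscle = "x") {
  structure(list(muscle = muscle, percent = 0:100, values = values),
            class = "stance_envelope")
}

test_that("find_peak and find_min honor windows and tie rules", {
  bump <- mk_env(exp(-((0:100) - 10)^2 / 8))
  expect_equal(find_peak(bump, c(0, 30))$time, 10)
  flat <- mk_env(rep(1, 101))
  expect_equal(find_peak(flat, c(5, 60))$time, 5)   # earliest-time tie rule
  expect_equal(find_min(flat, c(20, 70)), 1)
  vee <- mk_env(abs((0:100) - 40) / 40 + 0.2)
  expect_equal(find_min(vee, c(20, 70)), 0.2)
  expect_error(find_peak(bump, c(30, 10)), "window")
  # min of a mean-normalized envelope cannot exceed its mean
  expect_lte(find_min(bump, c(0, 100)), mean(bump$values))
})

test_that("relative_magnitude is the plain peak/min ratio with guards", {
  expect_equal(relative_magnitude(2, 1), 2)
  expect_equal(relative_magnitude(1.5, 1.5), 1)
  expect_error(relative_magnitude(2, 0), "degenerate")
})

test_that("detect_onset finds sustained threshold crossings", {
  env <- mk_env(c(rep(0.2, 80), rep(2, 21)))
  expect_equal(detect_onset(env, c(50, 74), c(75, 100), k = 2), 80)
  quiet <- mk_env(c(rep(0.2, 101)))
  expect_error(detect_onset(quiet, c(50, 74), c(75, 100)), "no onset")
  expect_error(detect_onset(env, c(40, 80), c(75, 100)), "disjoint")
  # min_run: a 2-point blip does not count
  blip <- mk_env(c(rep(0.2, 85), 2, 2, rep(0.2, 7), rep(2, 7)))
  expect_equal(detect_onset(blip, c(50, 74), c(75, 100), min_run = 3), 94)
})

test_that("extract_features composes the nine variables with NA on failure", {
  flat <- list(vl = mk_env(rep(1, 101), "vl"), ta = mk_env(rep(1, 101), "ta"),
               gm = mk_env(rep(1, 101), "gm"))
  f <- extract_features(flat)
  expect_equal(unname(f[c("vl_mag", "ta_mag", "gm_mag")]), rep(1, 3))
  expect_true(is.na(f[["ta_onset"]]) && is.na(f[["gm_onset"]]))
  errs <- attr(f, "errors")
  expect_true(any(grepl("^ta_onset", errs)) && any(grepl("^gm_onset", errs)))
})

test_that("feature extraction is scale- and duration-invariant", {
  spec <- sine_spec()
  tt <- make_truth()
  set.seed(6); tr <- generate_gait_trial(tt, spec)
  f1 <- extract_features(process_trial(tr))
  tr2 <- tr
  for (m in names(tr2$emg)) tr2$emg[[m]] <- tr2$emg[[m]] * 37.5
  f2 <- extract_features(process_trial(tr2))
  expect_equal(f1, f2, tolerance = 1e-6)

  # same truth at a different stance duration: time features unchanged
  tt_slow <- make_truth(stance_duration = 0.85)
  set.seed(6); tr3 <- generate_gait_trial(tt_slow, spec)
  f3 <- extract_features(process_trial(tr3))
  times <- c("vl_time", "ta_time", "gm_time", "ta_onset", "gm_onset")
  expect_equal(unname(f1[times]), unname(f3[times]), tolerance = 1)
})

test_that("aggregate_subject averages per variable and skips failures", {
  a <- c(vl_time = 8, vl_mag = 4)
  b <- c(vl_time = 12, vl_mag = NA)
  agg <- aggregate_subject(list(a, b))
  expect_equal(unname(agg["vl_time"]), 10)
  expect_equal(unname(agg["vl_mag"]), 4)
  expect_equal(unname(attr(agg, "n_skipped")["vl_mag"]), 1)
  expect_equal(aggregate_subject(list(a, a)), a, ignore_attr = TRUE)
  expect_error(aggregate_subject(list(c(x = NA_real_), c(x = NA_real_))),
               "missing in all trials")
})
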