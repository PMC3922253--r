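# Gait-trial generator: determinism, signal statistics, truth realization.

test_that("identical truth and RNG state give bit-identical trials", {
  spec <- cohort_spec(seed = 1)
  tt <- make_truth()
  set.seed(99); t1 <- generate_gait_trial(tt, spec)
  set.seed(99); t2 <- generate_gait_trial(tt, spec)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$grf_z, t2$grf_z)
})

test_that("cohorts are reproducible from the spec seed", {
  spec <- cohort_spec(groups = data.frame(label = "mild", n = 2),
                      trials_per_subject = 2, seed = 13)
  c1 <- generate_cohort_trials(spec)
  c2 <- generate_cohort_trials(spec)
  expect_identical(c1[[1]]$trials[[2]]$emg, c2[[1]]$trials[[2]]$emg)
  expect_identical(c1[[2]]$truth, c2[[2]]$truth)
})

test_that("raw EMG is near-zero-mean and GRF swing is silent", {
  spec <- cohort_spec(seed = 3)
  set.seed(3)
  tr <- generate_gait_trial(make_truth(), spec)
  for (m in c("vl", "ta", "gm")) {
    x <- tr$emg[[m]]
    expect_lt(abs(mean(x)), 0.01 * sqrt(mean(x^2)))
  }
  expect_true(all(tr$grf_z[1:(tr$stance_samples[1] - 1)] < 20))
  expect_true(all(tr$grf_z[(tr$stance_samples[2] + 1):length(tr$grf_z)] < 20))
  expect_gt(max(tr$grf_z), 500)
})

test_that("degenerate draws behave: SD 0 reproduces the group mean", {
  tg <- default_feature_targets()
  tg[tg$group == "control", grep("_sd$", names(tg))] <- 0
  spec <- cohort_spec(groups = data.frame(label = "control", n = 1),
                      feature_targets = tg, stance_duration_sd = 0,
                      trials_per_subject = 1, within_subject_frac = 0,
                      seed = 5)
  coh <- generate_cohort_trials(spec)
  expect_equal(coh[[1]]$truth$vl_time,
               tg$vl_time_mean[tg$group == "control"])
  expect_equal(coh[[1]]$truth$gm_mag,
               tg$gm_mag_mean[tg$group == "control"])
})

test_that("subject truths track the group targets (control VL)", {
  rc <- recovery_cohort("control", 30, seed = 301)
  truths <- vapply(rc$cohort, function(s) s$truth$vl_time, numeric(1))
  expect_lt(abs(mean(truths) - 9.7), 3 * 3.2 / sqrt(30))
})

test_that("a trial with sub-threshold GRF propagates a stance error", {
  spec <- cohort_spec(seed = 4)
  set.seed(4)
  tr <- generate_gait_trial(make_truth(), spec)
  tr$grf_z <- tr$grf_z * 0   # force never crosses the contact threshold
  expect_error(process_trial(tr), "no stance")
})

test_that("trial files and cohort manifests round-trip through disk", {
  spec <- cohort_spec(groups = data.frame(label = "severe", n = 1),
                      trials_per_subject = 2, seed = 8)
  coh <- generate_cohort_trials(spec)
  dir <- tempfile()
  mf <- write_cohort(coh, dir)
  man <- read.delim(mf)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(dir, man$path))))

  tr0 <- coh[[1]]$trials[[1]]
  tr1 <- read_gait_trial(file.path(dir, man$path[1]))
  expect_equal(tr1$rate, tr0$rate, tolerance = 1e-6)
  expect_equal(tr1$emg$ta, tr0$emg$ta, tolerance = 1e-6)
  # identical features from the re-read trial
  f0 <- extract_features(process_trial(tr0))
  f1 <- extract_features(process_trial(tr1))
  expect_equal(f0, f1, tolerance = 1e-4)
})

test_that("noiseless trials recover the generator truth (round trip)", {
  spec <- sine_spec()
  set.seed(20)
  n_bad_time <- 0; n_bad_ratio <- 0
  for (i in 1:40) {
    tt <- random_truth()
    tr <- generate_gait_trial(tt, spec)
    f <- extract_features(process_trial(tr))
    tv <- unlist(tt[feature_names()])
    times <- c("vl_time", "ta_time", "gm_time", "ta_onset", "gm_onset")
    ratios <- c("vl_mag", "ta_mag", "ta_mag_pushoff", "gm_mag")
    expect_lt(max(abs(f[times] - tv[times])), 1.0001)
    expect_lt(max(abs(f[ratios] / tv[ratios] - 1)), 0.05)
  }
})
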