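# Synthetic raw gait trials with known ground truth.
#
# Raw EMG per muscle is a carrier (band-limited Gaussian noise, 20-450 Hz,
# or a deterministic 150 Hz sinusoid) amplitude-modulated by an envelope
# profile of Gaussian activity bursts on a constant quiet-period baseline;
# the vertical ground reaction force is a double-hump stance curve padded
# with zero-force swing segments. Because the downstream measurement chain
# (5 Hz zero-lag envelope smoothing, windowed peak/min search, threshold
# onset detection) attenuates bursts, rings slightly beside them, and
# fires the onset detector at a baseline-dependent level, burst amplitudes,
# quiet-level depth and burst placement are calibrated per trial against a
# kernel model of that chain, so that the features the pipeline extracts
# from a generated trial match the requested ground truth.

# Moment-matched lognormal sampler: positive, right-skewed draws with the
# requested mean and SD -- appropriate for peak/min ratio targets whose
# reference SDs approach their means (a normal draw would put substantial
# mass below 1).
rlnorm_mom <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Runs `expr` under an isolated, fixed RNG stream, restoring the caller's
# RNG state afterwards.
with_isolated_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.gaitdsp_cache <- new.env(parent = emptyenv())

#' Relative ripple of the rectified-and-smoothed noise carrier
#'
#' The linear envelope of a band-limited Gaussian carrier retains a
#' multiplicative ripple after full-wave rectification and 5 Hz zero-lag
#' low-pass filtering. Its coefficient of variation is a property of the
#' measurement chain (carrier band, low-pass cutoff, sampling rate) and is
#' what the onset detector's baseline SD measures on a synthetic trial.
#' The generator uses `k * this CV` as the expected relative threshold
#' excursion when realizing onset ground truth. Estimated once per
#' parameter set by filtering a long fixed-seed noise realization
#' (deterministic), then cached.
#'
#' @param rate sampling rate (Hz).
#' @param band carrier band (Hz).
#' @param cutoff envelope low-pass cutoff (Hz).
#' @param seconds length of the probe realization.
#' @return the coefficient of variation (SD/mean) of the envelope.
#' @export
envelope_ripple_cv <- function(rate = 2000, band = c(20, 450), cutoff = 5,
                               seconds = 60) {
  key <- paste0("cv_", rate, "_", band[1], "_", band[2], "_", cutoff)
  if (!is.null(.gaitdsp_cache[[key]])) return(.gaitdsp_cache[[key]])
  cv <- with_isolated_rng(902131L, {
    w <- stats::rnorm(round(rate * seconds))
    carrier <- bandpass_zero_lag(w, rate, low = band[1], high = band[2])
    env <- lowpass_envelope(rectify(carrier), rate, cutoff = cutoff)
    core <- env[round(rate):(length(env) - round(rate))]  # drop edges
    stats::sd(core) / mean(core)
  })
  .gaitdsp_cache[[key]] <- cv
  cv
}

# Impulse-like response of the envelope low-pass to a unit Gaussian burst
# of width sigma_s seconds, as a function of time offset from the burst
# center. Unclipped (retains the filter's small negative ring lobes, which
# the calibration must model). Cached per (sigma rounded to 1 ms, rate,
# cutoff).
smoothed_burst_t <- function(sigma_s, rate, cutoff = 5, span_s = 2.4) {
  key <- sprintf("k_%d_%g_%g", round(sigma_s * 4000), rate, cutoff)
  if (!is.null(.gaitdsp_cache[[key]])) return(.gaitdsp_cache[[key]])
  sig <- round(sigma_s * 4000) / 4000
  half <- round(span_s / 2 * rate)
  tt <- (seq_len(2 * half + 1) - half - 1) / rate
  ba <- butter_design(4, cutoff, rate, type = "low")
  g <- filtfilt_ba(ba$b, ba$a, exp(-tt^2 / (2 * sig^2)),
                   padlen = min(2 * half, round(1.5 * rate / cutoff)))
  out <- list(fun = stats::approxfun(tt, g, yleft = 0, yright = 0),
              max = max(g))
  .gaitdsp_cache[[key]] <- out
  out
}

# Kernel in % stance units for a burst of width sigma_pct at a given stance
# duration.
kern_pct <- function(sigma_pct, stance_dur, rate, cutoff = 5) {
  kt <- smoothed_burst_t(sigma_pct * stance_dur / 100, rate, cutoff)
  list(fun = function(d) kt$fun(d * stance_dur / 100), max = kt$max)
}

# --- per-muscle calibration against the kernel model ----------------------
# The predicted noiseless envelope is E(x) = b + sum_i A_i K_i(x - c_i)
# (x in % stance); peaks, windowed minima and threshold crossings are
# computed on a fine grid and the free parameters (quiet level b, burst
# amplitude, burst placement/width) are fixed-point iterated so that the
# measured ratios and onset equal the ground truth.

fine_grid <- seq(0, 100, by = 0.25)

win_min <- function(e, w) min(e[fine_grid >= w[1] & fine_grid <= w[2]])
win_max <- function(e, w) max(e[fine_grid >= w[1] & fine_grid <= w[2]])

# Single-burst muscle (VL): choose quiet level b so peak/min equals r.
calibrate_single <- function(r, c0, kern, peak_w, min_w, floor_min = 5e-3) {
  b <- kern$max / (r - 1)
  for (it in 1:4) {
    e <- kern$fun(fine_grid - c0)
    p <- win_max(e, peak_w)   # burst contribution at the measured peak
    m <- win_min(e, min_w)    # burst contribution at the measured minimum
    b <- (p - r * m) / (r - 1)
    if (b + m < floor_min) b <- floor_min - m
  }
  b
}

# TA: early burst (A1 = 1, center c1, width s1) + push-off burst (A2, c2,
# width s2); solves quiet level b, A2 and c2 for targets r1 = TA1/TA2,
# r3 = TA3/TA2 and expected detector crossing at t_on. The crossing is
# aimed at t_on - 0.5 so that the detector's 1 %-grid first-point-above
# report is an unbiased estimate of t_on.
calibrate_ta <- function(r1, r3, t_on, c1, s1, s2, stance_dur, rate, cutoff,
                         cv, windows, c2_max, floor_min = 5e-3) {
  k1 <- kern_pct(s1, stance_dur, rate, cutoff)
  k2 <- kern_pct(s2, stance_dur, rate, cutoff)
  kmin <- max(windows$onset_k * cv, windows$onset_floor_rel)
  if (r3 - 1 <= kmin * 2) r3 <- 1 + kmin * 2   # keep the burst detectable
  b <- k1$max / (r1 - 1)
  A2 <- (r3 - 1) * b / k2$max
  c2 <- min(t_on + 12, c2_max)
  e1 <- k1$fun(fine_grid - c1)
  # baseline statistics on the detector's own 1 % integer grid
  gb <- seq(ceiling(windows$ta_onset_baseline[1]),
            floor(windows$ta_onset_baseline[2]))
  e1b <- k1$fun(gb - c1)
  target <- t_on - 0.5
  cand <- seq(target + 0.5, max(c2_max, target + 1), by = 0.25)
  K2ib <- vapply(cand, function(cc) k2$fun(gb - cc), numeric(length(gb)))
  for (it in 1:6) {
    e <- e1 + A2 * k2$fun(fine_grid - c2)
    m <- win_min(e, windows$ta_min)
    p1 <- win_max(e, windows$ta_peak)
    b <- (p1 - r1 * m) / (r1 - 1)
    if (b + m < floor_min) b <- floor_min - m
    # push-off burst amplitude for TA3 = r3 * min
    i3 <- fine_grid >= windows$ta_pushoff_peak[1] &
      fine_grid <= windows$ta_pushoff_peak[2]
    k2v <- k2$fun(fine_grid - c2)
    j <- which(i3)[which.max(k2v[i3])]
    A2 <- max((r3 * (b + m) - b - e1[j]) / k2v[j], kmin * b / k2$max)
    # place the push-off burst so the expected detector threshold (baseline
    # mean + max(k SD, floor) with both carrier ripple and deterministic
    # burst spill in the SD) is crossed at the target; scan candidate
    # centers (robust to the kernel's ring lobes)
    B <- b + e1b + A2 * K2ib             # baseline-window model, per cand
    thr <- expected_threshold(B, cv, windows)
    lvl <- b + k1$fun(target - c1) + A2 * k2$fun(target - cand)
    rv <- lvl - thr
    c2 <- if (rv[1] <= 0) cand[1]
      else if (all(rv > 0)) cand[length(cand)]
      else {
        i <- which(rv <= 0)[1]
        cand[i - 1] + 0.25 * rv[i - 1] / (rv[i - 1] - rv[i])
      }
  }
  list(b = b, A2 = A2, c2 = c2)
}

# Expected onset-detector threshold for a model baseline-window envelope.
# `B` is a vector (or matrix, one column per candidate) of noiseless model
# values; the carrier ripple contributes cv * local mean to the SD.
expected_threshold <- function(B, cv, windows) {
  if (is.matrix(B)) {
    mu <- colMeans(B)
    spill_var <- apply(B, 2, stats::var)
    msq <- colMeans(B^2)
  } else {
    mu <- mean(B)
    spill_var <- stats::var(B)
    msq <- mean(B^2)
  }
  sd_tot <- sqrt(spill_var + cv^2 * msq)
  mu + pmax(windows$onset_k * sd_tot, windows$onset_floor_rel * mu)
}

# GM: single propulsion burst centered at the peak-time truth; solves quiet
# level b, burst width sigma (so the expected detector crossing falls at
# t_on - 0.5, centering the detector's 1 %-grid report on t_on) and keeps
# peak/min = r.
calibrate_gm <- function(r, t_peak, t_on, stance_dur, rate, cutoff, cv,
                         windows, sigma_range = c(3, 16), floor_min = 5e-3) {
  kmin <- max(windows$onset_k * cv, windows$onset_floor_rel)
  if (r - 1 <= kmin * 2) r <- 1 + kmin * 2
  d <- max(t_peak - t_on + 0.5, 2)   # distance from center to the crossing
  bw <- windows$gm_onset_baseline
  gb <- seq(ceiling(bw[1]), floor(bw[2]))   # detector's integer grid
  sig_cand <- seq(sigma_range[1], sigma_range[2], by = 0.25)
  sigma <- 8; b <- NULL
  for (it in 1:4) {
    k <- kern_pct(sigma, stance_dur, rate, cutoff)
    e <- k$fun(fine_grid - t_peak)
    p <- win_max(e, windows$gm_peak)
    m <- win_min(e, windows$gm_min)
    b <- (p - r * m) / (r - 1)
    if (b + m < floor_min) b <- floor_min - m
    # resid(sigma): expected envelope at the crossing target minus the
    # expected threshold; increasing in sigma on the burst's main flank
    rv <- vapply(sig_cand, function(s) {
      ks <- kern_pct(s, stance_dur, rate, cutoff)
      B <- b + ks$fun(gb - t_peak)
      b + ks$fun(-d) - expected_threshold(B, cv, windows)
    }, numeric(1))
    sigma <- if (all(rv >= 0)) sig_cand[1]
      else if (all(rv < 0)) sig_cand[length(sig_cand)]
      else {
        # last sign change from below: widest flank that still crosses late
        i <- max(which(rv < 0))
        if (i == length(sig_cand)) sig_cand[i]
        else sig_cand[i] + 0.25 * (-rv[i]) / (rv[i + 1] - rv[i])
      }
  }
  list(b = b, sigma = sigma)
}

#' Generate one raw synthetic gait trial
#'
#' Builds raw EMG for the three muscles (VL, TA, GM) and a vertical ground
#' reaction force channel realizing the requested ground truth. Consumes
#' the current RNG stream (seed it for reproducibility).
#'
#' @param truth named list of ground-truth feature values (see
#'   [feature_names()]) plus optionally `stance_duration` (s).
#' @param spec a [cohort_spec()] (rate, swing padding, carrier model).
#' @param lp_cutoff envelope low-pass cutoff the downstream pipeline will
#'   use (calibration target).
#' @param windows feature-extraction windows the downstream pipeline will
#'   use.
#' @return object of class `gait_trial`: list with `rate`, `time`, `emg`
#'   (named list `vl`, `ta`, `gm`), `grf_z`, `stance_samples` (true
#'   stance-sample range), and `truth` (the realized ground truth).
#' @export
generate_gait_trial <- function(truth, spec, lp_cutoff = 5,
                                windows = default_feature_windows()) {
  rate <- spec$rate
  stance_dur <- truth$stance_duration %||% spec$stance_duration_mean
  n_stance <- round(stance_dur * rate) + 1
  n_pad <- round(spec$swing_pad * rate)
  n <- n_stance + 2 * n_pad
  i_stance <- c(n_pad + 1, n_pad + n_stance)
  # % stance coordinate for every sample (swing maps to < 0 and > 100)
  pct <- (seq_len(n) - i_stance[1]) / (n_stance - 1) * 100

  cv <- if (spec$carrier == "noise") {
    envelope_ripple_cv(rate, cutoff = lp_cutoff)
  } else 0
  # burst widths are fixed in time (84 / 56 ms, i.e. 12 / 8 % stance at the
  # 0.7 s reference duration): activity bursts last about as long regardless
  # of walking speed, and this keeps the measurement chain's conditioning
  # independent of the stance duration
  s_early <- 12 * 0.7 / stance_dur
  s_late <- 8 * 0.7 / stance_dur

  bump <- function(c0, sigma) exp(-(pct - c0)^2 / (2 * sigma^2))

  k8 <- kern_pct(s_early, stance_dur, rate, lp_cutoff)
  b_vl <- calibrate_single(truth$vl_mag, truth$vl_time, k8,
                           windows$vl_peak, windows$vl_min)
  m_vl <- b_vl + bump(truth$vl_time, s_early)

  swing_pct <- spec$swing_pad / stance_dur * 100
  ta <- calibrate_ta(truth$ta_mag, truth$ta_mag_pushoff, truth$ta_onset,
                     truth$ta_time, s_early, s_late, stance_dur, rate,
                     lp_cutoff, cv, windows,
                     c2_max = 100 + swing_pct - 2.5 * s_late)
  m_ta <- ta$b + bump(truth$ta_time, s_early) + ta$A2 * bump(ta$c2, s_late)

  gm <- calibrate_gm(truth$gm_mag, truth$gm_time, truth$gm_onset,
                     stance_dur, rate, lp_cutoff, cv, windows)
  m_gm <- gm$b + bump(truth$gm_time, gm$sigma)

  make_carrier <- function() {
    if (spec$carrier == "noise") {
      w <- stats::rnorm(n)
      ca <- bandpass_zero_lag(w, rate, low = 20, high = 450)
      ca / stats::sd(ca)
    } else {
      tt <- (seq_len(n) - 1) / rate
      sqrt(2) * sin(2 * pi * 150 * tt)
    }
  }
  scale <- 0.05  # arbitrary units; all magnitudes self-normalize downstream
  emg <- list(vl = scale * m_vl * make_carrier(),
              ta = scale * m_ta * make_carrier(),
              gm = scale * m_gm * make_carrier())

  # Vertical GRF: double-hump stance curve (body weight 735 N), steep
  # 1%-stance contact edges, zero force in swing.
  shape <- 0.15 + 0.95 * exp(-((pct - 25) / 12)^2) +
    0.95 * exp(-((pct - 78) / 12)^2) + 0.30 * exp(-((pct - 50) / 25)^2)
  edge <- clamp(pmin(pct, 100 - pct) / 0.4, 0, 1)
  grf <- 735 * shape * edge
  grf[pct < 0 | pct > 100] <- 0

  realized <- truth
  realized$ta_late_center <- ta$c2
  realized$gm_sigma <- gm$sigma
  structure(list(rate = rate, time = (seq_len(n) - 1) / rate, emg = emg,
                 grf_z = grf, stance_samples = i_stance, truth = realized),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("gait trial: %d samples @ %g Hz, stance samples %d-%d\n",
              length(x$grf_z), x$rate, x$stance_samples[1],
              x$stance_samples[2]))
  invisible(x)
}

# Truth feasibility boxes: keep drawn truths strictly inside the windows
# the extractor searches (margins of ~2 % stance / a floor of 1.3 on
# ratios); mass outside is negligible for the reference targets.
truth_box <- function(windows) {
  list(vl_time = windows$vl_peak + c(2, -2),
       ta_time = c(max(windows$ta_peak[1], 0.8), windows$ta_peak[2] - 2),
       gm_time = windows$gm_peak + c(2, -2),
       ta_onset = windows$ta_onset_search + c(2, -4),
       gm_onset = windows$gm_onset_search + c(2, -5),
       ratio_floor = 1.3, ratio_cap = 80)
}

#' Generate a full synthetic cohort of gait trials
#'
#' Subject-level true feature values are drawn from the per-group targets
#' (normal for times and onsets, moment-matched lognormal for ratios),
#' then each of the subject's trials receives small within-subject jitter
#' (SD = `within_subject_frac` of the between-subject SD) before the raw
#' signals are synthesized. Reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param windows feature windows the downstream pipeline will use.
#' @param lp_cutoff envelope low-pass cutoff of the downstream pipeline.
#' @return list of subjects: each a list with `subject`, `group`, `truth`
#'   (subject-level ground truth) and `trials` (list of `gait_trial`).
#' @export
generate_cohort_trials <- function(spec, windows = default_feature_windows(),
                                   lp_cutoff = 5) {
  set.seed(spec$seed)
  box <- truth_box(windows)
  tg <- spec$feature_targets
  out <- list()
  sid <- 0L
  for (gi in seq_len(nrow(spec$groups))) {
    glab <- spec$groups$label[gi]
    row <- tg[tg$group == glab, ]
    for (si in seq_len(spec$groups$n[gi])) {
      sid <- sid + 1L
      subj_truth <- draw_truth(row, box, jitter_of = NULL, spec)
      trials <- lapply(seq_len(spec$trials_per_subject), function(k) {
        tr_truth <- draw_truth(row, box, jitter_of = subj_truth, spec)
        generate_gait_trial(tr_truth, spec, lp_cutoff = lp_cutoff,
                            windows = windows)
      })
      out[[sid]] <- list(subject = sprintf("S%03d", sid), group = glab,
                         truth = subj_truth, trials = trials)
    }
  }
  out
}

# Draw one truth set. With jitter_of = NULL draws subject-level truth from
# the group targets; otherwise perturbs the given subject truth with
# within-subject jitter.
draw_truth <- function(row, box, jitter_of, spec) {
  g <- function(feat) c(row[[paste0(feat, "_mean")]], row[[paste0(feat, "_sd")]])
  draw_time <- function(feat, lim) {
    p <- g(feat)
    if (is.null(jitter_of)) clamp(stats::rnorm(1, p[1], p[2]), lim[1], lim[2])
    else clamp(jitter_of[[feat]] +
                 stats::rnorm(1, 0, spec$within_subject_frac * p[2]),
               lim[1], lim[2])
  }
  draw_ratio <- function(feat) {
    p <- g(feat)
    # floor keeps ratios meaningfully > 1; cap is the measurement chain's
    # dynamic range (quiet levels below ~1% of the burst peak are not
    # resolvable through the 5 Hz envelope, see the methods vignette)
    x <- if (is.null(jitter_of)) rlnorm_mom(1, p[1], p[2])
      else jitter_of[[feat]] +
        stats::rnorm(1, 0, spec$within_subject_frac * p[2])
    clamp(x, box$ratio_floor, box$ratio_cap)
  }
  tr <- list(
    vl_time = draw_time("vl_time", box$vl_time),
    vl_mag = draw_ratio("vl_mag"),
    ta_time = draw_time("ta_time", box$ta_time),
    ta_mag = draw_ratio("ta_mag"),
    ta_onset = draw_time("ta_onset", box$ta_onset),
    ta_mag_pushoff = draw_ratio("ta_mag_pushoff"),
    gm_time = draw_time("gm_time", box$gm_time),
    gm_mag = draw_ratio("gm_mag"),
    gm_onset = draw_time("gm_onset", box$gm_onset))
  # GM onset must precede the GM peak by a usable margin
  tr$gm_onset <- min(tr$gm_onset, tr$gm_time - 8)
  tr$stance_duration <- if (is.null(jitter_of)) {
    max(stats::rnorm(1, spec$stance_duration_mean, spec$stance_duration_sd),
        0.4)
  } else {
    max(jitter_of$stance_duration +
          stats::rnorm(1, 0, spec$within_subject_frac *
                         spec$stance_duration_sd), 0.4)
  }
  tr
}

#' Write / read a gait trial as delimited text
#'
#' Tab-separated columns `time_s`, `emg_vl`, `emg_ta`, `emg_gm`, `fz_N`
#' with a header row.
#'
#' @param trial a `gait_trial`.
#' @param path file path.
#' @param rate sampling rate to assume when reading (inferred from the time
#'   column when `NULL`).
#' @return `read_gait_trial` returns a `gait_trial` (without ground truth).
#' @export
write_gait_trial <- function(trial, path) {
  df <- data.frame(time_s = trial$time, emg_vl = trial$emg$vl,
                   emg_ta = trial$emg$ta, emg_gm = trial$emg$gm,
                   fz_N = trial$grf_z)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gait_trial
#' @export
read_gait_trial <- function(path, rate = NULL) {
  df <- utils::read.delim(path)
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time_s))
  structure(list(rate = rate, time = df$time_s,
                 emg = list(vl = df$emg_vl, ta = df$emg_ta, gm = df$emg_gm),
                 grf_z = df$fz_N, stance_samples = NULL, truth = NULL),
            class = "gait_trial")
}

#' Write a cohort to disk (trial files + manifest)
#'
#' One tab-separated file per trial plus a `manifest.tsv` listing subject,
#' group, trial path and the subject-level ground truth.
#'
#' @param cohort result of [generate_cohort_trials()].
#' @param dir output directory (created if missing).
#' @return path of the manifest file.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort) {
    for (k in seq_along(subj$trials)) {
      f <- file.path(dir, sprintf("%s_trial%d.tsv", subj$subject, k))
      write_gait_trial(subj$trials[[k]], f)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject = subj$subject, group = subj$group, trial = k,
                   path = basename(f), stringsAsFactors = FALSE),
        as.data.frame(subj$truth[feature_names()]))
    }
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  mf
}
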