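# Extraction of the nine temporal and relative-magnitude variables from
# stance-normalized linear envelopes:
#   vl_time, ta_time, gm_time : time to peak activity (% stance)
#   vl_mag, ta_mag, gm_mag    : peak/minimum activity ratio (VL1/VL2, ...)
#   ta_mag_pushoff            : TA late-stance peak / TA minimum (TA3/TA2)
#   ta_onset                  : TA onset at push off (% stance)
#   gm_onset                  : GM propulsion-burst onset (% stance)

#' Default analysis windows for feature extraction
#'
#' Windows (in % stance) for peak, minimum and onset searches, plus onset
#' detector parameters. All values are configurable; the defaults follow
#' typical lower-limb envelope morphology (VL/TA peaks near heel strike,
#' GM burst in mid/late stance, TA push-off onset in terminal stance).
#'
#' @return named list of windows and onset parameters.
#' @export
default_feature_windows <- function() {
  list(
    vl_peak = c(0, 30), ta_peak = c(0, 20), gm_peak = c(30, 85),
    ta_pushoff_peak = c(75, 100),
    vl_min = c(30, 100), ta_min = c(20, 70), gm_min = c(0, 25),
    ta_onset_baseline = c(42, 54), ta_onset_search = c(55, 100),
    gm_onset_baseline = c(0, 15), gm_onset_search = c(15, 60),
    onset_k = 2, onset_min_run = 3, onset_floor_rel = 0.15)
}

window_idx <- function(env, window) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("invalid window [", paste(window, collapse = ", "), "]")
  }
  which(env$percent >= window[1] & env$percent <= window[2])
}

#' Locate the envelope peak within a window
#'
#' @param env a `stance_envelope`.
#' @param window `c(lo, hi)` in % stance.
#' @return list with `time` (% stance, ties broken by earliest time) and
#'   `value`.
#' @export
find_peak <- function(env, window) {
  i <- window_idx(env, window)
  j <- i[which.max(env$values[i])]
  list(time = env$percent[j], value = env$values[j])
}

#' Minimum envelope activity within a window
#'
#' @param env a `stance_envelope`.
#' @param window `c(lo, hi)` in % stance.
#' @return minimum value over the window.
#' @export
find_min <- function(env, window) {
  i <- window_idx(env, window)
  min(env$values[i])
}

#' Relative magnitude (peak over minimum activity)
#'
#' @param peak_value,min_value envelope activity values.
#' @param eps degenerate-baseline guard.
#' @return `peak_value / min_value`.
#' @export
relative_magnitude <- function(peak_value, min_value, eps = 1e-9) {
  if (min_value <= eps) stop("degenerate baseline: minimum activity is ~0")
  peak_value / min_value
}

#' Threshold-based onset detection
#'
#' The onset is the first grid time inside `search_window` at which the
#' envelope exceeds `baseline_mean + k * baseline_SD` for at least
#' `min_run` consecutive grid points. A relative floor on the threshold
#' excursion (`floor_rel`, default 15% of the baseline mean) keeps the
#' criterion meaningful when the baseline is nearly noise-free (the mean +
#' k SD rule alone degenerates as the baseline SD tends to zero).
#'
#' @param env a `stance_envelope`.
#' @param baseline_window,search_window windows in % stance (disjoint).
#' @param k threshold multiplier on the baseline SD.
#' @param min_run sustained-crossing run length in grid points.
#' @param floor_rel minimum threshold excursion relative to baseline mean.
#' @return onset time in % stance.
#' @export
detect_onset <- function(env, baseline_window, search_window, k = 2,
                         min_run = 3, floor_rel = 0.05) {
  if (max(baseline_window[1], search_window[1]) <
      min(baseline_window[2], search_window[2])) {
    stop("baseline and search windows must be disjoint")
  }
  base <- env$values[window_idx(env, baseline_window)]
  thr <- mean(base) + max(k * stats::sd(base), floor_rel * mean(base))
  i <- window_idx(env, search_window)
  above <- env$values[i] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) stop("no onset in window: envelope never exceeds threshold")
  first <- which(ok)[1]
  env$percent[i[ends[first] - r$lengths[first] + 1]]
}

#' Extract the nine EMG features from one trial's envelopes
#'
#' @param envelopes named list of `stance_envelope` objects with elements
#'   `vl`, `ta` and `gm` (as produced by [process_trial()]).
#' @param windows analysis windows, see [default_feature_windows()].
#' @return named numeric vector over [feature_names()]. Features whose
#'   sub-operation fails are `NA` and the failure messages (prefixed with
#'   the variable name) are attached as attribute `"errors"`.
#' @export
extract_features <- function(envelopes, windows = default_feature_windows()) {
  stopifnot(all(c("vl", "ta", "gm") %in% names(envelopes)))
  errors <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(name, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  vl <- envelopes$vl; ta <- envelopes$ta; gm <- envelopes$gm
  vl_peak <- grab("vl_time", find_peak(vl, windows$vl_peak))
  ta_peak <- grab("ta_time", find_peak(ta, windows$ta_peak))
  gm_peak <- grab("gm_time", find_peak(gm, windows$gm_peak))
  ta3 <- grab("ta_mag_pushoff", find_peak(ta, windows$ta_pushoff_peak)$value)
  vl_min <- grab("vl_mag", find_min(vl, windows$vl_min))
  ta_min <- grab("ta_mag", find_min(ta, windows$ta_min))
  gm_min <- grab("gm_mag", find_min(gm, windows$gm_min))
  out <- c(
    vl_time = if (is.list(vl_peak)) vl_peak$time else NA_real_,
    vl_mag = grab("vl_mag", relative_magnitude(vl_peak$value, vl_min)),
    ta_time = if (is.list(ta_peak)) ta_peak$time else NA_real_,
    ta_mag = grab("ta_mag", relative_magnitude(ta_peak$value, ta_min)),
    ta_onset = grab("ta_onset",
                    detect_onset(ta, windows$ta_onset_baseline,
                                 windows$ta_onset_search, k = windows$onset_k,
                                 min_run = windows$onset_min_run,
                                 floor_rel = windows$onset_floor_rel)),
    ta_mag_pushoff = grab("ta_mag_pushoff", relative_magnitude(ta3, ta_min)),
    gm_time = if (is.list(gm_peak)) gm_peak$time else NA_real_,
    gm_mag = grab("gm_mag", relative_magnitude(gm_peak$value, gm_min)),
    gm_onset = grab("gm_onset",
                    detect_onset(gm, windows$gm_onset_baseline,
                                 windows$gm_onset_search, k = windows$onset_k,
                                 min_run = windows$onset_min_run,
                                 floor_rel = windows$onset_floor_rel)))
  if (length(errors)) attr(out, "errors") <- errors
  out
}

#' Aggregate per-trial feature sets to one subject-level feature set
#'
#' Per-variable arithmetic mean over trials; trials in which a variable
#' failed to extract (`NA`) are skipped for that variable and the skip
#' count is recorded in attribute `"n_skipped"`.
#'
#' @param trial_features list of vectors from [extract_features()], or a
#'   matrix with one row per trial.
#' @return named numeric vector over [feature_names()].
#' @export
aggregate_subject <- function(trial_features) {
  m <- if (is.matrix(trial_features)) trial_features else
    do.call(rbind, trial_features)
  if (is.null(m) || nrow(m) < 1) stop("at least one trial is required")
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("variable(s) missing in all trials: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  }
  out <- colMeans(m, na.rm = TRUE)
  attr(out, "n_skipped") <- colSums(is.na(m))
  out
}

#' Run the full pipeline over a generated cohort
#'
#' Processes every trial of every subject ([process_trial()] +
#' [extract_features()]) and aggregates to one row per subject.
#'
#' @param cohort result of [generate_cohort_trials()].
#' @param windows analysis windows.
#' @param ... further arguments passed to [process_trial()].
#' @return data.frame: `subject`, `group`, then the nine features.
#' @export
extract_cohort_features <- function(cohort, windows = default_feature_windows(),
                                    ...) {
  rows <- lapply(cohort, function(subj) {
    feats <- lapply(subj$trials, function(tr) {
      extract_features(process_trial(tr, ...), windows = windows)
    })
    agg <- tryCatch(aggregate_subject(feats), error = function(e) {
      warning(sprintf("subject %s: %s", subj$subject, conditionMessage(e)),
              call. = FALSE)
      m <- do.call(rbind, feats)
      colMeans(m, na.rm = TRUE)   # all-NA columns stay NaN
    })
    agg[!is.finite(agg)] <- NA_real_
    cbind(data.frame(subject = subj$subject, group = subj$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(agg)))
  })
  do.call(rbind, rows)
}
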