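# Cohort specification for the synthetic-data generator.

#' Reference group-level EMG feature targets
#'
#' Mean and SD of the nine gait-EMG variables for the five study groups of a
#' diabetic-gait cohort (control, diabetic without neuropathy = "absent",
#' mild, moderate and severe neuropathy) used as the generator's default
#' targets. Times and onsets are in % stance, magnitudes are dimensionless
#' peak/minimum ratios.
#'
#' @return data.frame with columns `group`, `n`, then `<feature>_mean` /
#'   `<feature>_sd` for the nine features `vl_time`, `vl_mag`, `ta_time`,
#'   `ta_mag`, `ta_onset`, `ta_mag_pushoff`, `gm_time`, `gm_mag`,
#'   `gm_onset`.
#' @export
default_feature_targets <- function() {
  tg <- data.frame(
    group = c("control", "absent", "mild", "moderate", "severe"),
    n = c(30L, 43L, 30L, 16L, 28L),
    vl_time_mean = c(9.7, 12.1, 11.0, 9.7, 13.5),
    vl_time_sd = c(3.2, 2.3, 3.3, 2.5, 3.6),
    vl_mag_mean = c(8.3, 11.0, 13.6, 6.8, 17.1),
    vl_mag_sd = c(4.0, 6.5, 10.0, 3.1, 15.6),
    ta_time_mean = c(3.7, 4.2, 3.6, 2.2, 3.3),
    ta_time_sd = c(2.0, 2.4, 2.1, 2.0, 2.6),
    ta_mag_mean = c(60.9, 21.3, 24.7, 22.7, 33.4),
    ta_mag_sd = c(55.5, 12.8, 15.7, 20.6, 31.0),
    ta_onset_mean = c(90.4, 72.7, 79.4, 76.7, 68.8),
    ta_onset_sd = c(6.1, 10.8, 12.5, 10.5, 4.9),
    ta_mag_pushoff_mean = c(6.0, 8.1, 7.1, 7.6, 7.1),
    ta_mag_pushoff_sd = c(2.7, 2.7, 2.8, 2.0, 2.2),
    gm_time_mean = c(60.0, 60.5, 61.3, 59.3, 64.0),
    gm_time_sd = c(6.4, 5.1, 3.9, 4.3, 5.6),
    gm_mag_mean = c(52.8, 33.7, 37.9, 19.2, 16.0),
    gm_mag_sd = c(48.8, 24.0, 24.5, 13.5, 13.4),
    gm_onset_mean = c(40.4, 37.3, 38.7, 34.8, 38.1),
    gm_onset_sd = c(5.4, 5.4, 8.5, 9.2, 6.1),
    stringsAsFactors = FALSE)
  tg
}

#' Names of the nine extracted EMG features
#' @return character vector.
#' @export
feature_names <- function() {
  c("vl_time", "vl_mag", "ta_time", "ta_mag", "ta_onset",
    "ta_mag_pushoff", "gm_time", "gm_mag", "gm_onset")
}

#' Build a synthetic-cohort specification
#'
#' @param groups data.frame with columns `label` and `n`; labels must be a
#'   subset of control/absent/mild/moderate/severe. Default: the five
#'   reference groups at their reference sizes.
#' @param trials_per_subject gait trials collected per subject.
#' @param feature_targets per-group feature means and SDs, in the layout of
#'   [default_feature_targets()]; only rows for requested groups are used.
#' @param stance_duration_mean,stance_duration_sd stance-phase duration (s)
#'   across subjects. Self-selected-pace adult walking has stance phases of
#'   roughly 0.6-0.8 s.
#' @param rate sampling rate (Hz); EMG and ground reaction force are
#'   synchronous.
#' @param swing_pad swing-phase padding added before and after stance (s).
#' @param carrier `"noise"` (band-limited Gaussian interference-pattern
#'   carrier, 20-450 Hz, the realistic default) or `"sine"` (deterministic
#'   150 Hz carrier whose rectified-smoothed envelope is exactly
#'   proportional to the modulation profile; used for noiseless
#'   convergence checks).
#' @param within_subject_frac within-subject (trial-to-trial) SD as a
#'   fraction of the between-subject SD.
#' @param seed integer seed making the whole cohort reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL,
                        trials_per_subject = 5,
                        feature_targets = default_feature_targets(),
                        stance_duration_mean = 0.70,
                        stance_duration_sd = 0.05,
                        rate = 2000,
                        swing_pad = 0.2,
                        carrier = c("noise", "sine"),
                        within_subject_frac = 0.2,
                        seed = 1L) {
  carrier <- match.arg(carrier)
  if (is.null(groups)) {
    groups <- data.frame(label = feature_targets$group, n = feature_targets$n)
  }
  stopifnot(all(groups$n >= 1), stance_duration_mean > 0,
            trials_per_subject >= 1)
  bad <- setdiff(groups$label, feature_targets$group)
  if (length(bad)) stop("no feature targets for group(s): ",
                        paste(bad, collapse = ", "))
  sds <- unlist(feature_targets[grep("_sd$", names(feature_targets))])
  if (any(sds < 0)) stop("feature target SDs must be >= 0")
  if (rate <= 2 * 450) stop("sampling rate must exceed twice the carrier band")
  structure(list(groups = groups, trials_per_subject = trials_per_subject,
                 feature_targets = feature_targets,
                 stance_duration_mean = stance_duration_mean,
                 stance_duration_sd = stance_duration_sd,
                 rate = rate, swing_pad = swing_pad, carrier = carrier,
                 within_subject_frac = within_subject_frac,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort spec: %s; %d trial(s)/subject, %g Hz, %s carrier, seed %d\n",
              paste(sprintf("%s n=%d", x$groups$label, x$groups$n),
                    collapse = ", "),
              x$trials_per_subject, x$rate, x$carrier, x$seed))
  invisible(x)
}
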