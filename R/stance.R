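# Stance-phase segmentation from vertical ground reaction force, and
# amplitude/time normalization of linear envelopes onto a 0-100 % stance grid.

#' Detect the stance phase from vertical ground reaction force
#'
#' The stance phase is taken as the longest contiguous run of samples with
#' `grf_z > threshold` lasting at least `min_duration`. 20 N is a
#' conventional force-plate contact threshold.
#'
#' @param grf_z vertical ground reaction force (N).
#' @param rate sampling rate (Hz).
#' @param threshold contact threshold (N).
#' @param min_duration minimum stance duration (s).
#' @return object of class `stance_segment` with fields `start`, `end`
#'   (sample indices, 1-based, inclusive) and `duration` (s).
#' @export
detect_stance <- function(grf_z, rate, threshold = 20, min_duration = 0.1) {
  above <- grf_z > threshold
  if (!any(above)) stop("no stance detected: force never exceeds threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & (r$lengths / rate >= min_duration)
  if (!any(ok)) stop("no stance detected: no contact run of sufficient duration")
  i <- which(ok)[which.max(r$lengths[ok])]
  seg <- list(start = starts[i], end = ends[i],
              duration = (ends[i] - starts[i]) / rate)
  class(seg) <- "stance_segment"
  seg
}

#' @export
print.stance_segment <- function(x, ...) {
  cat(sprintf("stance segment: samples %d-%d (%.3f s)\n",
              x$start, x$end, x$duration))
  invisible(x)
}

#' Amplitude- and time-normalize a linear envelope over stance
#'
#' Slices the envelope to the stance segment, divides by its mean over that
#' slice (amplitude normalization "by the EMG mean value"), and linearly
#' resamples onto a closed 0-100 % stance grid of 101 points.
#'
#' @param envelope linear envelope (full trial length).
#' @param stance a [detect_stance()] segment.
#' @param muscle optional muscle label carried along.
#' @param denominator `"stance"` (default) normalizes by the envelope mean
#'   over the stance window; `"trial"` by the mean over the whole trial.
#' @return object of class `stance_envelope`: list with `muscle`,
#'   `percent` (0:100) and `values` (101 nonnegative samples, mean 1 under
#'   the default denominator).
#' @export
normalize_envelope <- function(envelope, stance, muscle = NA_character_,
                               denominator = c("stance", "trial")) {
  denominator <- match.arg(denominator)
  if (stance$start < 1 || stance$end > length(envelope)) {
    stop("stance segment outside signal bounds")
  }
  seg <- envelope[stance$start:stance$end]
  denom <- if (denominator == "stance") mean(seg) else mean(envelope)
  if (!is.finite(denom) || denom <= .Machine$double.eps) {
    stop("envelope mean over the normalization window is zero")
  }
  pct <- seq(0, 100, by = 1)
  values <- stats::approx(x = seq(0, 100, length.out = length(seg)),
                          y = seg / denom, xout = pct)$y
  out <- list(muscle = muscle, percent = pct, values = values)
  class(out) <- "stance_envelope"
  out
}

#' @export
print.stance_envelope <- function(x, ...) {
  cat(sprintf("stance envelope [%s]: 101 points, mean %.3f, peak %.2f at %d%%\n",
              x$muscle, mean(x$values), max(x$values),
              x$percent[which.max(x$values)]))
  invisible(x)
}

#' Quality-control flags for a raw trial
#'
#' Automatic stand-in for visual inspection: flags flat-lined segments
#' (identical consecutive samples for more than `flat_ms`) and amplitude
#' saturation (many samples at the absolute extremes). Flags only, the data
#' are never altered.
#'
#' @param trial a `gait_trial`.
#' @param flat_ms flat-line duration threshold (ms).
#' @return named logical vector per EMG channel with attributes describing
#'   the reason.
#' @export
qc_trial <- function(trial, flat_ms = 50) {
  flags <- vapply(names(trial$emg), function(m) {
    x <- trial$emg[[m]]
    r <- rle(diff(x) == 0)
    flat <- any(r$values & r$lengths > flat_ms / 1000 * trial$rate)
    sat <- mean(abs(x) >= max(abs(x)) * (1 - 1e-12)) > 0.01
    flat || sat
  }, logical(1))
  flags
}

#' Process one gait trial into stance-normalized envelopes
#'
#' Runs the full conditioning chain per EMG channel: offset removal,
#' zero-lag Butterworth band-pass (default 20-500 Hz, order 4), full-wave
#' rectification, zero-lag low-pass at 5 Hz (linear envelope), then stance
#' segmentation from the vertical ground reaction force and amplitude/time
#' normalization.
#'
#' @param trial a `gait_trial` (see [generate_gait_trial()] or
#'   [read_gait_trial()]).
#' @param band band-pass edges in Hz.
#' @param band_order band-pass design order.
#' @param lp_cutoff envelope low-pass cutoff in Hz.
#' @param stance_threshold,stance_min_duration stance detection parameters.
#' @param denominator amplitude-normalization denominator window.
#' @return named list of [normalize_envelope()] results, one per muscle,
#'   with the detected stance attached as attribute `"stance"`.
#' @export
process_trial <- function(trial, band = c(20, 500), band_order = 4,
                          lp_cutoff = 5, stance_threshold = 20,
                          stance_min_duration = 0.1,
                          denominator = c("stance", "trial")) {
  denominator <- match.arg(denominator)
  stance <- detect_stance(trial$grf_z, trial$rate,
                          threshold = stance_threshold,
                          min_duration = stance_min_duration)
  envs <- lapply(names(trial$emg), function(m) {
    x <- remove_offset(trial$emg[[m]])
    x <- bandpass_zero_lag(x, trial$rate, low = band[1], high = band[2],
                           order = band_order)
    env <- lowpass_envelope(rectify(x), trial$rate, cutoff = lp_cutoff)
    normalize_envelope(env, stance, muscle = m, denominator = denominator)
  })
  names(envs) <- names(trial$emg)
  attr(envs, "stance") <- stance
  envs
}
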