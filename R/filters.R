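# ---------------------------------------------------------------------------
# Butterworth IIR design (zero-pole-gain route, bilinear transform).
#
# No DSP package is assumed at run time, so the design is done here from the
# analog prototype: poles on the unit circle in the left half plane, frequency
# transformed (low-pass / band-pass) with pre-warped edges, then discretized
# by the bilinear transform. Coefficients agree with standard references to
# ~1e-12 relative error (see the test suite, which freezes independently
# computed coefficients).
# ---------------------------------------------------------------------------

# Analog Butterworth prototype: n poles, no zeros, unit gain.
butter_prototype <- function(order) {
  k <- seq_len(order)
  list(z = complex(0),
       p = exp(1i * pi * (2 * k + order - 1) / (2 * order)),
       k = 1)
}

lp2lp_zpk <- function(zpk, w0) {
  degree <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * w0, p = zpk$p * w0, k = zpk$k * w0^degree)
}

lp2bp_zpk <- function(zpk, w0, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zl <- zpk$z * bw / 2
  pl <- zpk$p * bw / 2
  z <- c(zl + sqrt(zl^2 - w0^2), zl - sqrt(zl^2 - w0^2), rep(0 + 0i, degree))
  p <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  list(z = z, p = p, k = zpk$k * bw^degree)
}

bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  degree <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = kd)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients `b` (numerator) and `a`
#' (denominator) of a digital Butterworth filter obtained by bilinear
#' transform with pre-warped edge frequencies.
#'
#' @param order filter order (of the analog prototype; a band-pass design of
#'   order `n` has `2n` poles).
#' @param cutoff cutoff frequency in Hz (one value for `"low"`/`"high"`, two
#'   for `"bandpass"`).
#' @param rate sampling rate in Hz.
#' @param type `"low"` or `"bandpass"`.
#' @return list with numeric vectors `b` and `a` (`a[1] == 1`).
#' @export
butter_design <- function(order, cutoff, rate, type = c("low", "bandpass")) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= rate / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, rate/2)")
  }
  warped <- 2 * rate * tan(pi * cutoff / rate)  # pre-warp
  proto <- butter_prototype(order)
  analog <- switch(type,
    low = lp2lp_zpk(proto, warped),
    bandpass = {
      if (length(cutoff) != 2 || cutoff[1] >= cutoff[2]) {
        stop("bandpass design needs cutoff = c(low, high) with low < high")
      }
      lp2bp_zpk(proto, w0 = sqrt(prod(warped)), bw = diff(warped))
    }
  )
  dig <- bilinear_zpk(analog, rate)
  b <- Re(poly_from_roots(dig$z)) * dig$k
  a <- Re(poly_from_roots(dig$p))
  list(b = b, a = a)
}

# Direct-form IIR filtering, delegated to C via stats::filter:
# convolution (MA part) then recursion (AR part). Zero initial conditions.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter `(b, a)` forwards and backwards so the net phase
#' response is zero and the magnitude response is squared. Edge transients
#' are controlled by odd-symmetric signal extension of length `padlen` at
#' both ends, which is stripped before returning.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal.
#' @param padlen extension length in samples; defaults to
#'   `3 * max(length(a), length(b))` and is capped at `length(x) - 1`.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  if (is.null(padlen)) padlen <- 3 * max(length(a), length(b))
  padlen <- min(padlen, n - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Remove the DC offset from a raw signal
#'
#' Subtracts the sample mean, so the output mean is exactly zero. Idempotent
#' for signals that are already zero-mean.
#'
#' @param raw numeric signal.
#' @return zero-mean signal.
#' @export
remove_offset <- function(raw) {
  if (length(raw) == 0) stop("empty signal")
  raw - mean(raw)
}

#' Zero-lag Butterworth band-pass filter
#'
#' Standard surface-EMG conditioning: a fourth-order Butterworth band-pass
#' (default 20-500 Hz) applied forwards and backwards (zero net phase,
#' squared magnitude response).
#'
#' @param raw numeric signal.
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @param order filter order of the underlying design (default 4).
#' @return filtered signal.
#' @export
bandpass_zero_lag <- function(raw, rate, low = 20, high = 500, order = 4) {
  if (high >= rate / 2) {
    stop("band-pass upper edge must be below the Nyquist frequency (rate/2)")
  }
  ba <- butter_design(order, c(low, high), rate, type = "bandpass")
  filtfilt_ba(ba$b, ba$a, raw,
              padlen = min(length(raw) - 1, round(1.5 * rate / low)))
}

#' Full-wave rectification
#'
#' @param x numeric signal.
#' @return elementwise absolute value.
#' @export
rectify <- function(x) abs(x)

#' Linear-envelope low-pass filter
#'
#' Zero-lag Butterworth low-pass (default 5 Hz cutoff, order 4) of a
#' rectified EMG signal; small negative ripple introduced by the filter is
#' clipped to zero so the envelope is nonnegative.
#'
#' @param rectified rectified (nonnegative) signal.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return nonnegative envelope, same length as input.
#' @export
lowpass_envelope <- function(rectified, rate, cutoff = 5, order = 4) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  ba <- butter_design(order, cutoff, rate, type = "low")
  env <- filtfilt_ba(ba$b, ba$a, rectified,
                     padlen = min(length(rectified) - 1,
                                  round(1.5 * rate / cutoff)))
  pmax(env, 0)
}
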