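#' Sliding median filter specification
#'
#' A 10 ms window slid in steps of one sample fully covers the roughly
#' 5 ms stimulation transient, so the window median suppresses the
#' high-amplitude peaks while low-frequency oscillations pass with small
#' attenuation. For even window lengths (10 samples at 1000 Hz) the median
#' is the mean of the two middle order statistics, and the output sample
#' is aligned to the window centre (no group delay).
#'
#' @param window_ms Window length in milliseconds (default 10).
#' @param edge_policy `"shrink"` (windows shrink at the signal ends,
#'   default) or `"reflect"` (signal reflected about its end points).
#' @return Object of class `median_filter_spec`.
#' @export
median_filter_spec <- function(window_ms = 10, edge_policy = c("shrink", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  if (!is.numeric(window_ms) || window_ms <= 0) {
    stopf("window_ms must be positive")
  }
  structure(list(window_ms = window_ms, edge_policy = edge_policy),
            class = "median_filter_spec")
}

window_samples <- function(spec, fs) {
  w <- round(spec$window_ms * fs / 1000)
  if (w < 3) stopf("window of %g ms is below 3 samples at %g Hz", spec$window_ms, fs)
  as.integer(w)
}

#' Apply the sliding median filter to a signal
#'
#' Output has the same length as the input; each output sample is the
#' median of the window centred on it, computed in steps of one sample.
#'
#' @param x Numeric signal (microvolts); a matrix is filtered column-wise.
#' @param fs Sampling rate in Hz.
#' @param spec A [median_filter_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
#' @examples
#' sliding_median_filter(c(0, 0, 0, 100, 0, 0, 0), fs = 1000,
#'                       spec = median_filter_spec(window_ms = 3))
sliding_median_filter <- function(x, fs, spec = median_filter_spec()) {
  w <- window_samples(spec, fs)
  edge <- if (spec$edge_policy == "shrink") 0L else 1L
  if (is.matrix(x)) {
    if (nrow(x) < w) stopf("window (%d samples) longer than signal (%d)", w, nrow(x))
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- .sliding_median_cpp(x[, j], w, edge)
    return(out)
  }
  if (length(x) < w) stopf("window (%d samples) longer than signal (%d)", w, length(x))
  .sliding_median_cpp(as.numeric(x), w, edge)
}

#' Frequency attenuation profile of the sliding median filter
#'
#' For each frequency a long unit-amplitude sinusoid is generated,
#' filtered, and the surviving peak amplitude measured over an integer
#' number of cycles away from the signal edges. Attenuation is
#' `(1 - A_out/A_in) x 100` percent. With a 10 ms window at 1000 Hz the
#' profile grows from near zero at low frequencies to complete
#' attenuation at 100 Hz, the frequency whose period exactly fits the
#' window (1.28%, 4.89% and 10.90% at 10, 20 and 30 Hz).
#'
#' @param spec A [median_filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies (Hz) at which to measure; must be below fs/2.
#' @param duration Test-signal duration in s (default 10).
#' @return Named numeric vector: percent attenuation per frequency.
#' @export
attenuation_profile <- function(spec = median_filter_spec(), fs = 1000,
                                freqs = c(10, 20, 30), duration = 10) {
  if (any(freqs >= fs / 2)) stopf("frequencies must be below fs/2")
  if (any(freqs <= 0)) stopf("frequencies must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  guard <- round(0.5 * fs)
  out <- vapply(freqs, function(f) {
    x <- sin(2 * pi * f * t)
    y <- sliding_median_filter(x, fs, spec)
    # integer number of cycles inside the guarded region
    usable <- n - 2 * guard
    n_cyc <- floor(usable * f / fs)
    if (n_cyc < 1) stopf("duration too short for %g Hz", f)
    idx <- guard + seq_len(round(n_cyc * fs / f))
    a_out <- max(abs(y[idx]))
    (1 - a_out) * 100
  }, numeric(1))
  names(out) <- as.character(freqs)
  out
}
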