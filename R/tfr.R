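#' Time-frequency / ERD analysis configuration
#'
#' Morlet wavelet decomposition from 1 to 45 Hz in 0.5 Hz steps, with the
#' ERD/ERS baseline taken at (-2.5, -1.5) s, the stimulation interval at
#' (0.5, 2.5) s (starting 0.5 s after onset to avoid the evoked response
#' at t = 0), and the non-stimulation interval at (-3, -1) s. Band
#' summaries cover rolandic alpha (7-13 Hz) and beta (14-30 Hz); the
#' sensorimotor region of interest is C3, C1, CP3, CP1 (contralateral to
#' the stimulated arm).
#'
#' @param freqs Analysis frequencies in Hz.
#' @param n_cycles Morlet wavelet width in cycles (default 7).
#' @param baseline Baseline interval (s) for the percent-change
#'   normalization.
#' @param stim_interval,nostim_interval Scalar-summary intervals (s).
#' @param bands Named list of band limits (Hz).
#' @param roi Region-of-interest channel labels.
#' @return Object of class `tfr_config`.
#' @export
tfr_config <- function(freqs = seq(1, 45, by = 0.5),
                       n_cycles = 7,
                       baseline = c(-2.5, -1.5),
                       stim_interval = c(0.5, 2.5),
                       nostim_interval = c(-3, -1),
                       bands = list(alpha = c(7, 13), beta = c(14, 30)),
                       roi = c("C3", "C1", "CP3", "CP1")) {
  if (n_cycles <= 0) stopf("n_cycles must be positive")
  for (iv in list(baseline, stim_interval, nostim_interval)) {
    if (length(iv) != 2 || iv[1] >= iv[2]) stopf("intervals must be increasing pairs")
  }
  for (b in bands) {
    if (b[1] >= b[2]) stopf("band limits must be increasing")
  }
  structure(list(freqs = freqs, n_cycles = n_cycles, baseline = baseline,
                 stim_interval = stim_interval,
                 nostim_interval = nostim_interval,
                 bands = bands, roi = roi),
            class = "tfr_config")
}

# Complex Morlet kernel at frequency f, unit-energy normalised: white
# noise then yields flat expected power across frequencies, and any
# per-frequency constant cancels in the baseline-ratio ERD normalization.
morlet_kernel <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  k <- env * exp(2i * pi * f * t)
  k / sqrt(sum(Mod(k)^2))
}

#' Morlet wavelet time-frequency power of an epoch set
#'
#' Convolves each trial and channel with unit-energy complex Morlet
#' wavelets and returns power (proportional to microvolts squared; the
#' per-frequency scale cancels in the percent-change normalization of
#' [erd_percent()]). Samples closer to the
#' epoch edges than the wavelet half-width `n_cycles / (2 f)` are
#' edge-contaminated; the half-widths are returned so interval selections
#' can be checked against them.
#'
#' @param epochs An `epoch_set`.
#' @param cfg A [tfr_config()].
#' @param channels Channels to analyse (default all).
#' @param keep_trials Keep the per-trial dimension (`TRUE`) or average
#'   power across trials on the fly (`FALSE`, default).
#' @return Object of class `tfr_power`: list with `power` (freq x time x
#'   channel, or trial x freq x time x channel when `keep_trials`),
#'   `freqs`, `time`, `channels`, `edge_halfwidth` (s, per frequency),
#'   `n_trials`.
#' @export
morlet_tfr <- function(epochs, cfg = tfr_config(), channels = NULL,
                       keep_trials = FALSE) {
  if (is.null(channels)) channels <- epochs$channels
  cidx <- match(channels, epochs$channels)
  if (anyNA(cidx)) stopf("unknown channels: %s",
                         paste(channels[is.na(cidx)], collapse = ", "))
  fs <- epochs$fs
  nt <- length(epochs$time)
  ntr <- dim(epochs$data)[1]
  freqs <- cfg$freqs
  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = cfg$n_cycles)
  halves <- vapply(kernels, function(k) (length(k) - 1L) / 2L, numeric(1))
  nfft <- stats::nextn(nt + max(lengths(kernels)) - 1L, c(2, 3, 5))
  kf <- lapply(kernels, function(k) fft(c(k, rep(0, nfft - length(k)))))

  if (keep_trials) {
    power <- array(0, c(ntr, length(freqs), nt, length(cidx)),
                   dimnames = list(NULL, NULL, NULL, channels))
  } else {
    power <- array(0, c(length(freqs), nt, length(cidx)),
                   dimnames = list(NULL, NULL, channels))
  }
  for (ci in seq_along(cidx)) {
    for (tr in seq_len(ntr)) {
      x <- epochs$data[tr, cidx[ci], ]
      X <- fft(c(x, rep(0, nfft - nt)))
      for (fi in seq_along(freqs)) {
        z <- fft(X * kf[[fi]], inverse = TRUE) / nfft
        p <- Mod(z[(halves[fi] + 1L):(halves[fi] + nt)])^2
        if (keep_trials) power[tr, fi, , ci] <- p
        else power[fi, , ci] <- power[fi, , ci] + p / ntr
      }
    }
  }
  structure(list(power = power, freqs = freqs, time = epochs$time,
                 channels = channels,
                 edge_halfwidth = cfg$n_cycles / (2 * freqs),
                 n_trials = ntr, keep_trials = keep_trials),
            class = "tfr_power")
}

# Warn when an analysis interval overlaps edge-contaminated samples at
# any analysis frequency; reports the lowest safe frequency.
check_interval_edges <- function(tfr, interval) {
  t0 <- min(tfr$time); t1 <- max(tfr$time)
  margin <- min(interval[1] - t0, t1 - interval[2])
  bad <- tfr$edge_halfwidth > margin
  if (any(bad)) {
    n_cycles <- tfr$edge_halfwidth[1] * 2 * tfr$freqs[1]
    warnf("interval (%g, %g) overlaps wavelet edge effects below %.2f Hz",
          interval[1], interval[2], n_cycles / (2 * margin))
  }
  invisible(!any(bad))
}

#' Percent power change relative to baseline (ERD/ERS)
#'
#' Converts trial-averaged wavelet power to percent change,
#' `ERD/ERS_j = (P_j - Baseline) / Baseline x 100`, where the baseline is
#' the mean power over the baseline interval, per frequency and channel.
#' Negative values (ERD) indicate desynchronization, i.e. cortical
#' activation; positive values (ERS) indicate a power increase.
#'
#' @param tfr A [morlet_tfr()] result (trial-averaged; per-trial input is
#'   averaged across trials first).
#' @param cfg A [tfr_config()] providing the baseline interval.
#' @return Object of class `erd_map`: `values` (freq x time x channel, in
#'   percent), `freqs`, `time`, `channels`, `baseline_power` (freq x
#'   channel).
#' @export
erd_percent <- function(tfr, cfg = tfr_config()) {
  p <- tfr$power
  if (isTRUE(tfr$keep_trials)) {
    p <- apply(p, c(2, 3, 4), mean)
  }
  check_interval_edges(tfr, cfg$baseline)
  bsel <- tfr$time >= cfg$baseline[1] & tfr$time <= cfg$baseline[2]
  if (!any(bsel)) stopf("baseline interval outside the epoch")
  base <- apply(p[, bsel, , drop = FALSE], c(1, 3), mean)
  if (any(base <= 0)) stopf("zero baseline power; cannot normalise")
  vals <- p
  for (ci in seq_len(dim(p)[3])) {
    vals[, , ci] <- (p[, , ci] - base[, ci]) / base[, ci] * 100
  }
  structure(list(values = vals, freqs = tfr$freqs, time = tfr$time,
                 channels = tfr$channels, baseline_power = base),
            class = "erd_map")
}

#' Scalar band/interval summary of an ERD map
#'
#' Averages the percent-change values over the band's frequency bins,
#' then over the interval's time samples (both operations are linear, so
#' the order only matters for bookkeeping). Returns one value per channel.
#'
#' @param erd An [erd_percent()] result.
#' @param band Band limits in Hz, or the name of a band in `cfg$bands`.
#' @param interval Interval in s, or `"stim"` / `"nostim"` from `cfg`.
#' @param cfg A [tfr_config()] used to resolve names.
#' @return Named numeric vector: percent change per channel.
#' @export
band_interval_summary <- function(erd, band = "alpha", interval = "stim",
                                  cfg = tfr_config()) {
  if (is.character(band)) band <- cfg$bands[[band]]
  if (is.character(interval)) {
    interval <- switch(interval, stim = cfg$stim_interval,
                       nostim = cfg$nostim_interval,
                       baseline = cfg$baseline,
                       stopf("unknown interval name"))
  }
  fsel <- erd$freqs >= band[1] & erd$freqs <= band[2]
  tsel <- erd$time >= interval[1] & erd$time <= interval[2]
  if (!any(fsel) || !any(tsel)) stopf("empty band or interval selection")
  v <- erd$values[fsel, tsel, , drop = FALSE]
  out <- apply(v, 3, mean)
  names(out) <- erd$channels
  out
}

#' Average per-channel values over the sensorimotor ROI
#'
#' Unweighted mean over the ROI channels that are available (present and
#' not masked out by channel rejection). The contributing channels are
#' attached as an attribute.
#'
#' @param values Named numeric vector of per-channel values, or a trials
#'   x channels matrix.
#' @param roi ROI channel labels (default sensorimotor C3, C1, CP3, CP1).
#' @param mask Optional logical vector (per channel) or trials x channels
#'   matrix; `FALSE` excludes a channel.
#' @return Scalar (or per-trial vector) ROI mean with attribute
#'   `"channels"`.
#' @export
roi_average <- function(values, roi = c("C3", "C1", "CP3", "CP1"),
                        mask = NULL) {
  if (is.matrix(values)) {
    use <- intersect(roi, colnames(values))
    if (!length(use)) stopf("no ROI channels available")
    m <- matrix(TRUE, nrow(values), length(use))
    if (!is.null(mask)) m <- mask[, use, drop = FALSE]
    v <- values[, use, drop = FALSE]
    v[!m] <- NA
    if (any(rowSums(m) == 0)) stopf("all ROI channels rejected for some trial")
    out <- rowMeans(v, na.rm = TRUE)
    return(structure(out, channels = use))
  }
  use <- intersect(roi, names(values))
  if (!is.null(mask)) use <- use[mask[use]]
  if (!length(use)) stopf("all ROI channels rejected")
  structure(mean(values[use]), channels = use)
}

#' @export
print.erd_map <- function(x, ...) {
  cat(sprintf("<erd_map> %d freqs (%g..%g Hz) x %d samples x %d channels, range %.1f..%.1f%%\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$time),
              length(x$channels), min(x$values), max(x$values)))
  invisible(x)
}

#' Plot an ERD/ERS time-frequency map
#'
#' Image of percent power change for one channel (blue = ERD,
#' red = ERS).
#'
#' @param x An `erd_map`.
#' @param channel Channel label (default first).
#' @param zlim Colour range in percent (default symmetric about 0).
#' @param ... Passed to [graphics::image()].
#' @export
plot.erd_map <- function(x, channel = x$channels[1], zlim = NULL, ...) {
  ci <- match(channel, x$channels)
  if (is.na(ci)) stopf("unknown channel '%s'", channel)
  z <- t(x$values[, , ci])
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(z))
  cols <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(x$time, x$freqs, z, zlim = zlim, col = cols,
                  xlab = "time relative to stimulation onset (s)",
                  ylab = "frequency (Hz)",
                  main = sprintf("ERD/ERS (%%), channel %s", channel), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
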