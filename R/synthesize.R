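# Synthetic session generation: 1/f background + narrowband oscillators
# with stimulation-locked envelope modulation + 50 Hz pickup + NMES
# transient trains. One master seed fans out to independent substreams
# (timeline, background, oscillators, artifacts, power line) so a component
# can be toggled without changing the realization of the others.

# Gaussian noise spectrally shaped to PSD ~ 1/f^exponent (flat below f0),
# scaled to RMS `sd_target`. Uses a length with small prime factors for the
# FFT and truncates.
one_over_f_noise <- function(n, fs, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  X <- fft(x)
  f <- c(0, seq_len(m - 1)) * (fs / m)
  f <- pmin(f, fs - f)            # two-sided frequency axis
  f0 <- 0.5                        # flatten below 0.5 Hz
  shape <- 1 / pmax(f, f0)^(exponent / 2)
  shape[1] <- 0                    # remove DC
  y <- Re(fft(X * shape, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y * (sd_target / sd(y))
}

# Unit-RMS Gaussian noise band-limited to [band[1], band[2]] Hz with a
# 1 Hz raised-cosine transition to limit ringing.
band_limited_noise <- function(n, fs, band) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(m))
  f <- c(0, seq_len(m - 1)) * (fs / m)
  f <- pmin(f, fs - f)
  tw <- 1
  g <- numeric(m)
  g[f >= band[1] & f <= band[2]] <- 1
  lo <- f >= band[1] - tw & f < band[1]
  hi <- f > band[2] & f <= band[2] + tw
  g[lo] <- 0.5 - 0.5 * cos(pi * (f[lo] - band[1] + tw) / tw)
  g[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - band[2]) / tw)
  y <- Re(fft(X * g, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / sd(y)
}

# Fraction of the 1/f background variance that falls inside `band`,
# mirroring the spectral shape used by one_over_f_noise (PSD flat below
# f0, then 1/f^exponent up to fs/2).
background_band_fraction <- function(band, exponent, fs, f0 = 0.5) {
  seg <- function(a, b) {
    a <- max(a, f0)
    if (b <= a) return(0)
    if (abs(exponent - 1) < 1e-12) log(b / a)
    else (b^(1 - exponent) - a^(1 - exponent)) / (1 - exponent)
  }
  flat <- function(a, b) max(0, min(b, f0) - min(a, f0)) * f0^(-exponent)
  total <- flat(0, fs / 2) + seg(f0, fs / 2)
  (flat(band[1], band[2]) + seg(band[1], band[2])) / total
}

# The planted roi_erd is defined on the total channel band power, but the
# envelope only modulates the oscillator; scale the modulation so the
# unmodulated in-band 1/f floor is accounted for.
erd_compensation <- function(gt, band_name) {
  band <- gt[[paste0(band_name, "_band")]]
  p_osc <- gt[[paste0(band_name, "_rms")]]^2
  if (p_osc == 0) return(1)
  p_bg <- gt$background_sd^2 *
    background_band_fraction(band, gt$background_exponent, 1000)
  (p_osc + p_bg) / p_osc
}

# Multiplicative amplitude envelope implementing per-trial percent power
# change with 200 ms raised-cosine transitions at the stimulation edges.
erd_envelope <- function(n, fs, trials, erd_by_trial, ramp = 0.2) {
  env <- rep(1, n)
  nr <- max(1L, round(ramp * fs))
  up <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = nr))
  for (k in seq_len(nrow(trials))) {
    erd <- max(erd_by_trial[k], -95)
    g <- sqrt(1 + erd / 100)
    i_on <- round(trials$stim_onset[k] * fs) + 1L
    i_off <- round(trials$stim_offset[k] * fs) + 1L
    ion_end <- min(i_on + nr - 1L, n)
    env[i_on:ion_end] <- 1 + (g - 1) * up[seq_len(ion_end - i_on + 1L)]
    if (ion_end < i_off) env[(ion_end + 1L):min(i_off, n)] <- g
    ioff_end <- min(i_off + nr - 1L, n)
    if (i_off < ioff_end) {
      env[i_off:ioff_end] <- g + (1 - g) * up[seq_len(ioff_end - i_off + 1L)]
    }
  }
  env
}

# Planted ERD of trial k of one intensity: base + session-wide drift per
# pooled trial index + within-block drift that resets each block.
erd_schedule <- function(trials_int, base, hab, wib) {
  pooled <- seq_len(nrow(trials_int))
  base + hab * (pooled - 1) + wib * (trials_int$trial - 1)
}

#' Generate a synthetic NMES-EEG session
#'
#' Produces a full multichannel recording with known ground truth: 32 EEG
#' channels (10/20 montage) containing 1/f background activity, rolandic
#' alpha/beta oscillators whose power drops by the planted ERD percentage
#' during each stimulation interval, 50 Hz power-line pickup (strong on
#' designated bad-impedance channels), and 35 Hz trains of short biphasic
#' stimulation transients scaled with intensity; plus two muscle channels
#' carrying the amplified artifact train, and the event annotations of the
#' block/trial schedule.
#'
#' @param design A [session_design()].
#' @param ground_truth A [neural_ground_truth()].
#' @param artifacts An [artifact_model()].
#' @param seed Master integer seed; fans out to independent substreams for
#'   the timeline, background, oscillators, artifact gains and power line.
#' @param thresholds Optional [intensity_thresholds()]; when given, the mA
#'   value of each intensity is recorded in the session metadata.
#'
#' @return An object of class `nmes_session`: list with elements `eeg`
#'   (samples x 32 matrix, microvolts, column names = channel labels),
#'   `emg` (samples x 2), `fs`, `annotations` (onset/label data frame),
#'   `trials` (per-trial schedule), `design`, `ground_truth`, `artifacts`,
#'   `intensities_mA`.
#' @export
synthesize_session <- function(design = session_design(),
                               ground_truth = neural_ground_truth(),
                               artifacts = artifact_model(),
                               seed = 1L,
                               thresholds = NULL) {
  montage <- nmes_montage()
  gt <- ground_truth
  am <- artifacts
  if (!all(am$bad_channels %in% montage)) {
    stopf("bad_channels not in montage: %s",
          paste(setdiff(am$bad_channels, montage), collapse = ", "))
  }
  if (!all(gt$roi %in% montage)) stopf("ROI channels not in montage")
  if (!is.null(am$transient_amplitude) && any(am$transient_amplitude > 0)) {
    miss <- setdiff(unique(design$intensities), names(am$transient_amplitude))
    if (length(miss)) stopf("transient_amplitude missing labels: %s",
                            paste(miss, collapse = ", "))
  }
  seeds <- substream_seeds(seed, 5L)
  tl <- build_timeline(design, seeds[1])
  fs <- design$fs
  n <- round(tl$duration * fs)
  nch <- length(montage)

  eeg <- matrix(0, n, nch, dimnames = list(NULL, montage))

  # 1/f background, independent per channel
  with_seed(seeds[2], {
    for (j in seq_len(nch)) {
      eeg[, j] <- one_over_f_noise(n, fs, gt$background_exponent,
                                   gt$background_sd)
    }
  })

  # narrowband oscillators with stimulation-locked envelopes
  with_seed(seeds[3], {
    env <- list()
    for (band in c("alpha", "beta")) {
      erd_all <- numeric(nrow(tl$trials))
      for (lab in unique(tl$trials$intensity)) {
        sel <- which(tl$trials$intensity == lab)
        erd_all[sel] <- erd_schedule(tl$trials[sel, , drop = FALSE],
                                     gt$roi_erd[[lab]][band],
                                     gt$habituation_slope[[lab]][band],
                                     gt$within_block_slope[[lab]][band])
      }
      erd_all <- erd_all * erd_compensation(gt, band)
      env[[band]] <- erd_envelope(n, fs, tl$trials, erd_all)
    }
    for (ch in gt$roi) {
      if (gt$alpha_rms > 0) {
        eeg[, ch] <- eeg[, ch] +
          gt$alpha_rms * env$alpha * band_limited_noise(n, fs, gt$alpha_band)
      }
      if (gt$beta_rms > 0) {
        eeg[, ch] <- eeg[, ch] +
          gt$beta_rms * env$beta * band_limited_noise(n, fs, gt$beta_band)
      }
    }
    if (gt$occipital_alpha_rms > 0) {
      for (ch in intersect(c("O1", "O2"), montage)) {
        eeg[, ch] <- eeg[, ch] +
          gt$occipital_alpha_rms * band_limited_noise(n, fs, gt$alpha_band)
      }
    }
  })

  # 50 Hz power line, random phase per channel, excess on bad channels
  with_seed(seeds[5], {
    tvec <- (seq_len(n) - 1) / fs
    for (j in seq_len(nch)) {
      a <- if (montage[j] %in% am$bad_channels) am$powerline_amplitude
           else am$baseline_powerline
      if (a > 0) eeg[, j] <- eeg[, j] + a * sin(2 * pi * 50 * tvec + runif(1, 0, 2 * pi))
    }
  })

  # NMES transient trains during stimulation intervals
  emg <- matrix(0, n, 2, dimnames = list(NULL, c("EMG1", "EMG2")))
  with_seed(seeds[4], {
    gains <- runif(nch, am$channel_gain_range[1], am$channel_gain_range[2])
    art <- numeric(n)
    shape_t <- (seq_along(am$transient_shape) - 1) / 1000
    dur_sh <- length(am$transient_shape) / 1000
    any_art <- any(am$transient_amplitude > 0)
    if (any_art) {
      for (k in seq_len(nrow(tl$trials))) {
        a <- am$transient_amplitude[tl$trials$intensity[k]]
        if (is.na(a) || a == 0) next
        t0 <- tl$trials$stim_onset[k]
        tp <- seq(t0, tl$trials$stim_offset[k] - dur_sh, by = 1 / am$pulse_rate)
        taps <- if (fs == 1000) a * am$transient_shape else {
          a * approx(shape_t, am$transient_shape,
                     xout = seq(0, dur_sh - 1 / fs, by = 1 / fs),
                     rule = 2)$y
        }
        for (t1 in tp) {
          i0 <- round(t1 * fs) + 1L
          idx <- i0:(i0 + length(taps) - 1L)
          art[idx] <- art[idx] + taps
        }
      }
      for (j in seq_len(nch)) eeg[, j] <- eeg[, j] + gains[j] * art
    }
    emg[, 1] <- am$emg_gain * art
    emg[, 2] <- 0.8 * am$emg_gain * art
    if (am$emg_noise_sd > 0) {
      emg[, 1] <- emg[, 1] + rnorm(n, sd = am$emg_noise_sd)
      emg[, 2] <- emg[, 2] + rnorm(n, sd = am$emg_noise_sd)
    }
  })

  structure(list(eeg = eeg, emg = emg, fs = fs,
                 annotations = tl$annotations, trials = tl$trials,
                 design = design, ground_truth = gt, artifacts = am,
                 intensities_mA = if (!is.null(thresholds))
                   compute_intensities(thresholds) else NULL),
            class = "nmes_session")
}

#' @export
print.nmes_session <- function(x, ...) {
  cat(sprintf("<nmes_session> %d channels + %d EMG, %.1f s at %g Hz\n",
              ncol(x$eeg), ncol(x$emg), nrow(x$eeg) / x$fs, x$fs))
  cat(sprintf("  %d trials in %d blocks; intensities: %s\n",
              nrow(x$trials), max(x$trials$block),
              paste(unique(x$trials$intensity), collapse = "/")))
  invisible(x)
}
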