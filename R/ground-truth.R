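#' Ground-truth neural modulation for the synthetic session generator
#'
#' Parameters of the simulated brain signal: a 1/f background, rolandic
#' alpha and beta oscillators over the contralateral sensorimotor
#' region of interest (ROI), occipital alpha, and the planted
#' event-related desynchronization (ERD) of each stimulation intensity.
#' ERD is realized as a multiplicative envelope change of the narrowband
#' oscillators, with the power ratio during stimulation equal to
#' `1 + erd/100` and smooth 200 ms transitions at the interval edges, so
#' that the percent-power definition used by the analysis is matched by
#' construction.
#'
#' Default ERD magnitudes increase with intensity (strongest above the
#' motor threshold), emulating the intensity-dependent sensorimotor
#' activation the pipeline is designed to quantify.
#'
#' @param roi_erd Named list per intensity, each a named numeric
#'   `c(alpha = , beta = )` percent power change during stimulation at the
#'   ROI channels (negative = desynchronization; must be > -100).
#' @param habituation_slope Same structure: percent ERD change per pooled
#'   trial index within an intensity (session-wide drift). Scalars recycle.
#' @param within_block_slope Same structure: percent ERD change per
#'   within-block trial index, resetting at each block boundary.
#' @param background_sd Broadband RMS amplitude of the 1/f background, in
#'   microvolts.
#' @param background_exponent Spectral exponent of the background
#'   (power spectral density proportional to `1/f^exponent`).
#' @param alpha_band,beta_band Frequency extent (Hz) of the two oscillators.
#' @param alpha_rms,beta_rms RMS amplitude (microvolts) of the ROI alpha and
#'   beta oscillators at baseline.
#' @param occipital_alpha_rms RMS amplitude (microvolts) of unmodulated
#'   occipital alpha (channels O1, O2).
#' @param roi ROI channel labels carrying the modulated oscillators.
#'
#' @return Object of class `neural_ground_truth`.
#' @export
neural_ground_truth <- function(
    roi_erd = list(low    = c(alpha = -8,  beta = -5),
                   medium = c(alpha = -12, beta = -8),
                   high   = c(alpha = -35, beta = -25)),
    habituation_slope = 0,
    within_block_slope = 0,
    background_sd = 10,
    background_exponent = 1,
    alpha_band = c(7, 13),
    beta_band = c(14, 30),
    alpha_rms = 10,
    beta_rms = 6,
    occipital_alpha_rms = 8,
    roi = c("C3", "C1", "CP3", "CP1")) {
  expand <- function(x, labels) {
    if (!is.list(x)) {
      x <- stats::setNames(rep(list(c(alpha = x[1],
                                      beta = if (length(x) > 1) x[2] else x[1])),
                               length(labels)), labels)
    }
    for (l in labels) {
      if (is.null(x[[l]])) stopf("missing intensity label '%s'", l)
      if (is.null(names(x[[l]]))) names(x[[l]]) <- c("alpha", "beta")
    }
    x[labels]
  }
  labels <- names(roi_erd)
  if (is.null(labels)) stopf("roi_erd must be a named list per intensity")
  habituation_slope <- expand(habituation_slope, labels)
  within_block_slope <- expand(within_block_slope, labels)
  if (any(unlist(roi_erd) <= -100)) {
    stopf("roi_erd percent values must be > -100 (power cannot go negative)")
  }
  amps <- c(background_sd, alpha_rms, beta_rms, occipital_alpha_rms)
  if (any(amps < 0)) stopf("amplitudes must be >= 0")
  structure(list(roi_erd = roi_erd, habituation_slope = habituation_slope,
                 within_block_slope = within_block_slope,
                 background_sd = background_sd,
                 background_exponent = background_exponent,
                 alpha_band = alpha_band, beta_band = beta_band,
                 alpha_rms = alpha_rms, beta_rms = beta_rms,
                 occipital_alpha_rms = occipital_alpha_rms, roi = roi),
            class = "neural_ground_truth")
}

#' Stimulation artifact and bad-channel model
#'
#' Describes the contamination added to the synthetic EEG: a 35 Hz train
#' of short (about 5 ms) high-amplitude biphasic transients during each
#' stimulation interval, whose amplitude grows with stimulation intensity
#' and varies across channels; excess 50 Hz power-line pickup on
#' designated bad-impedance channels; and a small 50 Hz baseline on all
#' channels. The muscle (EMG) channels carry an amplified copy of the
#' artifact train, which downstream onset detection exploits.
#'
#' @param pulse_rate Stimulation pulse rate in Hz (default 35).
#' @param pulse_width_us Electrical pulse width in microseconds (metadata;
#'   the recorded transient is modelled directly via `transient_shape`).
#' @param transient_amplitude Named numeric, peak transient amplitude in
#'   microvolts per intensity label; must be strictly increasing from low
#'   to high.
#' @param transient_shape Numeric taps (at 1000 Hz) of the canonical
#'   biphasic transient spanning about 5 ms; interpolated for other
#'   sampling rates. The default decays exponentially and changes sign so
#'   that no more than three consecutive samples share a sign.
#' @param bad_channels Character vector of channel labels with degraded
#'   impedance (strong 50 Hz pickup).
#' @param powerline_amplitude 50 Hz amplitude (microvolts) on bad channels.
#' @param baseline_powerline 50 Hz amplitude (microvolts) on normal channels.
#' @param channel_gain_range Range of the per-channel multiplicative gain
#'   applied to the EEG artifact (spatial variability of contamination).
#' @param emg_gain Artifact gain on the EMG channels relative to EEG.
#' @param emg_noise_sd EMG sensor noise RMS in microvolts.
#'
#' @return Object of class `artifact_model`.
#' @export
artifact_model <- function(
    pulse_rate = 35,
    pulse_width_us = 300,
    transient_amplitude = c(low = 200, medium = 400, high = 800),
    transient_shape = c(1, 0.7, -0.9, -0.6, 0.05),
    bad_channels = character(0),
    powerline_amplitude = 20,
    baseline_powerline = 1,
    channel_gain_range = c(0.5, 1.5),
    emg_gain = 5,
    emg_noise_sd = 2) {
  ta <- transient_amplitude
  if (length(ta) >= 2 && any(diff(unname(ta)) < 0)) {
    stopf("transient_amplitude must not decrease with intensity")
  }
  if (pulse_rate <= 0) stopf("pulse_rate must be positive")
  structure(list(pulse_rate = pulse_rate, pulse_width_us = pulse_width_us,
                 transient_amplitude = ta, transient_shape = transient_shape,
                 bad_channels = bad_channels,
                 powerline_amplitude = powerline_amplitude,
                 baseline_powerline = baseline_powerline,
                 channel_gain_range = channel_gain_range,
                 emg_gain = emg_gain, emg_noise_sd = emg_noise_sd),
            class = "artifact_model")
}
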