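# Properties of the synthetic session generator, checked with the same
# spectral estimators the cleaning stage uses.

one_block <- function(seed = 5, erd = 0, amp = c(low = 0, medium = 0, high = 0),
                      bad = character(0), powerline = 20) {
  synthesize_session(
    session_design(n_blocks = 1, trials_per_block = 6, intensities = "high"),
    gt_uniform(alpha = erd, beta = erd / 2),
    artifact_model(transient_amplitude = amp, bad_channels = bad,
                   powerline_amplitude = powerline),
    seed = seed)
}

band_power_in <- function(x, fs, band, idx) {
  ps <- nmeserd:::welch_psd(x[idx], fs)
  mean(ps$psd[ps$freq >= band[1] & ps$freq <= band[2]])
}

test_that("null effect: without ERD or artifacts, stimulation leaves band power flat", {
  s <- cached("synth_null", one_block(seed = 5, erd = 0))
  tr <- s$trials
  stim_idx <- unlist(lapply(seq_len(nrow(tr)), function(k)
    round(tr$stim_onset[k] * s$fs + 500):round(tr$stim_offset[k] * s$fs)))
  base_idx <- unlist(lapply(seq_len(nrow(tr)), function(k)
    round((tr$stim_onset[k] - 2.5) * s$fs):round((tr$stim_onset[k] - 1.5) * s$fs)))
  p_ratio <- vapply(s$ground_truth$roi, function(ch) {
    band_power_in(s$eeg[, ch], s$fs, c(7, 13), stim_idx) /
      band_power_in(s$eeg[, ch], s$fs, c(7, 13), base_idx)
  }, numeric(1))
  expect_true(all(abs(mean(p_ratio) - 1) < 0.15))
})

test_that("planted ERD drops stimulation-interval alpha power by about the stated percentage", {
  s <- cached("synth_erd40", one_block(seed = 5, erd = -40))
  tr <- s$trials
  stim_idx <- unlist(lapply(seq_len(nrow(tr)), function(k)
    round(tr$stim_onset[k] * s$fs + 500):round(tr$stim_offset[k] * s$fs)))
  base_idx <- unlist(lapply(seq_len(nrow(tr)), function(k)
    round((tr$stim_onset[k] - 2.5) * s$fs):round((tr$stim_onset[k] - 1.5) * s$fs)))
  ratios <- vapply(s$ground_truth$roi, function(ch) {
    band_power_in(s$eeg[, ch], s$fs, c(7, 13), stim_idx) /
      band_power_in(s$eeg[, ch], s$fs, c(7, 13), base_idx)
  }, numeric(1))
  # oscillator drops by 40%; the 1/f floor dilutes the observed drop a little
  expect_true(all(ratios > 0.5 & ratios < 0.8))
})

test_that("stimulation transients raise 35 Hz power during stimulation", {
  s <- cached("synth_art",
              one_block(seed = 6, amp = c(low = 200, medium = 400, high = 800)))
  tr <- s$trials
  stim_idx <- round(tr$stim_onset[1] * s$fs):round(tr$stim_offset[1] * s$fs)
  base_idx <- round((tr$stim_onset[1] - 3.2) * s$fs):round(tr$stim_onset[1] * s$fs - 200)
  p_stim <- band_power_in(s$eeg[, "C3"], s$fs, c(34, 36), stim_idx)
  p_base <- band_power_in(s$eeg[, "C3"], s$fs, c(34, 36), base_idx)
  expect_gt(p_stim / p_base, 10)
})

test_that("a 20x power-line channel stands far outside the channel distribution", {
  s <- cached("synth_bad", one_block(seed = 7, bad = "Cz"))
  pow <- nmeserd:::segment_band_power(
    s$eeg, s$fs, c(48, 52),
    nmeserd:::trial_segments(s$trials$stim_onset, s$fs, nrow(s$eeg)),
    1, 0.5)
  others <- pow[names(pow) != "Cz"]
  expect_gt(pow["Cz"], mean(others) + 4 * sd(others))
})

test_that("EMG artifact train is periodic at the pulse rate", {
  s <- cached("synth_art",
              one_block(seed = 6, amp = c(low = 200, medium = 400, high = 800)))
  tr <- s$trials
  idx <- round(tr$stim_onset[1] * s$fs):round(tr$stim_offset[1] * s$fs)
  x <- s$emg[idx, 1]
  ac <- stats::acf(x, lag.max = 60, plot = FALSE)$acf[-1]
  lag_period <- round(1000 / 35)  # samples
  expect_equal(which.max(ac[10:60]) + 9, lag_period, tolerance = 1)
})

test_that("component substreams are independent of one another", {
  a <- one_block(seed = 9, amp = c(low = 0, medium = 0, high = 0))
  b <- one_block(seed = 9, amp = c(low = 100, medium = 200, high = 400))
  # same timeline and same background/oscillator noise, different artifacts
  expect_identical(a$annotations, b$annotations)
  quiet <- seq_len(round(a$trials$stim_onset[1] * a$fs) - 1000)
  expect_equal(a$eeg[quiet, "C3"], b$eeg[quiet, "C3"])
  stim <- round(a$trials$stim_onset[1] * a$fs + 100):round(a$trials$stim_onset[1] * a$fs + 500)
  expect_false(isTRUE(all.equal(a$eeg[stim, "C3"], b$eeg[stim, "C3"])))
})
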