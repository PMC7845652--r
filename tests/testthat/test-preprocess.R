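test_that("common average reference zeroes the channel mean at every sample", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.numeric(common_average_reference(m)), c(-1, 1))

  same <- matrix(rep(1:10, 3), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(common_average_reference(same) == 0))

  set.seed(8)
  x <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("c", 1:5)))
  y <- common_average_reference(x)
  expect_true(all(abs(rowSums(y)) < 1e-9))

  expect_error(common_average_reference(x, retained = "c1"), "at least 2")
})

test_that("band-pass keeps 10 Hz, attenuates 60 Hz, removes DC", {
  fs <- 1000
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  amp_of <- function(y, f) {
    idx <- 5001:15000
    2 * abs(mean(y[idx] * exp(-2i * pi * f * tt[idx])))
  }
  # zero-phase 1st-order 0.1-45 Hz Butterworth: |H|^2 at 10 Hz is ~0.96
  y10 <- bandpass_filter(sin(2 * pi * 10 * tt), fs)
  expect_equal(amp_of(y10, 10), 1, tolerance = 0.05)
  y60 <- bandpass_filter(sin(2 * pi * 60 * tt), fs)
  expect_lt(amp_of(y60, 60), 0.8 * amp_of(y10, 10))
  ydc <- bandpass_filter(rep(100, length(tt)), fs)
  expect_lt(max(abs(ydc[5001:15000])), 5)
  expect_error(bandpass_filter(tt, fs, low = 0, high = 45), "cutoffs")
})

test_that("onset detection from the muscle artifact lands within 10 ms", {
  s <- cached("pp_session", synthesize_session(
    session_design(n_blocks = 1, trials_per_block = 4, intensities = "high"),
    gt_uniform(alpha = -30),
    artifact_model(transient_amplitude = c(low = 0, medium = 0, high = 600)),
    seed = 12))
  # jitter the annotated onsets; detection must recover the true ones
  jittered <- s$trials$stim_onset + runif(4, -0.2, 0.2)
  det <- detect_stim_onsets(s$emg, s$fs, jittered)
  expect_true(all(abs(as.numeric(det) - s$trials$stim_onset) <= 0.010))
  expect_true(all(attr(det, "detected")))
})

test_that("onset detection falls back to annotations for flat EMG", {
  emg <- matrix(0, 20000, 2)
  det <- detect_stim_onsets(emg, 1000, c(5.0, 12.5))
  expect_equal(as.numeric(det), c(5.0, 12.5))
  expect_false(any(attr(det, "detected")))
})

test_that("spurious EMG bursts outside the search window are ignored", {
  fs <- 1000
  emg <- matrix(rnorm(2 * 30000, sd = 1), ncol = 2)
  true_on <- 20.0
  emg[round(true_on * fs) + 1:50, ] <- 500      # real artifact
  emg[round(10 * fs) + 1:50, ] <- 800           # burst far from any event
  det <- detect_stim_onsets(emg, fs, annotated_onsets = true_on + 0.1)
  expect_equal(as.numeric(det), true_on, tolerance = 0.005)
})

test_that("epoching yields one 8-s trial per onset and drops edge cases", {
  fs <- 200
  eeg <- matrix(rnorm(fs * 60 * 2), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  trials <- data.frame(block = 1L, trial = 1:3,
                       intensity = "low",
                       stim_onset = c(2, 10, 20))  # first too close to start
  expect_warning(
    ep <- epoch_session(eeg, fs, trials$stim_onset, trials),
    "dropping 1")
  expect_equal(dim(ep$data), c(2, 2, 8 * fs))
  expect_equal(range(ep$time), c(-4, 4 - 1 / fs))
  # epoch content matches the raw slice
  i0 <- round((10 - 4) * fs) + 1
  expect_equal(ep$data[1, "a", ], eeg[i0:(i0 + 8 * fs - 1), "a"])
})

test_that("downsampling decimates by an integer factor and keeps the time span", {
  fs <- 1000
  eeg <- matrix(sin(2 * pi * 9 * seq(0, 39.999, by = 1 / fs)), ncol = 1,
                dimnames = list(NULL, "a"))
  trials <- data.frame(block = 1L, trial = 1:2, intensity = "low",
                       stim_onset = c(10, 25))
  ep <- epoch_session(eeg, fs, trials$stim_onset, trials)
  dn <- downsample_epochs(ep, 100)
  expect_equal(dim(dn$data)[3], 800)
  expect_equal(dn$fs, 100)
  expect_equal(range(dn$time), c(-4, 3.99))
  expect_equal(dn$data[1, 1, ], ep$data[1, 1, seq(1, 8000, by = 10)])
  expect_error(downsample_epochs(ep, 300), "integer multiple")
})

test_that("pooling groups trials by intensity in acquisition order", {
  s <- cached("pool_session", synthesize_session(
    small_design(), gt_uniform(alpha = -20), no_artifacts(), seed = 4))
  ep <- preprocess_session(s, rejection = FALSE, median_spec = NULL,
                           align_with_emg = FALSE)
  pooled <- pool_by_intensity(ep)
  expect_setequal(names(pooled), c("low", "medium", "high"))
  for (lab in names(pooled)) {
    e <- pooled[[lab]]
    expect_equal(dim(e$data)[1], 6)
    expect_true(all(diff(e$trials$onset) > 0))
    expect_true(all(e$trials$intensity == lab))
  }
  # total conserved
  expect_equal(sum(vapply(pooled, function(e) dim(e$data)[1], numeric(1))),
               dim(ep$data)[1])
  # shuffled trial order is restored by acquisition time
  shuf <- ep
  idx <- sample(dim(ep$data)[1])
  shuf$data <- shuf$data[idx, , , drop = FALSE]
  shuf$trials <- shuf$trials[idx, ]
  shuf$mask <- shuf$mask[idx, , drop = FALSE]
  pooled2 <- pool_by_intensity(shuf)
  for (lab in names(pooled2)) {
    expect_true(all(diff(pooled2[[lab]]$trials$onset) > 0))
  }
})

test_that("CAR zero-sum survives the linear downstream steps", {
  s <- cached("pool_session", synthesize_session(
    small_design(), gt_uniform(alpha = -20), no_artifacts(), seed = 4))
  ep <- preprocess_session(s, rejection = FALSE, median_spec = NULL,
                           align_with_emg = FALSE)
  # band-pass and decimation are linear and channel-independent, so the
  # instantaneous mean across channels stays (numerically) zero
  sums <- apply(ep$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-6)
})
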