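# Trial-wise ERD series, regression over trial order, block-wise fits.

test_that("identical trials give a constant series equal to the condition ERD", {
  fs <- 100
  tt <- -4 + (0:799) / fs
  g <- ifelse(tt >= 0, sqrt(0.6), 1)          # -40% power during stimulation
  one <- g * sin(2 * pi * 10 * tt)
  data <- array(rep(one, each = 6), c(6, 1, 800),
                dimnames = list(NULL, "C3", NULL))
  ep <- make_epochs(data, fs = fs)
  cfg <- tfr_config(freqs = seq(8, 12, 0.5))
  ser <- single_trial_erd(ep, cfg, "alpha")
  expect_lt(diff(range(ser)), 1e-9)
  expect_equal(ser[1], -40, tolerance = 3)
})

test_that("scaling one trial's stimulation power shifts only that element", {
  ep <- make_erd_epochs(ntr = 6, erd = -40)
  cfg <- tfr_config(freqs = seq(8, 12, 0.5))
  ser0 <- single_trial_erd(ep, cfg, "alpha")
  ep2 <- ep
  stim <- ep$time >= 0.3
  ep2$data[3, , stim] <- ep2$data[3, , stim] * sqrt(2)
  ser1 <- single_trial_erd(ep2, cfg, "alpha")
  # the grand-average baseline is shared and unchanged (baseline < 0 s)
  expect_gt(ser1[3] - ser0[3], 10)
  expect_equal(ser0[-3], ser1[-3], tolerance = 0.5)
})

test_that("series mean is consistent with the condition-averaged ERD", {
  ep <- make_erd_epochs(ntr = 20, erd = -35, seed = 77)
  cfg <- tfr_config(freqs = seq(7, 13, 0.5))
  ser <- single_trial_erd(ep, cfg, "alpha")
  erd <- erd_percent(morlet_tfr(ep, cfg), cfg)
  cond <- roi_average(band_interval_summary(erd, c(7, 13), "stim", cfg))
  expect_equal(mean(ser), as.numeric(cond), tolerance = 2)
})

test_that("regression recovers a perfect line and flags degenerate series", {
  r <- trial_regression(c(1, 2, 3, 4))
  expect_equal(r$slope, 1)
  expect_equal(r$pearson_r, 1)
  expect_true(r$r_defined)

  d <- trial_regression(c(5, 5, 5))
  expect_equal(d$slope, 0)
  expect_false(d$r_defined)
  expect_true(is.na(d$pearson_r))
  expect_false(d$significant)

  expect_error(trial_regression(c(1, 2)), "at least 3")
  expect_error(trial_regression(c(1, NA, 3)), "non-finite")
  # slope sign equals correlation sign
  set.seed(5)
  y <- -0.4 * (1:30) + rnorm(30)
  r2 <- trial_regression(y)
  expect_equal(sign(r2$slope), sign(r2$pearson_r))
})

test_that("block-wise fits expose within-block attenuation and between-block resets", {
  set.seed(9)
  blocks <- rep(1:3, each = 18)
  wib <- rep(0:17, 3)
  y <- -40 + 1.2 * wib + rnorm(54, sd = 1)    # decays toward zero, resets
  bw <- blockwise_regressions(y, blocks)
  expect_length(bw$regressions, 3)
  expect_length(bw$resets, 2)
  expect_true(all(vapply(bw$regressions, `[[`, numeric(1), "slope") > 0))
  expect_true(all(bw$resets < 0))

  flat <- blockwise_regressions(rep(-20, 54) + rnorm(54, sd = 0.01), blocks)
  expect_true(all(abs(vapply(flat$regressions, `[[`, numeric(1), "slope")) < 0.01))

  expect_warning(blockwise_regressions(y, c(rep(1, 52), 2, 2)), "fewer than 3")
})

test_that("planted habituation slope is recovered from the generator", {
  s <- cached("dose_session", synthesize_session(
    session_design(n_blocks = 2, trials_per_block = 12, intensities = "high",
                   inter_block = 8),
    gt_uniform(alpha = -40, beta = -20,
               habituation_slope = list(low = c(alpha = 0, beta = 0),
                                        medium = c(alpha = 0, beta = 0),
                                        high = c(alpha = 0.8, beta = 0))),
    no_artifacts(), seed = 31))
  ep <- preprocess_session(s, rejection = FALSE, median_spec = NULL)
  pooled <- pool_by_intensity(ep)
  ser <- single_trial_erd(pooled[["high"]], tfr_config(), "alpha")
  r <- trial_regression(ser)
  # 0.8 pp/trial planted; tolerance covers single-series sampling noise
  expect_equal(r$slope, 0.8, tolerance = 0.35)
  expect_gt(r$pearson_r, 0.3)
})
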