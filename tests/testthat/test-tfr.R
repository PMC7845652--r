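# Morlet decomposition and ERD/ERS quantification on constructed epochs.

test_that("wavelet power concentrates at the carrier frequency", {
  fs <- 100
  tt <- -4 + (0:799) / fs
  data <- array(sin(2 * pi * 10 * tt), c(1, 1, 800))
  ep <- make_epochs(data, fs = fs)
  cfg <- tfr_config(freqs = c(5, 10, 20))
  tfr <- morlet_tfr(ep, cfg)
  mid <- abs(ep$time) < 1
  p <- apply(tfr$power[, mid, 1], 1, mean)
  expect_gt(p[2] / p[3], 10)
  expect_gt(p[2] / p[1], 10)
})

test_that("white-noise epochs give flat mean power across bins", {
  set.seed(21)
  fs <- 100
  data <- array(rnorm(60 * 1 * 800), c(60, 1, 800))
  ep <- make_epochs(data, fs = fs)
  cfg <- tfr_config(freqs = seq(10, 40, by = 5))
  tfr <- morlet_tfr(ep, cfg)
  mid <- abs(ep$time) < 2
  p <- apply(tfr$power[, mid, 1], 1, mean)
  expect_lt(max(p) / min(p), 1.35)
})

test_that("halving the amplitude quarters the power", {
  fs <- 100
  tt <- -4 + (0:799) / fs
  amp <- ifelse(tt < 0, 1, 0.5)
  data <- array(amp * sin(2 * pi * 12 * tt), c(1, 1, 800))
  ep <- make_epochs(data, fs = fs)
  tfr <- morlet_tfr(ep, tfr_config(freqs = 12))
  p1 <- mean(tfr$power[1, ep$time > -3 & ep$time < -1, 1])
  p2 <- mean(tfr$power[1, ep$time > 1 & ep$time < 3, 1])
  expect_equal(p2 / p1, 0.25, tolerance = 0.03)
})

test_that("percent change follows the baseline-normalisation formula", {
  # direct substitution: P = 50 against baseline 100 -> -50%
  tfr <- structure(list(
    power = array(c(rep(100, 40), rep(50, 40)), c(1, 80, 1)),
    freqs = 10, time = seq(-4, 3.9, by = 0.1), channels = "C3",
    edge_halfwidth = 0.35, n_trials = 1, keep_trials = FALSE),
    class = "tfr_power")
  cfg <- tfr_config(freqs = 10)
  erd <- erd_percent(tfr, cfg)
  expect_equal(unique(erd$values[1, erd$time >= 0.5, 1]), -50)
  expect_equal(unique(erd$values[1, erd$time >= -2.5 & erd$time <= -1.5, 1]), 0)
})

test_that("recovered ERD matches the planted drop and baseline self-consistency holds", {
  ep <- make_erd_epochs(ntr = 16, erd = -40, f = 10)
  cfg <- tfr_config(freqs = seq(7, 13, 0.5))
  tfr <- morlet_tfr(ep, cfg)
  erd <- erd_percent(tfr, cfg)
  v <- band_interval_summary(erd, c(7, 13), "stim", cfg)
  expect_equal(as.numeric(roi_average(v)), -40, tolerance = 5)
  # condition-averaged ERD over the baseline interval is 0 by construction
  bsel <- erd$time >= -2.5 & erd$time <= -1.5
  expect_lt(max(abs(apply(erd$values[, bsel, , drop = FALSE], c(1, 3), mean))),
            1e-9)
})

test_that("ERD is invariant to a global amplitude rescaling", {
  ep <- make_erd_epochs(ntr = 4, erd = -30)
  cfg <- tfr_config(freqs = seq(8, 12, 1))
  e1 <- erd_percent(morlet_tfr(ep, cfg), cfg)
  ep$data <- ep$data * 13.7
  e2 <- erd_percent(morlet_tfr(ep, cfg), cfg)
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
})

test_that("band summaries select the right bins and intervals", {
  # constant map -> the constant, whatever band/interval
  em <- structure(list(values = array(-30, c(5, 80, 2)),
                       freqs = seq(8, 12), time = seq(-4, 3.9, by = 0.1),
                       channels = c("C3", "C1")), class = "erd_map")
  cfg <- tfr_config(freqs = seq(8, 12))
  expect_equal(unname(band_interval_summary(em, c(8, 12), "stim", cfg)),
               c(-30, -30))
  # beta-only modulation leaves the alpha summary near zero
  ep <- make_erd_epochs(ntr = 10, erd = -50, f = 20)
  cfgw <- tfr_config()
  erd <- suppressWarnings(erd_percent(morlet_tfr(ep, cfgw), cfgw))
  a <- unname(roi_average(band_interval_summary(erd, "alpha", "stim", cfgw)))
  b <- unname(roi_average(band_interval_summary(erd, "beta", "stim", cfgw)))
  expect_lt(abs(a), 8)
  expect_lt(b, -35)
  expect_error(band_interval_summary(em, c(20, 25), "stim", cfg), "empty")
})

test_that("ROI averaging respects masks and reports contributors", {
  v <- c(C3 = -10, C1 = -20, CP3 = -30, CP1 = -40)
  expect_equal(as.numeric(roi_average(v)), -25)
  m <- c(C3 = TRUE, C1 = TRUE, CP3 = FALSE, CP1 = TRUE)
  r <- roi_average(v, mask = m)
  expect_equal(as.numeric(r), mean(c(-10, -20, -40)))
  expect_setequal(attr(r, "channels"), c("C3", "C1", "CP1"))
  none <- c(C3 = FALSE, C1 = FALSE, CP3 = FALSE, CP1 = FALSE)
  expect_error(roi_average(v, mask = none), "rejected")
})

test_that("interval edge checking warns about slow wavelets", {
  ep <- make_erd_epochs(ntr = 2, erd = 0)
  cfg <- tfr_config(freqs = c(1.5, 10))
  expect_warning(erd_percent(morlet_tfr(ep, cfg), cfg), "edge effects")
})
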