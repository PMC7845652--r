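# Iterative power-line-based channel rejection on constructed blocks.

# small constructed block: broadband noise + a 50 Hz line per channel
toy_block <- function(n_ch = 8, dur = 20, fs = 500, line_amp = rep(1, n_ch),
                      seed = 1) {
  set.seed(seed)
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg <- sapply(seq_len(n_ch), function(j) {
    rnorm(length(tt), sd = 5) + line_amp[j] * sin(2 * pi * 50 * tt + j)
  })
  colnames(eeg) <- paste0("ch", seq_len(n_ch))
  list(eeg = eeg, fs = fs)
}

test_that("a single heavily contaminated channel is rejected in few iterations", {
  b <- toy_block(n_ch = 32, line_amp = c(20, rep(1, 31)), seed = 2)
  res <- reject_contaminated_channels(b$eeg, b$fs)
  rejected <- setdiff(colnames(b$eeg), res$retained)
  expect_identical(rejected, "ch1")
  expect_lte(length(res$report$iterations), 2)
  expect_true(res$report$converged)
})

test_that("identical channels produce no rejection (degenerate SD)", {
  b <- toy_block(n_ch = 1, seed = 3)
  eeg <- b$eeg[, rep(1, 6)]
  colnames(eeg) <- paste0("ch", 1:6)
  res <- reject_contaminated_channels(eeg, b$fs)
  expect_identical(res$retained, colnames(eeg))
  expect_true(res$report$converged)
})

test_that("two contaminated channels of different magnitude are both rejected iteratively", {
  # the second channel only exceeds the threshold once the first (which
  # inflates mean and SD) has been removed
  b <- toy_block(n_ch = 32, line_amp = c(40, 15, rep(1, 30)), seed = 4)
  res <- reject_contaminated_channels(b$eeg, b$fs)
  rejected <- setdiff(colnames(b$eeg), res$retained)
  expect_setequal(rejected, c("ch1", "ch2"))
  expect_gte(length(res$report$iterations), 2)
})

test_that("rejection is scale invariant and converges within n_channels iterations", {
  b <- toy_block(n_ch = 32, line_amp = c(25, rep(1, 31)), seed = 5)
  r1 <- reject_contaminated_channels(b$eeg, b$fs)
  r2 <- reject_contaminated_channels(b$eeg * 3.7, b$fs)
  expect_identical(r1$retained, r2$retained)
  expect_lte(length(r1$report$iterations), ncol(b$eeg))
  # every retained channel sits below the final threshold
  final <- r1$report$iterations[[length(r1$report$iterations)]]
  expect_true(all(final$power[r1$retained] <=
                    final$mean + 4 * final$sd + 1e-12))
  # rejected sets across iterations are disjoint
  rej <- lapply(r1$report$iterations, `[[`, "rejected")
  expect_equal(length(unlist(rej)), length(unique(unlist(rej))))
})

test_that("rejection aborts when fewer than 4 channels would survive", {
  # an aggressive threshold on well-separated channels keeps rejecting
  # until the statistics would become meaningless
  b <- toy_block(n_ch = 6, line_amp = c(20, 15, 10, 6, 3, 1), seed = 6)
  cfg <- rejection_config(sd_multiplier = 0.2)
  expect_error(reject_contaminated_channels(b$eeg, b$fs, cfg = cfg),
               "fewer than 4")
  expect_error(reject_contaminated_channels(b$eeg[, 1:3], b$fs), "at least 4")
})

test_that("Welch estimator recovers sinusoid band power", {
  fs <- 500
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 50 * tt)
  ps <- nmeserd:::welch_psd(x, fs)
  sel <- ps$freq >= 48 & ps$freq <= 52
  # integrated PSD over the band approximates the sinusoid power A^2/2
  expect_equal(sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1]), 4.5,
               tolerance = 0.05)
})
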