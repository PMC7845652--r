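#' Configuration of power-line-based channel rejection
#'
#' Channels whose skin-electrode impedance has degraded behave like
#' antennas and pick up disproportionate power-line (50 Hz) noise, so
#' unusually high 48-52 Hz power flags a bad channel. The statistic is
#' computed block-wise with Welch's method on high-pass-filtered data and
#' channels exceeding `mean + sd_multiplier x SD` are discarded
#' iteratively until none exceed the threshold.
#'
#' @param band Frequency band (Hz) summarising power-line pickup,
#'   default `c(48, 52)`.
#' @param hp_cutoff High-pass cutoff in Hz applied to a working copy
#'   before spectral estimation (default 0.1).
#' @param hp_order Butterworth order of the high-pass (default 4).
#' @param welch_window Welch segment length in s (default 1, Hamming).
#' @param welch_overlap Segment overlap fraction in `[0, 1)` (default 0.5).
#' @param sd_multiplier Rejection threshold in standard deviations above
#'   the mean (default 4).
#' @return Object of class `rejection_config`.
#' @export
rejection_config <- function(band = c(48, 52), hp_cutoff = 0.1, hp_order = 4,
                             welch_window = 1, welch_overlap = 0.5,
                             sd_multiplier = 4) {
  if (welch_overlap < 0 || welch_overlap >= 1) stopf("overlap must be in [0, 1)")
  if (sd_multiplier <= 0) stopf("sd_multiplier must be positive")
  if (length(band) != 2 || band[1] >= band[2] || band[1] <= 0) {
    stopf("band must be an increasing positive interval")
  }
  structure(list(band = band, hp_cutoff = hp_cutoff, hp_order = hp_order,
                 welch_window = welch_window, welch_overlap = welch_overlap,
                 sd_multiplier = sd_multiplier),
            class = "rejection_config")
}

# Welch PSD (one-sided density, Hamming window) of one contiguous signal.
# Returns list(freq, psd).
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  L <- round(window_s * fs)
  if (length(x) < L) stopf("signal shorter than one Welch window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hamming
  norm <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    X <- fft(x[s:(s + L - 1L)] * w)
    p <- Mod(X[seq_len(nf)])^2 / norm
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = acc / length(starts))
}

# Mean band power per channel over a set of segments (index ranges).
segment_band_power <- function(eeg, fs, band, segments, window_s, overlap) {
  nch <- ncol(eeg)
  pow <- numeric(nch)
  for (j in seq_len(nch)) {
    acc <- 0; nw <- 0L
    for (seg in segments) {
      ps <- welch_psd(eeg[seg, j], fs, window_s, overlap)
      sel <- ps$freq >= band[1] & ps$freq <= band[2]
      acc <- acc + mean(ps$psd[sel])
      nw <- nw + 1L
    }
    pow[j] <- acc / nw
  }
  names(pow) <- colnames(eeg)
  pow
}

# Segment index ranges covering the trials of a block ([-4, +4] s around
# each stimulation onset), clipped to the recording.
trial_segments <- function(onsets, fs, n, half = 4) {
  lapply(onsets, function(t0) {
    i0 <- max(1L, round((t0 - half) * fs) + 1L)
    i1 <- min(n, round((t0 + half) * fs))
    i0:i1
  })
}

#' Iterative rejection of power-line-contaminated channels
#'
#' High-pass filters a working copy of the block, estimates each channel's
#' mean 48-52 Hz Welch power over all trial segments, and iteratively
#' discards channels above `mean + 4 SD` of the surviving channels until
#' none exceed the threshold. The returned data are the original
#' (unfiltered) samples of the retained channels; the spectral working
#' copy is internal.
#'
#' @param eeg Samples x channels matrix (one block), column names =
#'   channel labels.
#' @param fs Sampling rate in Hz.
#' @param onsets Stimulation onsets (s) of the block's trials; the
#'   statistic uses the 8-s trial windows around them. `NULL` uses the
#'   whole block.
#' @param cfg A [rejection_config()].
#' @return List with `retained` (channel labels), `report` (class
#'   `channel_rejection_report`: per-iteration power/mean/SD/rejections,
#'   `final_retained`, `converged`).
#' @export
reject_contaminated_channels <- function(eeg, fs, onsets = NULL,
                                         cfg = rejection_config()) {
  if (ncol(eeg) < 4) stopf("need at least 4 channels for rejection statistics")
  if (nrow(eeg) < 3 * fs) stopf("need at least a few seconds of data")
  labels <- colnames(eeg)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(eeg)))

  bf <- signal::butter(cfg$hp_order, cfg$hp_cutoff / (fs / 2), type = "high")
  work <- apply(eeg, 2, function(x) signal::filtfilt(bf, x))
  segs <- if (is.null(onsets)) list(seq_len(nrow(eeg)))
          else trial_segments(onsets, fs, nrow(eeg))
  pow <- segment_band_power(work, fs, cfg$band, segs,
                            cfg$welch_window, cfg$welch_overlap)
  names(pow) <- labels

  retained <- labels
  iterations <- list()
  converged <- FALSE
  for (it in seq_along(labels)) {
    p <- pow[retained]
    m <- mean(p); s <- sd(p)
    if (!is.finite(s) || s < .Machine$double.eps * max(1, m)) {
      # degenerate spread (e.g. identical channels): nothing exceeds
      iterations[[it]] <- list(power = p, mean = m, sd = s,
                               rejected = character(0))
      converged <- TRUE
      break
    }
    bad <- names(p)[p > m + cfg$sd_multiplier * s]
    iterations[[it]] <- list(power = p, mean = m, sd = s, rejected = bad)
    if (!length(bad)) { converged <- TRUE; break }
    retained <- setdiff(retained, bad)
    if (length(retained) < 4) {
      stopf("fewer than 4 channels survive rejection; statistics are meaningless (rejected: %s)",
            paste(setdiff(labels, retained), collapse = ", "))
    }
  }
  report <- structure(list(iterations = iterations,
                           final_retained = retained,
                           converged = converged),
                      class = "channel_rejection_report")
  list(retained = retained, report = report)
}

#' @export
print.channel_rejection_report <- function(x, ...) {
  cat(sprintf("<channel_rejection_report> %d iteration(s), converged: %s\n",
              length(x$iterations), x$converged))
  rej <- unlist(lapply(x$iterations, `[[`, "rejected"))
  cat(sprintf("  rejected: %s\n",
              if (length(rej)) paste(rej, collapse = ", ") else "none"))
  invisible(x)
}

#' Block-wise channel rejection over a whole session
#'
#' Applies [reject_contaminated_channels()] to each block of a session,
#' using that block's trial windows. A channel rejected in one block is
#' excluded from downstream averages for that block only.
#'
#' @param session An `nmes_session`.
#' @param cfg A [rejection_config()].
#' @return List with `mask` (blocks x channels logical matrix, TRUE =
#'   retained) and `reports` (per-block rejection reports).
#' @export
reject_channels_by_block <- function(session, cfg = rejection_config()) {
  trials <- session$trials
  blocks <- sort(unique(trials$block))
  labels <- colnames(session$eeg)
  mask <- matrix(TRUE, length(blocks), length(labels),
                 dimnames = list(paste0("block", blocks), labels))
  reports <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    onsets <- trials$stim_onset[trials$block == b]
    rng <- block_sample_range(session, b)
    res <- reject_contaminated_channels(
      session$eeg[rng, , drop = FALSE], session$fs,
      onsets - (rng[1] - 1) / session$fs, cfg)
    mask[i, ] <- labels %in% res$retained
    reports[[i]] <- res$report
  }
  list(mask = mask, reports = reports)
}

# Sample range (indices) of block b: from its block_start annotation (or
# 5 s before its first ready cue) to the start of the next block.
block_sample_range <- function(session, b) {
  trials <- session$trials
  fs <- session$fs
  n <- nrow(session$eeg)
  blocks <- sort(unique(trials$block))
  t0 <- if (b == blocks[1]) 0 else min(trials$stim_onset[trials$block == b]) - 8
  nxt <- blocks[blocks > b]
  t1 <- if (length(nxt)) min(trials$stim_onset[trials$block == nxt[1]]) - 8
        else n / fs
  i0 <- max(1L, round(t0 * fs) + 1L)
  i1 <- min(n, round(t1 * fs))
  i0:i1
}
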