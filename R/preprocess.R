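# Preprocessing chain: common average reference, band-pass, stimulation
# onset alignment from the muscle channels, epoching, downsampling and
# pooling by intensity. Order of operations over a session follows the
# two-step cleaning (channel rejection, median filter) -> CAR -> band-pass
# -> epoch -> downsample -> pool.

#' Common average reference
#'
#' Subtracts the instantaneous mean over the retained channels from each
#' retained channel; afterwards the mean across retained channels is zero
#' at every sample.
#'
#' @param eeg Samples x channels matrix with column names.
#' @param retained Labels of the channels entering the reference (default
#'   all). Contaminated channels must be excluded so they do not re-inject
#'   artifact through the mean.
#' @return Matrix of the same shape; non-retained columns are unchanged.
#' @export
common_average_reference <- function(eeg, retained = colnames(eeg)) {
  idx <- match(retained, colnames(eeg))
  if (anyNA(idx)) stopf("unknown channels: %s",
                        paste(retained[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stopf("CAR needs at least 2 retained channels")
  ref <- rowMeans(eeg[, idx, drop = FALSE])
  eeg[, idx] <- eeg[, idx, drop = FALSE] - ref
  eeg
}

#' Zero-phase Butterworth band-pass filter
#'
#' First-order 0.1-45 Hz Butterworth by default, applied forward and
#' backward (zero phase, effective order doubled) so that response
#' latencies relative to stimulation onset are preserved.
#'
#' @param x Signal vector or samples x channels matrix.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order of the one-pass prototype (default 1).
#' @return Filtered signal, same shape.
#' @export
bandpass_filter <- function(x, fs, low = 0.1, high = 45, order = 1) {
  if (low <= 0 || high >= fs / 2 || low >= high) {
    stopf("cutoffs must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- signal::filtfilt(bf, x[, j])
    x
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Align stimulation onsets using the muscle channels
#'
#' The stimulation artifact recorded by the muscle sensors marks the true
#' onset of each pulse train. The rectified EMG is thresholded at
#' `median + k x MAD` (robust to the artifact's heavy tail) and, for each
#' annotated stimulation event, the first crossing within +/- `search` s
#' of the annotated onset is taken. Events with no crossing (e.g. zero
#' artifact amplitude) fall back to the annotated onset.
#'
#' @param emg Samples x channels EMG matrix.
#' @param fs Sampling rate in Hz.
#' @param annotated_onsets Annotated stimulation onsets in s.
#' @param k MAD multiplier of the threshold (default 8).
#' @param search Half-width (s) of the search window (default 0.5).
#' @return Numeric vector of onsets (s), one per annotated event, with a
#'   logical attribute `"detected"` marking events aligned from the EMG.
#' @export
detect_stim_onsets <- function(emg, fs, annotated_onsets, k = 8, search = 0.5) {
  r <- rowMeans(abs(emg))
  thr <- median(r) + k * mad(r)
  n <- length(r)
  out <- numeric(length(annotated_onsets))
  detected <- logical(length(annotated_onsets))
  for (i in seq_along(annotated_onsets)) {
    t0 <- annotated_onsets[i]
    i0 <- max(1L, round((t0 - search) * fs) + 1L)
    i1 <- min(n, round((t0 + search) * fs))
    hit <- which(r[i0:i1] > thr)
    if (length(hit) && thr > 0) {
      out[i] <- (i0 + hit[1] - 2L) / fs
      detected[i] <- TRUE
    } else {
      out[i] <- t0
    }
  }
  structure(out, detected = detected)
}

#' Cut a continuous recording into stimulation-locked epochs
#'
#' Extracts one window per onset, spanning `window` seconds around it
#' (left-closed: `[-4, +4)` gives exactly `8 x fs` samples). Onsets whose
#' window would leave the recording are dropped with a warning.
#'
#' @param eeg Samples x channels matrix.
#' @param fs Sampling rate in Hz.
#' @param onsets Stimulation onsets in s.
#' @param trials Data frame describing each onset (block, trial,
#'   intensity); rows must match `onsets`.
#' @param window Epoch window in s relative to onset, default `c(-4, 4)`.
#' @param mask Optional blocks x channels logical matrix from block-wise
#'   channel rejection; expanded to a per-trial channel mask.
#' @return Object of class `epoch_set`: list with `data` (trials x
#'   channels x time array), `time` (s, relative to onset), `fs`,
#'   `channels`, `trials` (metadata), `mask` (trials x channels logical).
#' @export
epoch_session <- function(eeg, fs, onsets, trials, window = c(-4, 4),
                          mask = NULL) {
  stopifnot(length(onsets) == nrow(trials))
  nt <- round((window[2] - window[1]) * fs)
  n <- nrow(eeg)
  i_on <- round(onsets * fs) + 1L
  first <- i_on + round(window[1] * fs)
  keep <- first >= 1L & (first + nt - 1L) <= n
  if (!any(keep)) stopf("no usable onsets: all epochs leave the recording")
  if (any(!keep)) {
    warnf("dropping %d epoch(s) too close to the recording edges", sum(!keep))
  }
  onsets <- onsets[keep]; first <- first[keep]
  trials <- trials[keep, , drop = FALSE]
  nch <- ncol(eeg)
  data <- array(NA_real_, c(length(onsets), nch, nt),
                dimnames = list(NULL, colnames(eeg), NULL))
  for (k in seq_along(onsets)) {
    data[k, , ] <- t(eeg[first[k]:(first[k] + nt - 1L), , drop = FALSE])
  }
  tmask <- matrix(TRUE, length(onsets), nch,
                  dimnames = list(NULL, colnames(eeg)))
  if (!is.null(mask)) {
    bidx <- match(paste0("block", trials$block), rownames(mask))
    tmask[] <- mask[bidx, colnames(eeg), drop = FALSE]
  }
  ord <- order(onsets)
  structure(list(data = data[ord, , , drop = FALSE],
                 time = window[1] + (seq_len(nt) - 1) / fs,
                 fs = fs, channels = colnames(eeg),
                 trials = cbind(trials[ord, , drop = FALSE],
                                onset = onsets[ord]),
                 mask = tmask[ord, , drop = FALSE]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples at %g Hz (%.2f..%.2f s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$time), max(x$time)))
  invisible(x)
}

#' Downsample epochs by an integer factor
#'
#' Decimates to the target rate by keeping every `fs/target`-th sample.
#' The 45 Hz band-pass applied upstream keeps the decimation to 100 Hz
#' Nyquist-safe.
#'
#' @param epochs An [epoch_session()] result.
#' @param target Target sampling rate in Hz (default 100); `fs` must be an
#'   integer multiple of it.
#' @return Downsampled `epoch_set`.
#' @export
downsample_epochs <- function(epochs, target = 100) {
  factor <- epochs$fs / target
  if (abs(factor - round(factor)) > 1e-9) {
    stopf("fs (%g) is not an integer multiple of the target rate (%g)",
          epochs$fs, target)
  }
  factor <- as.integer(round(factor))
  idx <- seq(1L, dim(epochs$data)[3], by = factor)
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$time <- epochs$time[idx]
  epochs$fs <- target
  epochs
}

#' Pool epochs by stimulation intensity
#'
#' Concatenates trials belonging to the same intensity across blocks, in
#' order of acquisition (block order of appearance, within-block order
#' preserved), as required by the trial-wise dose-effect analysis.
#'
#' @param epochs An `epoch_set`, or a list of them with identical
#'   montages (concatenated by acquisition time first).
#' @return Named list of `epoch_set`, one per intensity present.
#' @export
pool_by_intensity <- function(epochs) {
  if (!inherits(epochs, "epoch_set") && is.list(epochs)) {
    es <- epochs[[1]]
    for (e in epochs[-1]) {
      if (!identical(e$channels, es$channels)) {
        stopf("inconsistent montages across pooled epoch sets")
      }
      es$data <- abind3(es$data, e$data)
      es$trials <- rbind(es$trials, e$trials)
      es$mask <- rbind(es$mask, e$mask)
    }
    epochs <- es
  }
  ord <- order(epochs$trials$onset)
  labels <- unique(epochs$trials$intensity[ord])
  out <- lapply(labels, function(lab) {
    sel <- ord[epochs$trials$intensity[ord] == lab]
    e <- epochs
    e$data <- e$data[sel, , , drop = FALSE]
    e$trials <- e$trials[sel, , drop = FALSE]
    e$mask <- e$mask[sel, , drop = FALSE]
    e
  })
  names(out) <- labels
  out
}

# rbind for trials x channels x time arrays
abind3 <- function(a, b) {
  stopifnot(identical(dim(a)[-1], dim(b)[-1]))
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = list(NULL, dimnames(a)[[2]], NULL))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Run the full preprocessing chain on a session
#'
#' Applies, in order: block-wise channel rejection, the sliding median
#' filter, per-block common average referencing over retained channels,
#' zero-phase 0.1-45 Hz band-pass, EMG-based stimulation-onset alignment,
#' epoching to `[-4, +4)` s and downsampling to 100 Hz.
#'
#' @param session An `nmes_session`.
#' @param rejection Result of [reject_channels_by_block()], or `NULL` to
#'   compute it; `FALSE` skips rejection (all channels retained).
#' @param median_spec A [median_filter_spec()], or `NULL` to skip the
#'   median filter.
#' @param rejection_cfg A [rejection_config()] used when `rejection` is
#'   `NULL`.
#' @param target_fs Epoch sampling rate after decimation (default 100).
#' @param align_with_emg Align onsets from the muscle channels (default
#'   TRUE; falls back to annotations where no artifact is detected).
#' @return An `epoch_set` (with per-trial channel masks), with the
#'   rejection result attached as attribute `"rejection"`.
#' @export
preprocess_session <- function(session, rejection = NULL,
                               median_spec = median_filter_spec(),
                               rejection_cfg = rejection_config(),
                               target_fs = 100, align_with_emg = TRUE) {
  if (isFALSE(rejection)) {
    blocks <- sort(unique(session$trials$block))
    mask <- matrix(TRUE, length(blocks), ncol(session$eeg),
                   dimnames = list(paste0("block", blocks),
                                   colnames(session$eeg)))
    rejection <- list(mask = mask, reports = list())
  } else if (is.null(rejection)) {
    rejection <- reject_channels_by_block(session, rejection_cfg)
  }
  eeg <- session$eeg
  if (!is.null(median_spec)) {
    eeg <- sliding_median_filter(eeg, session$fs, median_spec)
  }
  blocks <- sort(unique(session$trials$block))
  for (i in seq_along(blocks)) {
    rng <- block_sample_range(session, blocks[i])
    retained <- colnames(eeg)[rejection$mask[i, ]]
    eeg[rng, ] <- common_average_reference(eeg[rng, , drop = FALSE], retained)
  }
  eeg <- bandpass_filter(eeg, session$fs)
  onsets <- if (align_with_emg && !is.null(session$emg)) {
    as.numeric(detect_stim_onsets(session$emg, session$fs,
                                  session$trials$stim_onset))
  } else {
    session$trials$stim_onset
  }
  epochs <- epoch_session(eeg, session$fs, onsets, session$trials,
                          mask = rejection$mask)
  epochs <- downsample_epochs(epochs, target_fs)
  attr(epochs, "rejection") <- rejection
  epochs
}
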