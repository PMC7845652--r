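#' Session design: block/trial structure and timing
#'
#' Describes one recording session: nine blocks of 18 trials by default,
#' with each of the three stimulation intensities randomly assigned to
#' three blocks. Each trial consists of a ready cue, a stimulation interval
#' of random duration, and a fixed inter-trial period.
#'
#' @param n_blocks Number of blocks (default 9).
#' @param trials_per_block Trials in each block (default 18).
#' @param intensities Intensity labels to cycle over blocks (each must
#'   appear equally often); default `c("low", "medium", "high")`.
#' @param ready_lead Range (s) between ready cue and stimulation onset,
#'   default `c(2.6, 3.0)`.
#' @param stim_duration Range (s) of the stimulation interval, default
#'   `c(3.4, 3.8)`.
#' @param inter_trial Inter-trial period in s (default 3).
#' @param inter_block Break between blocks in s. The study protocol used
#'   breaks of about 150 s; the value is configurable (and typically
#'   compressed in simulations) because downstream stages use annotation
#'   timing, not file length.
#' @param fs Sampling rate in Hz (default 1000).
#' @param lead_in Quiet padding (s) before the first ready cue and after
#'   the last stimulation offset so that 8-s analysis epochs fit.
#'
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_blocks = 9L,
                           trials_per_block = 18L,
                           intensities = c("low", "medium", "high"),
                           ready_lead = c(2.6, 3.0),
                           stim_duration = c(3.4, 3.8),
                           inter_trial = 3,
                           inter_block = 150,
                           fs = 1000,
                           lead_in = 6) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1L || trials_per_block < 1L) {
    stopf("n_blocks and trials_per_block must be positive")
  }
  if (n_blocks %% length(intensities) != 0L) {
    stopf("n_blocks (%d) must be a multiple of the number of intensity labels (%d) so each appears equally often",
          n_blocks, length(intensities))
  }
  if (length(ready_lead) != 2L || any(ready_lead <= 0) || diff(ready_lead) < 0) {
    stopf("ready_lead must be an increasing positive range")
  }
  if (length(stim_duration) != 2L || any(stim_duration <= 0) ||
      diff(stim_duration) < 0) {
    stopf("stim_duration must be an increasing positive range")
  }
  if (inter_trial <= 0 || inter_block <= 0 || fs <= 0 || lead_in <= 0) {
    stopf("all durations and fs must be positive")
  }
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 intensities = intensities, ready_lead = ready_lead,
                 stim_duration = stim_duration, inter_trial = inter_trial,
                 inter_block = inter_block, fs = fs, lead_in = lead_in),
            class = "session_design")
}

#' Build the annotated event schedule of a session
#'
#' Lays out ready cues, stimulation onsets/offsets and block boundaries on
#' a common time axis. Stimulation durations and ready leads are drawn
#' uniformly from the design's ranges; the intensity-to-block assignment is
#' a seeded random permutation with each intensity appearing equally often.
#' All event times are rounded to the sample grid, and the schedule is
#' fully determined by `(design, seed)`.
#'
#' @param design A [session_design()] object.
#' @param seed Integer seed controlling the schedule randomness.
#'
#' @return An object of class `nmes_timeline`: a list with
#'   \describe{
#'     \item{trials}{data frame with one row per trial: `block`,
#'       `trial`, `intensity`, `ready_onset`, `stim_onset`, `stim_offset`
#'       (times in s).}
#'     \item{annotations}{data frame `(onset, label)` with labels
#'       `block_start/<k>`, `ready`, `stim_on/<intensity>`, `stim_off`.}
#'     \item{duration}{total recording duration in s.}
#'     \item{schedule}{the per-block intensity labels.}
#'   }
#' @export
build_timeline <- function(design, seed = 1L) {
  if (!inherits(design, "session_design")) {
    stopf("`design` must be a session_design object")
  }
  d <- design
  per <- d$n_blocks / length(d$intensities)
  with_seed(seed, {
    schedule <- sample(rep(d$intensities, per))
    snap <- function(t) round(t * d$fs) / d$fs
    rows <- vector("list", d$n_blocks * d$trials_per_block)
    ann <- list()
    t <- d$lead_in
    i <- 0L
    for (b in seq_len(d$n_blocks)) {
      ann[[length(ann) + 1L]] <-
        data.frame(onset = snap(t - 1), label = paste0("block_start/", b))
      for (tr in seq_len(d$trials_per_block)) {
        ready <- snap(t)
        stim_on <- snap(ready + runif(1, d$ready_lead[1], d$ready_lead[2]))
        stim_off <- snap(stim_on + runif(1, d$stim_duration[1], d$stim_duration[2]))
        i <- i + 1L
        rows[[i]] <- data.frame(block = b, trial = tr,
                                intensity = schedule[b],
                                ready_onset = ready, stim_onset = stim_on,
                                stim_offset = stim_off)
        ann[[length(ann) + 1L]] <- data.frame(
          onset = c(ready, stim_on, stim_off),
          label = c("ready", paste0("stim_on/", schedule[b]), "stim_off"))
        t <- stim_off + d$inter_trial
      }
      if (b < d$n_blocks) t <- t + d$inter_block
    }
    trials <- do.call(rbind, rows)
    annotations <- do.call(rbind, ann)
    annotations <- annotations[order(annotations$onset), , drop = FALSE]
    rownames(annotations) <- NULL
    structure(list(trials = trials, annotations = annotations,
                   duration = snap(t + d$lead_in), schedule = schedule),
              class = "nmes_timeline")
  })
}

# Reconstruct the per-trial table from raw (onset, label) annotations,
# e.g. after reading a session back from EDF+.
trials_from_annotations <- function(annotations) {
  lab <- annotations$label
  on_idx <- grep("^stim_on/", lab)
  off_idx <- which(lab == "stim_off")
  if (length(on_idx) != length(off_idx)) {
    stopf("unbalanced stim_on/stim_off annotations (%d vs %d)",
          length(on_idx), length(off_idx))
  }
  blk_idx <- grep("^block_start/", lab)
  blk_onsets <- annotations$onset[blk_idx]
  blk_id <- as.integer(sub("^block_start/", "", lab[blk_idx]))
  onsets <- annotations$onset[on_idx]
  block <- if (length(blk_idx)) {
    blk_id[findInterval(onsets, blk_onsets)]
  } else rep(1L, length(onsets))
  trial <- stats::ave(seq_along(onsets), block, FUN = seq_along)
  data.frame(block = block, trial = trial,
             intensity = sub("^stim_on/", "", lab[on_idx]),
             stim_onset = onsets,
             stim_offset = annotations$onset[off_idx])
}
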