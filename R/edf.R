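# Minimal EDF+ (continuous) writer/reader for session round-trips.
# 16-bit samples with per-signal physical scaling, one annotation signal
# holding time-stamped annotation lists (TALs) for the event markers.

edf_pad <- function(s, n) {
  s <- substr(s, 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

edf_num <- function(x, n) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > n) s <- substr(s, 1, n)
  edf_pad(s, n)
}

#' Write a session to an EDF+ file
#'
#' Stores the EEG and EMG channels as 16-bit signals in physical units of
#' microvolts (one-second data records, symmetric per-signal physical
#' range) and the event annotations in an `EDF Annotations` signal as
#' standard time-stamped annotation lists. The recording is zero-padded to
#' a whole number of records; the true sample count is recorded in the
#' recording-identification field and honoured by [read_session()].
#'
#' @param session An `nmes_session` (or compatible list with `eeg`, `emg`,
#'   `fs`, `annotations`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  eeg <- session$eeg
  emg <- session$emg
  fs <- session$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  sig <- cbind(eeg, if (!is.null(emg)) emg)
  labels <- colnames(sig)
  n <- nrow(sig)
  n_rec <- ceiling(n / fs)
  ns_data <- ncol(sig)

  # physical scaling per signal (symmetric range, 16-bit)
  pmax_v <- apply(sig, 2, function(x) max(1, max(abs(range(x)))) * 1.0001)
  dig_min <- -32768; dig_max <- 32767

  # annotation payload per record
  ann <- session$annotations
  if (is.null(ann)) ann <- data.frame(onset = numeric(0), label = character(0))
  nul <- as.raw(0)
  tal_raw <- function(onset, label) {
    c(charToRaw(sprintf("+%.4f\x14%s\x14", onset, label)), nul)
  }
  rec_of <- pmin(floor(ann$onset), n_rec - 1)
  rec_payload <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    ts <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), nul)
    ev <- which(rec_of == r - 1L)
    body <- if (length(ev)) {
      unlist(lapply(ev, function(i) tal_raw(ann$onset[i], ann$label[i])))
    } else raw(0)
    rec_payload[[r]] <- c(ts, body)
  }
  ann_bytes <- max(lengths(rec_payload)) + 2L
  ann_spr <- ceiling(ann_bytes / 2)        # samples (2 bytes each) per record

  ns <- ns_data + 1L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s, type = "bytes"),
                              eos = NULL)
  # fixed header
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(sprintf("Startdate 01-JAN-2026 nmeserd nsamples=%d", n), 80))
  wr("01.01.26"); wr("00.00.00")
  wr(edf_num(256 * (ns + 1L), 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_pad(as.character(ns), 4))
  # per-signal header fields
  for (l in labels) wr(edf_pad(l, 16)); wr(edf_pad("EDF Annotations", 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns_data)) wr(edf_pad("uV", 8)); wr(edf_pad("", 8))
  for (v in pmax_v) wr(edf_num(-v, 8)); wr(edf_num(-1, 8))
  for (v in pmax_v) wr(edf_num(v, 8)); wr(edf_num(1, 8))
  for (i in seq_len(ns)) wr(edf_num(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_num(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns_data)) wr(edf_num(fs, 8)); wr(edf_num(ann_spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  # data records
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * fs + 1L
    i1 <- min(n, r * fs)
    for (j in seq_len(ns_data)) {
      x <- numeric(fs)
      x[seq_len(i1 - i0 + 1L)] <- sig[i0:i1, j]
      d <- round((x + pmax_v[j]) / (2 * pmax_v[j]) * (dig_max - dig_min) + dig_min)
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
    raw_pl <- rec_payload[[r]]
    buf <- raw(2L * ann_spr)
    buf[seq_along(raw_pl)] <- raw_pl
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read a session from an EDF+ file
#'
#' Parses the header, 16-bit data records and the annotation signal
#' written by [write_session()] (or any continuous EDF+ file with one
#' annotation signal). EEG and EMG channels are separated by label; the
#' per-trial table is reconstructed from the `stim_on/...`, `stim_off` and
#' `block_start/...` annotations.
#'
#' @param path EDF+ file path.
#' @return An object of class `nmes_session` (without simulation ground
#'   truth).
#' @export
read_session <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stopf("not an EDF file (too short): %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8)                                   # version
  rd(80)                                  # patient
  recid <- rd(80)
  rd(8); rd(8)                            # date, time
  header_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("malformed EDF header: %s", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- trimws(fld(16))
  fld(80)
  fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)

  expected <- header_bytes + n_rec * sum(spr) * 2
  if (sz < expected) {
    stopf("truncated EDF file: %d bytes, expected %d", sz, expected)
  }
  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  out <- lapply(data_idx, function(j) numeric(n_rec * spr[j]))
  names(out) <- labels[data_idx]
  ann_raw <- list()
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      if (is_ann[j]) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, "raw", 2L * spr[j])
      } else {
        d <- readBin(con, "integer", spr[j], size = 2, endian = "little")
        k <- match(j, data_idx)
        scale <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
        out[[k]][((r - 1) * spr[j] + 1):(r * spr[j])] <-
          (d - dig_min[j]) * scale + phys_min[j]
      }
    }
  }
  # true sample count, if recorded by write_session
  n_true <- suppressWarnings(
    as.integer(sub(".*nsamples=([0-9]+).*", "\\1", recid)))
  fs <- spr[data_idx[1]] / rec_dur
  if (!is.na(n_true)) out <- lapply(out, function(x) x[seq_len(n_true)])

  # parse TALs: chunks are separated by NUL; "onset[\x15dur]\x14label\x14"
  ann <- do.call(rbind, lapply(ann_raw, function(b) {
    is0 <- b == as.raw(0)
    if (all(is0)) return(NULL)
    grp <- cumsum(is0)
    chunks <- vapply(split(b[!is0], grp[!is0]), rawToChar, "")
    rows <- lapply(chunks, function(ch) {
      if (!nzchar(ch)) return(NULL)
      parts <- strsplit(ch, "\x14", fixed = TRUE, useBytes = TRUE)[[1]]
      if (length(parts) < 2 || !nzchar(parts[2])) return(NULL)  # timestamp TAL
      onset <- as.numeric(sub("\x15.*", "", parts[1]))
      data.frame(onset = onset, label = parts[2])
    })
    do.call(rbind, rows)
  }))
  if (is.null(ann)) ann <- data.frame(onset = numeric(0), label = character(0))
  ann <- ann[order(ann$onset), , drop = FALSE]
  rownames(ann) <- NULL

  emg_lab <- grep("^EMG", names(out), value = TRUE)
  eeg_lab <- setdiff(names(out), emg_lab)
  eeg <- do.call(cbind, out[eeg_lab])
  emg <- if (length(emg_lab)) do.call(cbind, out[emg_lab]) else NULL
  trials <- if (any(grepl("^stim_on/", ann$label)))
    trials_from_annotations(ann) else NULL
  structure(list(eeg = eeg, emg = emg, fs = fs, annotations = ann,
                 trials = trials, design = NULL, ground_truth = NULL,
                 artifacts = NULL, intensities_mA = NULL),
            class = "nmes_session")
}
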