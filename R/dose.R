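# Dose-effect analysis: per-trial ERD series within each intensity, a
# session-wise linear regression of ERD on trial order with Pearson
# correlation, and block-wise regressions with a between-block reset
# statistic.

#' Single-trial ERD series for one intensity
#'
#' For each trial, band power is averaged over the stimulation interval
#' (0.5, 2.5) s at the ROI channels, then converted to percent change
#' using the intensity's grand-average baseline: the baseline power is
#' the mean over all of the intensity's trials of the (-2.5, -1.5) s
#' interval, so the trial series shares a common reference.
#'
#' @param epochs An `epoch_set` holding the pooled trials of one
#'   intensity, in acquisition order.
#' @param cfg A [tfr_config()].
#' @param band Band name in `cfg$bands` or numeric limits (Hz).
#' @return Numeric vector of per-trial ERD (percent), in acquisition
#'   order, with the trial metadata attached as attribute `"trials"`.
#' @export
single_trial_erd <- function(epochs, cfg = tfr_config(), band = "alpha") {
  ntr <- dim(epochs$data)[1]
  if (ntr < 2) stopf("need at least 2 trials")
  if (is.character(band)) band <- cfg$bands[[band]]
  roi <- intersect(cfg$roi, epochs$channels)
  if (!length(roi)) stopf("no ROI channels present")
  fsub <- cfg$freqs[cfg$freqs >= band[1] & cfg$freqs <= band[2]]
  if (!length(fsub)) stopf("band has no bins among the analysis frequencies")
  cfg_band <- cfg
  cfg_band$freqs <- fsub
  tfr <- morlet_tfr(epochs, cfg_band, channels = roi, keep_trials = TRUE)
  tsel_stim <- tfr$time >= cfg$stim_interval[1] & tfr$time <= cfg$stim_interval[2]
  tsel_base <- tfr$time >= cfg$baseline[1] & tfr$time <= cfg$baseline[2]
  # per trial: band power averaged over bins, interval and ROI channels
  collapse <- function(tsel) {
    v <- apply(tfr$power[, , tsel, , drop = FALSE], c(1, 4), mean)
    roi_average(v, roi, mask = epochs$mask[, roi, drop = FALSE])
  }
  p_stim <- collapse(tsel_stim)
  base <- mean(collapse(tsel_base))
  if (base <= 0) stopf("zero grand-average baseline power")
  series <- (p_stim - base) / base * 100
  structure(as.numeric(series), trials = epochs$trials)
}

#' Linear regression of an ERD series on trial order
#'
#' Ordinary least squares of the per-trial ERD values on the 1-based
#' trial index, with Pearson's correlation coefficient and its two-sided
#' p-value. A positive slope on a negative-ERD series means the
#' desynchronization weakens over trials (habituation); a negative slope
#' means it deepens (facilitation).
#'
#' @param erd_series Numeric vector of per-trial ERD (percent), in
#'   acquisition order.
#' @param band,intensity,scope Optional labels carried into the result.
#' @param alpha Significance level of the correlation test (default 0.05).
#' @return Object of class `dose_regression`: list with `slope`
#'   (percent/trial), `intercept`, `pearson_r`, `p_value`, `significant`,
#'   `n`, `r_defined`, plus the labels.
#' @export
trial_regression <- function(erd_series, band = NA_character_,
                             intensity = NA_character_,
                             scope = "session", alpha = 0.05) {
  y <- as.numeric(erd_series)
  if (length(y) < 3) stopf("need at least 3 trials for a regression")
  if (any(!is.finite(y))) stopf("ERD series contains non-finite values")
  x <- seq_along(y)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (sd(y) == 0) {
    r <- NA_real_; p <- NA_real_; defined <- FALSE
  } else {
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value; defined <- TRUE
  }
  structure(list(band = band, intensity = intensity, scope = scope,
                 n = length(y), slope = slope, intercept = intercept,
                 pearson_r = r, p_value = p, r_defined = defined,
                 significant = defined && p < alpha,
                 erd_series = y),
            class = "dose_regression")
}

#' @export
print.dose_regression <- function(x, ...) {
  cat(sprintf("<dose_regression> %s%s n=%d: slope=%.3f %%/trial, r=%s, p=%s\n",
              x$scope,
              if (!is.na(x$band)) sprintf(" [%s/%s]", x$band, x$intensity) else "",
              x$n, x$slope,
              if (x$r_defined) sprintf("%.3f", x$pearson_r) else "undefined",
              if (x$r_defined) format.pval(x$p_value, digits = 3) else "-"))
  invisible(x)
}

#' Block-wise regressions and between-block reset statistics
#'
#' Fits one regression of ERD on within-block trial order per block and
#' computes the reset statistic between consecutive blocks: the ERD of
#' the first trial of block k+1 minus the ERD of the last trial of
#' block k. Within-block ERD attenuation with a between-block reset shows
#' up as positive block slopes (ERD decaying toward zero) together with
#' negative reset differences (the new block starting with a larger,
#' more negative ERD).
#'
#' @param erd_series Per-trial ERD (percent) in acquisition order.
#' @param blocks Block index per trial (same length as the series).
#' @param ... Labels passed to [trial_regression()].
#' @return List with `regressions` (one `dose_regression` per block with
#'   at least 3 trials; shorter blocks are skipped with a warning) and
#'   `resets` (numeric, one per consecutive block pair).
#' @export
blockwise_regressions <- function(erd_series, blocks, ...) {
  y <- as.numeric(erd_series)
  stopifnot(length(y) == length(blocks))
  ub <- unique(blocks)
  regs <- list()
  for (b in ub) {
    sel <- blocks == b
    if (sum(sel) < 3) {
      warnf("block %s has fewer than 3 trials; skipped", b)
      next
    }
    regs[[as.character(b)]] <- trial_regression(y[sel], scope = paste0("block ", b), ...)
  }
  resets <- numeric(0)
  if (length(ub) > 1) {
    for (i in seq_len(length(ub) - 1)) {
      last_k <- tail(y[blocks == ub[i]], 1)
      first_k1 <- head(y[blocks == ub[i + 1]], 1)
      resets[i] <- first_k1 - last_k
    }
  }
  list(regressions = regs, resets = resets)
}

#' Dose-effect table across bands and intensities
#'
#' Convenience wrapper: computes single-trial ERD series and the
#' session-wise and block-wise regressions for every band x intensity
#' combination of a pooled epoch list.
#'
#' @param pooled Named list of `epoch_set` per intensity, from
#'   [pool_by_intensity()].
#' @param cfg A [tfr_config()].
#' @return Data frame with one row per band x intensity x scope: `n`,
#'   `slope`, `intercept`, `pearson_r`, `p_value`, `significant`.
#' @export
dose_effect_table <- function(pooled, cfg = tfr_config()) {
  rows <- list()
  for (band in names(cfg$bands)) {
    for (lab in names(pooled)) {
      series <- single_trial_erd(pooled[[lab]], cfg, band)
      trials <- attr(series, "trials")
      reg <- trial_regression(series, band, lab)
      bw <- blockwise_regressions(series, trials$block, band = band,
                                  intensity = lab)
      for (r in c(list(reg), unname(bw$regressions))) {
        rows[[length(rows) + 1L]] <- data.frame(
          band = band, intensity = lab, scope = r$scope, n = r$n,
          slope = r$slope, intercept = r$intercept,
          pearson_r = r$pearson_r, p_value = r$p_value,
          significant = r$significant)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
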