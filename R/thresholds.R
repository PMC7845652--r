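#' Stimulation-current thresholds
#'
#' Bundle of the three individually calibrated NMES currents: the sensory
#' threshold (first tingling of the forearm), the motor threshold (first
#' finger twitch) and the functional threshold (complete wrist extension).
#'
#' @param sth Sensory threshold in mA.
#' @param mth Motor threshold in mA.
#' @param fth Functional threshold in mA.
#'
#' @return An object of class `intensity_thresholds`.
#' @export
#' @examples
#' intensity_thresholds(sth = 4, mth = 10, fth = 14)
intensity_thresholds <- function(sth, mth, fth) {
  for (v in c(sth, mth, fth)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stopf("thresholds must be single finite numbers")
    }
  }
  if (!(0 < sth && sth < mth && mth <= fth)) {
    stopf("invalid threshold ordering: need 0 < sth < mth <= fth (got sth=%g, mth=%g, fth=%g)",
          sth, mth, fth)
  }
  structure(list(sth = sth, mth = mth, fth = fth),
            class = "intensity_thresholds")
}

#' Compute the three stimulation intensities from the thresholds
#'
#' Low intensity sits one third of the way between the sensory and motor
#' thresholds, medium intensity two thirds of the way, and high intensity
#' equals the functional threshold:
#' low = (MTh - STh) x 0.33 + STh, medium = (MTh - STh) x 0.66 + STh,
#' high = FTh.
#'
#' @param thresholds An [intensity_thresholds()] object.
#'
#' @return Named numeric vector with elements `low`, `medium`, `high` (mA).
#' @export
#' @examples
#' compute_intensities(intensity_thresholds(4, 10, 14))
compute_intensities <- function(thresholds) {
  if (!inherits(thresholds, "intensity_thresholds")) {
    stopf("`thresholds` must be created with intensity_thresholds()")
  }
  d <- thresholds$mth - thresholds$sth
  c(low    = d * 0.33 + thresholds$sth,
    medium = d * 0.66 + thresholds$sth,
    high   = thresholds$fth)
}
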