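#' Summary features of one ROI temperature signal
#'
#' Computes the four descriptive statistics used per thermal signal: the
#' mean and sample standard deviation of the temperature, and the mean and
#' sample standard deviation of its first derivative.  The derivative is the
#' forward first difference scaled by the frame rate, so `DMean` and `DStd`
#' are in degrees C per second.
#'
#' @param signal numeric temperature signal, degrees C (already cleaned).
#' @param fs frame rate, Hz.
#' @return named numeric vector `c(Mean, Std, DMean, DStd)`.
#' @examples
#' thermal_features(c(33, 33.1, 33.2), fs = 5)
#' @export
thermal_features <- function(signal, fs) {
  check_scalar(fs, "fs", 0, Inf, strict = TRUE)
  if (length(signal) < 2L)
    stop_ts("need at least 2 samples for thermal features",
            class = "insufficient_data")
  if (any(!is.finite(signal)))
    stop_ts("non-finite temperature in signal", class = "insufficient_data")
  d <- diff(signal) * fs
  c(Mean = mean(signal), Std = sd(signal), DMean = mean(d), DStd = sd(d))
}

# 56 named thermal features for one session's ROISignalSet.
thermal_feature_row <- function(signals, fs) {
  stopifnot(is.list(signals), length(signals) == 14L)
  out <- numeric(0)
  for (nm in roi_names()) {
    f <- thermal_features(signals[[nm]], fs)
    names(f) <- paste(roi_label(nm), names(f))
    out <- c(out, f)
  }
  out
}
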