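# Heart-rate variability and respiratory features: RR correction, 4 Hz
# HRV series, 10 HRV features, respiratory dominant frequency.

#' RR interbeat-interval series
#'
#' @param rr RR intervals, ms; or `NULL` to derive from `beat_times`.
#' @param beat_times beat (R-peak) times, s.  When both are given they must
#'   be mutually consistent to 1 ms; when only beat times are given, RR =
#'   successive differences and the series starts at the second beat.
#' @return object of class `rr_series` with `rr` (ms), `beat_times` (s),
#'   `flagged` (logical artifact flags, all `FALSE` initially).
#' @export
rr_series <- function(rr = NULL, beat_times = NULL) {
  if (is.null(rr)) {
    if (length(beat_times) < 2L)
      stop_ts("need at least 2 beat times", class = "invalid_config")
    rr <- diff(beat_times) * 1000
    beat_times <- beat_times[-1]
  }
  if (is.null(beat_times)) beat_times <- cumsum(rr) / 1000
  if (any(rr <= 0)) stop_ts("RR intervals must be positive", class = "invalid_config")
  if (any(diff(beat_times) <= 0))
    stop_ts("beat times must be strictly increasing", class = "invalid_config")
  gaps <- diff(beat_times) * 1000 - rr[-1]
  if (max(abs(gaps)) > 1)
    stop_ts("beat times inconsistent with RR values (max gap %.2f ms)",
            max(abs(gaps)), class = "invalid_config")
  structure(list(rr = rr, beat_times = beat_times,
                 flagged = rep(FALSE, length(rr))),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.0f ms (%d flagged)\n",
              length(x$rr), diff(range(x$beat_times)), mean(x$rr),
              sum(x$flagged)))
  invisible(x)
}

#' Detect and correct RR artefacts by cubic-spline interpolation
#'
#' Beats are flagged as artefacts when they deviate from the local median
#' (11-beat window) by more than `rel_tol` times that median, or when they
#' jump by more than that amount from both neighbouring beats (which
#' catches alternating artefacts that drag the local median along).
#' Flagged beats are replaced by cubic-spline interpolation over the
#' neighbouring valid beats; beat times are rebuilt from the corrected
#' intervals so times and values stay consistent.
#'
#' @param rr an [rr_series()].
#' @param rel_tol relative deviation threshold (default 0.3).
#' @param window local-median window, beats (odd).
#' @return corrected `rr_series` with `flagged` marking replaced beats.
#' @export
correct_rr <- function(rr, rel_tol = 0.3, window = 11L) {
  x <- rr$rr
  n <- length(x)
  if (n < 4L) stop_ts("need at least 4 beats", class = "insufficient_data")
  locmed <- runmed(x, min(window, n - (1 - n %% 2L)), endrule = "median")
  d_prev <- abs(x - c(x[1], x[-n]))
  d_next <- abs(x - c(x[-1], x[n]))
  bad <- abs(x - locmed) > rel_tol * locmed |
    (d_prev > rel_tol * locmed & d_next > rel_tol * locmed)
  if (mean(bad) > 0.5)
    stop_ts("more than half of the beats are artefacts; series unusable",
            class = "unusable_series")
  out <- x
  if (any(bad)) {
    good <- which(!bad)
    sf <- splinefun(good, x[good], method = "natural")
    out[bad] <- sf(which(bad))
  }
  t0 <- rr$beat_times[1] - out[1] / 1000
  structure(list(rr = out, beat_times = t0 + cumsum(out) / 1000,
                 flagged = bad),
            class = "rr_series")
}

#' Uniform 4 Hz heart-rate-variability series from the tachogram
#'
#' Cubic-spline interpolation of the RR tachogram over beat times, sampled
#' on a uniform grid covering the session.  With `unit = "bpm"` the series
#' is instantaneous heart rate 60000/RR.
#'
#' @param rr an [rr_series()] (artefact-corrected).
#' @param duration_s session duration; the grid is
#'   `seq(0, duration_s - 1/fs, by = 1/fs)`.
#' @param fs output rate, Hz.
#' @param unit `"bpm"` (instantaneous heart rate, default) or `"ms"` (RR).
#' @param max_gap_s largest tolerated beat gap / edge coverage gap.
#' @return object of class `hrv_series`: `time_s`, `values`, `fs`, `unit`.
#' @export
rr_to_hrv_series <- function(rr, duration_s, fs = 4, unit = c("bpm", "ms"),
                             max_gap_s = 3) {
  unit <- match.arg(unit)
  tb <- rr$beat_times
  gaps <- c(tb[1], diff(tb), duration_s - tb[length(tb)])
  if (max(gaps) > max_gap_s)
    stop_ts("session coverage gap of %.2f s exceeds %g s", max(gaps), max_gap_s,
            class = "coverage_gap")
  grid <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sf <- splinefun(tb, rr$rr, method = "natural")
  v <- sf(grid)
  if (unit == "bpm") v <- 60000 / v
  structure(list(time_s = grid, values = v, fs = fs, unit = unit),
            class = "hrv_series")
}

#' Time-domain HRV features
#'
#' `mean HRV` and `std HRV` are computed on the uniform 4 Hz series (in its
#' unit); `RMSSD` and `pNN50` on the corrected RR intervals: RMSSD is the
#' root mean square of successive differences (ms) and pNN50 the percentage
#' of successive differences exceeding 50 ms in magnitude.
#'
#' @param rr an [rr_series()].
#' @param hrv an [rr_to_hrv_series()] result.
#' @return named vector `c("mean HRV", "std HRV", RMSSD, pNN50)`.
#' @export
hrv_time_features <- function(rr, hrv) {
  if (length(rr$rr) < 3L)
    stop_ts("need at least 3 beats", class = "insufficient_data")
  d <- diff(rr$rr)
  c("mean HRV" = mean(hrv$values), "std HRV" = sd(hrv$values),
    RMSSD = sqrt(mean(d^2)), pNN50 = 100 * mean(abs(d) > 50))
}

#' Frequency-domain HRV features
#'
#' Welch spectrum of the linearly detrended 4 Hz HRV series; `LF` and `HF`
#' are the 0.04-0.15 Hz and 0.15-0.40 Hz band powers expressed as
#' percentages of the total 0.04-0.40 Hz power, and `LF/HF` their ratio.
#'
#' @param hrv an [rr_to_hrv_series()] result (at least 120 s).
#' @param window_s Welch segment length, s.
#' @return named vector `c(LF, HF, "LF/HF")`.
#' @export
hrv_freq_features <- function(hrv, window_s = 64) {
  if (length(hrv$values) < 120 * hrv$fs)
    stop_ts("need at least 120 s of HRV series", class = "insufficient_data")
  psd <- welch_psd(hrv$values, hrv$fs, window_s = window_s, overlap = 0.5,
                   detrend = "linear")
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15 + 1e-12, 0.40)
  tot <- band_power(psd, 0.04, 0.40)
  c(LF = 100 * lf / tot, HF = 100 * hf / tot, "LF/HF" = lf / hf)
}

#' Nonlinear HRV features: Poincare axes and sample entropy
#'
#' `SD1`/`SD2` are the minor/major axes of the ellipse fitted to the
#' Poincare plot of successive RR pairs.  `SD1` is computed from the
#' uncentered mean square of successive differences (whose mean is ~0 for
#' stationary tachograms), so the identity SD1 = RMSSD/sqrt(2) holds
#' exactly for every series; `SD2` uses the population SD of the series.
#' `SampEn` uses embedding dimension `m = 2`, tolerance `r = 0.2 * SD(RR)`
#' and the Chebyshev distance, excluding self-matches.
#'
#' @param rr an [rr_series()].
#' @param m,r_frac sample-entropy embedding dimension and tolerance
#'   fraction of the series SD.
#' @return named vector `c(SD1, SD2, SampEn)`.
#' @export
hrv_nonlinear_features <- function(rr, m = 2L, r_frac = 0.2) {
  x <- rr$rr
  if (length(x) < 10L)
    stop_ts("need at least 10 beats for Poincare axes", class = "insufficient_data")
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  sd1 <- sqrt(mean(diff(x)^2)) / sqrt(2)
  sd2sq <- 2 * pop_sd(x)^2 - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  c(SD1 = sd1, SD2 = sd2, SampEn = sample_entropy(x, m = m, r_frac = r_frac))
}

#' Sample entropy of a series
#'
#' Negative log of the conditional probability that template vectors of
#' length `m` matching within tolerance `r` (Chebyshev distance, no
#' self-matches) still match at length `m + 1`.
#'
#' @param x numeric series (50 or more points recommended).
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of the series SD (population).
#' @return nonnegative scalar; 0 for a constant series by convention.
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 2L) stop_ts("series too short for SampEn", class = "insufficient_data")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(0)
  r <- r_frac * s
  nt <- n - m                       # template count for both lengths
  D <- abs(outer(x, x, "-"))
  idx <- seq_len(nt)
  # Chebyshev distance between templates of length m (and m+1) via running max
  Dm <- D[idx, idx, drop = FALSE]
  for (k in seq_len(m - 1)) Dm <- pmax(Dm, D[idx + k, idx + k, drop = FALSE])
  Dm1 <- pmax(Dm, D[idx + m, idx + m, drop = FALSE])
  upper <- upper.tri(Dm)
  B <- sum(Dm[upper] <= r)
  A <- sum(Dm1[upper] <= r)
  if (B == 0L) return(0)
  if (A == 0L) return(Inf)
  -log(A / B)
}

#' Mean respiratory frequency
#'
#' Dominant spectral peak of the detrended respiration signal within the
#' physiological band 0.05-1 Hz (Welch spectrum).  The signal is block-mean
#' decimated to about 4 Hz first.
#'
#' @param resp respiration signal (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi search band, Hz.
#' @param window_s Welch segment length, s.
#' @return respiratory frequency, Hz.
#' @export
resp_frequency <- function(resp, fs, f_lo = 0.05, f_hi = 1, window_s = 64) {
  if (length(resp) < 60 * fs)
    stop_ts("need at least 60 s of respiration", class = "insufficient_data")
  fac <- max(1L, floor(fs / 4))
  x <- decimate_mean(resp, fac)
  psd <- welch_psd(x, fs / fac, window_s = window_s, overlap = 0.5,
                   detrend = "linear")
  psd_peak(psd, f_lo, f_hi)
}

# The 11 cardiorespiratory feature-table columns for one session.
cardioresp_feature_row <- function(rr, resp, resp_fs, duration_s) {
  rrc <- correct_rr(rr)
  hrv <- rr_to_hrv_series(rrc, duration_s = duration_s)
  c(hrv_time_features(rrc, hrv)[c("mean HRV", "std HRV", "RMSSD", "pNN50")],
    hrv_freq_features(hrv),
    hrv_nonlinear_features(rrc),
    "RESP freq" = resp_frequency(resp, resp_fs))
}
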