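#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann taper.  Used for the
#' skin-conductance sympathetic band power, the HRV band powers and the
#' respiratory dominant frequency, where a smoothed, low-variance spectrum
#' of a short physiological record is needed.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between consecutive segments.
#' @param detrend `"mean"` removes the segment mean, `"linear"` a
#'   least-squares line, `"none"` nothing.
#' @return data.frame with columns `freq` (Hz) and `psd` (signal
#'   units squared per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, window_s = 64, overlap = 0.5,
                      detrend = c("linear", "mean", "none")) {
  detrend <- match.arg(detrend)
  check_scalar(fs, "fs", 0, Inf, strict = TRUE)
  L <- round(window_s * fs)
  if (L < 8) stop_ts("Welch segment too short (%d samples)", L, class = "invalid_config")
  n <- length(x)
  step <- max(1L, floor(L * (1 - overlap)))
  if (n < L + step)
    stop_ts("signal shorter than two Welch segments (%d < %d)", n, L + step,
            class = "insufficient_data")
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  U <- sum(w^2)
  idx0 <- seq_len(L)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s + idx0 - 1L]
    seg <- switch(detrend,
      none = seg,
      mean = seg - mean(seg),
      linear = {
        tt <- idx0 - (L + 1) / 2
        seg - mean(seg) - (sum(seg * tt) / sum(tt^2)) * tt
      })
    acc <- acc + Mod(fft(seg * w))^2
  }
  acc <- acc / length(starts)
  nf <- floor(L / 2) + 1L
  psd <- acc[seq_len(nf)] / (fs * U)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1L) * fs / L, psd = psd * dbl)
}

#' Integrated band power from a PSD
#'
#' Rectangle-rule integral of the one-sided PSD over `[f_lo, f_hi]`
#' (inclusive bin centres).
#'
#' @param psd data.frame as returned by [welch_psd()].
#' @param f_lo,f_hi band edges, Hz.
#' @return power in signal units squared.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  df <- psd$freq[2] - psd$freq[1]
  keep <- psd$freq >= f_lo & psd$freq <= f_hi
  sum(psd$psd[keep]) * df
}

#' Dominant spectral peak within a band
#' @param psd data.frame from [welch_psd()].
#' @param f_lo,f_hi band edges, Hz.
#' @param min_ratio peak must exceed `min_ratio` times the median in-band
#'   PSD, otherwise a `no_peak` error is thrown.
#' @return frequency of the in-band maximum, Hz.
#' @keywords internal
psd_peak <- function(psd, f_lo, f_hi, min_ratio = 5) {
  inb <- psd[psd$freq >= f_lo & psd$freq <= f_hi, ]
  if (nrow(inb) == 0L) stop_ts("no spectral bins in band", class = "no_peak")
  i <- which.max(inb$psd)
  if (inb$psd[i] < min_ratio * (median(inb$psd) + .Machine$double.eps))
    stop_ts("no spectral peak above the noise floor in [%g, %g] Hz",
            f_lo, f_hi, class = "no_peak")
  inb$freq[i]
}

# Block-mean decimation (anti-aliasing by averaging) from fs to fs/factor.
decimate_mean <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(x)
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
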