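# Electrodermal activity: sparsity-regularised tonic/phasic decomposition
# and the 8 skin-conductance features.

# Discrete Bateman (biexponential) impulse response as an exact
# second-order recursive filter.  Kernel h[k] = c * (a^k - b^k), k >= 0,
# a = exp(-dt/tau_decay), b = exp(-dt/tau_rise), scaled so max(h) = 1:
# a unit driver impulse yields a phasic bump of unit amplitude (uS).
bateman_coefs <- function(fs, tau_rise = 0.7, tau_decay = 2.0) {
  dt <- 1 / fs
  a <- exp(-dt / tau_decay); b <- exp(-dt / tau_rise)
  # discrete peak of a^k - b^k
  kpk <- log(log(b) / log(a)) / (log(a) - log(b))
  pk <- max(a^floor(kpk) - b^floor(kpk), a^ceiling(kpk) - b^ceiling(kpk))
  list(a = a, b = b, scale = 1 / pk)
}

bateman_apply <- function(p, bc) {
  u <- bc$scale * (bc$a - bc$b) * c(0, p[-length(p)])
  as.numeric(filter(u, c(bc$a + bc$b, -bc$a * bc$b), method = "recursive"))
}

# Adjoint of the (lower-triangular Toeplitz) convolution operator.
bateman_adjoint <- function(r, bc) rev(bateman_apply(rev(r), bc))

tonic_basis <- function(n, fs, knot_s = 10) {
  tt <- (seq_len(n) - 1) / fs
  dur <- tt[n]
  inner <- seq(0, dur + knot_s, by = knot_s)
  knots <- c(rep(inner[1], 3), inner, rep(inner[length(inner)], 3))
  B <- splines::splineDesign(knots, tt, ord = 4)
  drift <- cbind(1, tt / max(tt[n], 1))
  list(B = B, drift = drift)
}

#' Decompose skin conductance into tonic, phasic, driver and noise
#'
#' Solves a convex program modelling the skin-conductance signal as the sum
#' of (i) a sparse nonnegative sudomotor driver convolved with a Bateman
#' biexponential response (the phasic component), (ii) a smooth tonic
#' component (cubic B-spline plus linear drift), and (iii) residual noise:
#'
#'   minimise 0.5 * ||y - M p - B l - C d||^2 + alpha * sum(p)
#'            + 0.5 * gamma * ||l||^2   subject to  p >= 0
#'
#' optimised by accelerated proximal gradient (FISTA) with an exact
#' recursive-filter implementation of the response operator `M`.  The
#' signal is block-mean decimated to `fs_model` before solving; the
#' returned components live at `fs_model` and reconstruct the decimated
#' input exactly (`tonic + phasic + noise`).
#'
#' @param signal skin conductance, microsiemens.
#' @param fs sampling rate of `signal`, Hz.
#' @param fs_model model rate for the optimisation, Hz (default 25; `fs`
#'   must be an integer multiple, or already at most `fs_model`).
#' @param tau_rise,tau_decay Bateman response time constants, s.
#' @param knot_s tonic spline knot spacing, s.
#' @param alpha l1 penalty on the driver (sparsity), per sample.
#' @param gamma l2 penalty on the tonic spline coefficients.
#' @param maxit,tol FISTA iteration cap and relative objective tolerance.
#' @return object of class `eda_decomposition`: `time_s`, `fs`, `tonic`,
#'   `phasic`, `driver`, `noise`, `objective`, `iterations`.
#' @export
decompose_eda <- function(signal, fs, fs_model = 25, tau_rise = 0.7,
                          tau_decay = 2.0, knot_s = 10, alpha = 0.05,
                          gamma = 1e-2, maxit = 1000L, tol = 1e-9) {
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop_ts("skin conductance must be finite and positive", class = "invalid_config")
  if (fs > fs_model) {
    fac <- fs / fs_model
    if (abs(fac - round(fac)) > 1e-9)
      stop_ts("fs must be an integer multiple of fs_model", class = "invalid_config")
    y <- decimate_mean(signal, round(fac))
  } else { y <- as.numeric(signal); fs_model <- fs }
  n <- length(y)
  if (n < 10 * fs_model)
    stop_ts("need at least 10 s of signal", class = "insufficient_data")

  bc <- bateman_coefs(fs_model, tau_rise, tau_decay)
  tb <- tonic_basis(n, fs_model, knot_s)
  B <- tb$B; C <- tb$drift
  nb <- ncol(B); nc <- ncol(C)

  model_apply <- function(p, l, d) bateman_apply(p, bc) + B %*% l + C %*% d

  # Lipschitz constant of the smooth part via power iteration.
  v <- list(p = rnorm(n), l = rnorm(nb), d = rnorm(nc))
  nv <- sqrt(sum(v$p^2) + sum(v$l^2) + sum(v$d^2))
  v <- lapply(v, function(z) z / nv)
  L <- 1
  for (it in 1:30) {
    w <- model_apply(v$p, v$l, v$d)
    hv <- list(p = bateman_adjoint(w, bc),
               l = as.numeric(crossprod(B, w)) + gamma * v$l,
               d = as.numeric(crossprod(C, w)))
    L <- sqrt(sum(hv$p^2) + sum(hv$l^2) + sum(hv$d^2))
    v <- lapply(hv, function(z) z / L)
  }
  step <- 1 / (1.05 * L)

  obj <- function(p, l, d, r) 0.5 * sum(r^2) + alpha * sum(p) +
    0.5 * gamma * sum(l^2)

  p <- numeric(n); l <- numeric(nb); d <- c(mean(y), 0)
  zp <- p; zl <- l; zd <- d
  tk <- 1
  r <- y - model_apply(p, l, d)
  J_prev <- obj(p, l, d, r)
  converged <- FALSE
  iterations <- 0L
  # stationarity violation on the active driver set (0 at the optimum,
  # measured relative to the sparsity penalty alpha)
  kkt_gap <- function(p) {
    r <- y - model_apply(p, l, d)
    g <- abs(pmin(bateman_adjoint(r, bc) - alpha, 0) * (p > 0))
    max(g, 0)
  }
  hard_cap <- 3L * maxit
  while (!converged && iterations < hard_cap) {
    for (it in seq_len(maxit)) {
      rz <- y - model_apply(zp, zl, zd)
      gp <- -bateman_adjoint(rz, bc)
      gl <- -as.numeric(crossprod(B, rz)) + gamma * zl
      gd <- -as.numeric(crossprod(C, rz))
      p_new <- pmax(0, zp - step * gp - step * alpha)
      l_new <- zl - step * gl
      d_new <- zd - step * gd
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      mom <- (tk - 1) / t_new
      zp <- p_new + mom * (p_new - p)
      zl <- l_new + mom * (l_new - l)
      zd <- d_new + mom * (d_new - d)
      p <- p_new; l <- l_new; d <- d_new; tk <- t_new
      iterations <- iterations + 1L
      if (it %% 25L == 0L || it == maxit) {
        r <- y - model_apply(p, l, d)
        J <- obj(p, l, d, r)
        if (J > J_prev) { tk <- 1; zp <- p; zl <- l; zd <- d }  # restart
        if (abs(J_prev - J) <= tol * max(1, abs(J_prev))) {
          converged <- TRUE
          break
        }
        J_prev <- J
      }
    }
    if (!converged && kkt_gap(p) <= 0.5 * alpha) break
  }
  if (!converged && kkt_gap(p) > 0.5 * alpha)
    stop_ts("EDA decomposition did not converge in %d iterations (gap %.3g)",
            iterations, kkt_gap(p), class = "decomposition_error")
  phasic <- bateman_apply(p, bc)
  tonic <- as.numeric(B %*% l + C %*% d)
  structure(list(time_s = (seq_len(n) - 1) / fs_model, fs = fs_model,
                 tonic = tonic, phasic = phasic, driver = p,
                 noise = y - tonic - phasic,
                 objective = obj(p, l, d, y - tonic - phasic),
                 iterations = iterations),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<eda_decomposition> %d samples @ %g Hz; tonic %.2f uS, ",
                     "driver mass %.3f, noise SD %.4f uS (%d iterations)\n"),
              length(x$tonic), x$fs, mean(x$tonic), sum(x$driver),
              sd(x$noise), x$iterations))
  invisible(x)
}

#' Discrete sudomotor events from the decomposition driver
#'
#' Groups contiguous runs of positive driver mass into events; the event
#' time is the driver maximum within the run and the amplitude the run's
#' summed driver (approximately the response amplitude in microsiemens).
#'
#' @param decomp an [decompose_eda()] result.
#' @param min_amplitude smallest event amplitude to keep, microsiemens.
#' @param eps driver floor below which samples count as zero.
#' @return data.frame with `time_s` and `amplitude`, time-ordered.
#' @export
driver_events <- function(decomp, min_amplitude = 0.05, eps = 1e-3) {
  on <- decomp$driver > eps
  if (!any(on)) return(data.frame(time_s = numeric(0), amplitude = numeric(0)))
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  ev <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    c(time = decomp$time_s[i[which.max(decomp$driver[i])]],
      amp = sum(decomp$driver[i]))
  })
  ev <- do.call(rbind, ev)
  out <- data.frame(time_s = ev[, 1], amplitude = ev[, 2])
  out[out$amplitude >= min_amplitude, , drop = FALSE]
}

#' Detect skin-conductance response peaks in the phasic component
#'
#' Local maxima of the phasic signal with amplitude at or above
#' `min_amplitude`.
#'
#' @param phasic phasic component, microsiemens.
#' @param fs sampling rate, Hz.
#' @param min_amplitude peak threshold, microsiemens.
#' @return data.frame with `time_s`, `amplitude` (strictly increasing times).
#' @export
detect_scr_peaks <- function(phasic, fs, min_amplitude = 0.01) {
  n <- length(phasic)
  if (n < 3L) return(data.frame(time_s = numeric(0), amplitude = numeric(0)))
  i <- 2:(n - 1)
  is_pk <- phasic[i] > phasic[i - 1] & phasic[i] >= phasic[i + 1] &
    phasic[i] >= min_amplitude
  idx <- i[is_pk]
  data.frame(time_s = (idx - 1) / fs, amplitude = phasic[idx])
}

#' The 8 electrodermal features of one session
#'
#' Tonic statistics (`TonicMean`, `TonicStd`) are computed per
#' non-overlapping 20 s window and averaged across windows; phasic
#' statistics (`PksMax`, `PhasicMean`, `PhasicStd`, `NPks`, `PksSum`) per
#' non-overlapping 5 s window and averaged; windows without a peak
#' contribute zero to the peak statistics.  `EDAsymp` is the integrated
#' Welch power of the raw skin-conductance signal in the sympathetic band
#' 0.04-0.25 Hz over the whole session.
#'
#' @param decomp an [decompose_eda()] result.
#' @param min_amplitude SCR peak threshold, microsiemens.
#' @param tonic_window_s,phasic_window_s window lengths, seconds.
#' @return named numeric vector of the 8 features.
#' @export
eda_features <- function(decomp, min_amplitude = 0.01,
                         tonic_window_s = 20, phasic_window_s = 5) {
  fs <- decomp$fs
  n <- length(decomp$tonic)
  dur <- n / fs
  if (dur < tonic_window_s)
    stop_ts("session shorter than one %g s window", tonic_window_s,
            class = "insufficient_data")
  win_stats <- function(x, w_s, f) {
    w <- round(w_s * fs)
    k <- floor(length(x) / w)
    vapply(seq_len(k), function(i) f(x[((i - 1) * w + 1):(i * w)]), 1.0)
  }
  peaks <- detect_scr_peaks(decomp$phasic, fs, min_amplitude)
  w <- phasic_window_s
  k5 <- floor(dur / w)
  pk_win <- findInterval(peaks$time_s, seq(0, k5 * w, by = w),
                         rightmost.closed = FALSE)
  per_win <- function(f, empty = 0) {
    vapply(seq_len(k5), function(i) {
      a <- peaks$amplitude[pk_win == i]
      if (length(a) == 0L) empty else f(a)
    }, 1.0)
  }
  raw <- decomp$tonic + decomp$phasic + decomp$noise
  psd <- welch_psd(raw, fs, window_s = min(60, dur / 2), overlap = 0.5,
                   detrend = "mean")
  c(TonicMean = mean(win_stats(decomp$tonic, tonic_window_s, mean)),
    TonicStd = mean(win_stats(decomp$tonic, tonic_window_s, sd)),
    PksMax = mean(per_win(max)),
    PhasicMean = mean(win_stats(decomp$phasic, w, mean)),
    PhasicStd = mean(win_stats(decomp$phasic, w, sd)),
    NPks = mean(per_win(length)),
    PksSum = mean(per_win(sum)),
    EDAsymp = band_power(psd, 0.04, 0.25))
}
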