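# Seeded synthetic cohorts: thermal frame stacks, electrodermal, cardiac
# and respiratory signals with known (planted) condition effects, so the
# full analysis pipeline is testable without the original recordings.

#' Planted condition-effect sizes
#'
#' Defines how the Stroop (stress) session differs from Rest in the
#' generated data.  The defaults reproduce the direction pattern reported
#' for acute mental stress: nasal / nasal-septum / periorbital cooling and
#' left-cheek warming in mean temperature, increased temperature
#' variability over forehead, cheeks, periorbital and maxillary regions, a
#' tonic skin-conductance rise with denser phasic responses, shortened RR
#' intervals with raised LF/HF balance, and faster respiration.
#' Magnitudes are presets, not estimates.
#'
#' @param roi_mean_shift named vector (degrees C added under stress); names
#'   from [roi_names()], missing names = 0.
#' @param roi_std_mult named vector of stress multipliers on the
#'   temperature-fluctuation SD; missing names = 1.
#' @param tonic_shift tonic skin-conductance rise under stress, uS.
#' @param scr_rate SCR event rates `c(rest, stress)`, events/min.
#' @param mean_rr mean RR intervals `c(rest, stress)`, ms.
#' @param lf_amp,hf_amp low/high-frequency RR modulation amplitudes
#'   `c(rest, stress)`, ms.
#' @param resp_freq respiratory frequencies `c(rest, stress)`, Hz.
#' @return object of class `effect_sizes`, with an `informative` element
#'   listing the feature names that carry a nonzero planted effect.
#' @export
effect_sizes <- function(roi_mean_shift = c("Nose" = -0.3, "N-Sept" = -0.3,
                                            "R-POrb" = -0.3, "L-POrb" = -0.3,
                                            "L-Cheek" = 0.2),
                         roi_std_mult = c("Forehead" = 1.5, "R-Forehead" = 1.5,
                                          "R-Cheek" = 1.5, "L-Cheek" = 1.5,
                                          "R-POrb" = 1.5, "L-POrb" = 1.5,
                                          "R-Max" = 1.5, "L-Max" = 1.5),
                         tonic_shift = 1,
                         scr_rate = c(rest = 2, stress = 8),
                         mean_rr = c(rest = 850, stress = 750),
                         lf_amp = c(rest = 30, stress = 40),
                         hf_amp = c(rest = 40, stress = 20),
                         resp_freq = c(rest = 0.25, stress = 0.35)) {
  shift <- stats::setNames(rep(0, 14), roi_names())
  shift[names(roi_mean_shift)] <- roi_mean_shift
  mult <- stats::setNames(rep(1, 14), roi_names())
  mult[names(roi_std_mult)] <- roi_std_mult
  if (any(mult <= 0)) stop_ts("std multipliers must be > 0", class = "invalid_config")
  if (any(scr_rate < 0)) stop_ts("SCR rates must be >= 0", class = "invalid_config")
  if (any(resp_freq <= 0.05 | resp_freq >= 1))
    stop_ts("resp frequencies must lie in (0.05, 1) Hz", class = "invalid_config")
  informative <- c(
    paste(roi_label(roi_names()[shift != 0]), "Mean"),
    paste(roi_label(roi_names()[mult != 1]), "Std"),
    if (tonic_shift != 0) "TonicMean",
    if (diff(scr_rate) != 0) c("NPks", "PksSum", "PksMax", "PhasicMean",
                               "PhasicStd"),
    if (diff(mean_rr) != 0) "mean HRV",
    if (diff(lf_amp) != 0 || diff(hf_amp) != 0)
      c("RMSSD", "pNN50", "SD1", "LF", "HF", "LF/HF"),
    if (diff(resp_freq) != 0) "RESP freq")
  structure(list(roi_mean_shift = shift, roi_std_mult = mult,
                 tonic_shift = tonic_shift, scr_rate = scr_rate,
                 mean_rr = mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
                 resp_freq = resp_freq, informative = informative),
            class = "effect_sizes")
}

#' Zero-effect (null) configuration
#'
#' All condition effects removed: Rest and Stroop sessions are generated
#' from identical distributions.
#' @return an [effect_sizes()] object with no planted effect.
#' @export
null_effects <- function() {
  effect_sizes(roi_mean_shift = numeric(0), roi_std_mult = numeric(0),
               tonic_shift = 0, scr_rate = c(rest = 4, stress = 4),
               mean_rr = c(rest = 850, stress = 850),
               lf_amp = c(rest = 30, stress = 30),
               hf_amp = c(rest = 40, stress = 40),
               resp_freq = c(rest = 0.25, stress = 0.25))
}

#' Cohort generation settings
#'
#' @param n_subjects number of subjects (>= 2); each contributes one Rest
#'   and one Stroop session.
#' @param session_duration_s session length, s.
#' @param fs_thermal thermal frame rate, Hz.
#' @param fs_physio physiological sampling rate (EDA, respiration), Hz.
#' @param frame_size thermal frame `c(H, W)` in pixels.
#' @param effect an [effect_sizes()] object.
#' @param seed root random seed; all randomness derives from it.
#' @param area_fraction per-ROI size as a fraction of face pixels.
#' @param motion `"walk"` (bounded +/-1 px random-walk head motion) or
#'   `"none"`.
#' @param noise list of realism constants; see Details.
#' @details `noise` entries (all overridable): `pixel_sd` thermal pixel
#'   noise (0.05 C, camera-like), `traj_sd` ROI fluctuation SD (0.1 C),
#'   `subj_temp_sd` between-subject baseline SD (0.4 C), `roi_temp_sd`
#'   per-ROI baseline jitter (0.15 C), `tonic_base`/`tonic_sd` (2.0/0.5
#'   uS), `tonic_wander` slow tonic wander amplitude (0.2 uS),
#'   `scr_amp_meanlog`/`scr_amp_sdlog` (log 0.4 / 0.4), `eda_sd` (0.01 uS),
#'   `rr_subj_sd` (60 ms), `rr_sd` beat noise (5 ms), `amp_subj_sdlog`
#'   subject scaling of RR modulation (0.2), `resp_sd` subject resp-rate SD
#'   (0.02 Hz), `resp_noise_sd` respiration signal noise (0.1).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, session_duration_s = 180,
                          fs_thermal = 5, fs_physio = 500,
                          frame_size = c(64, 64), effect = effect_sizes(),
                          seed = 1L, area_fraction = 0.02,
                          motion = c("walk", "none"), noise = list()) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop_ts("n_subjects must be >= 2", class = "invalid_config")
  check_scalar(session_duration_s, "session_duration_s", 0, Inf, strict = TRUE)
  check_scalar(fs_thermal, "fs_thermal", 0, Inf, strict = TRUE)
  check_scalar(fs_physio, "fs_physio", 0, Inf, strict = TRUE)
  stopifnot(inherits(effect, "effect_sizes"))
  defaults <- list(pixel_sd = 0.05, traj_sd = 0.1, subj_temp_sd = 0.4,
                   roi_temp_sd = 0.15, face_base = 33.5, background = 24,
                   texture_amp = 0.3,
                   tonic_base = 2.0, tonic_sd = 0.5, tonic_wander = 0.2,
                   scr_amp_meanlog = log(0.4), scr_amp_sdlog = 0.4,
                   eda_sd = 0.01, rr_subj_sd = 60, rr_sd = 5,
                   amp_subj_sdlog = 0.2, resp_sd = 0.02, resp_noise_sd = 0.1)
  defaults[names(noise)] <- noise
  structure(list(n_subjects = as.integer(n_subjects),
                 session_duration_s = session_duration_s,
                 fs_thermal = fs_thermal, fs_physio = fs_physio,
                 frame_size = as.integer(frame_size), effect = effect,
                 seed = as.integer(seed), area_fraction = area_fraction,
                 motion = match.arg(motion), noise = defaults),
            class = "cohort_config")
}

# Stream splitting: every random draw happens under a seed derived from the
# root via one call of sample.int per level (root -> subjects -> session
# components), so components are independent and reproducible in isolation.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Fixed relative ROI-centre positions inside the face rectangle
# (fractions of face height/width), chosen so default-size ROI patches
# never overlap.
roi_rel_positions <- function() {
  m <- rbind(
    "Nose" = c(0.45, 0.50), "Forehead" = c(0.10, 0.50),
    "R-Forehead" = c(0.10, 0.25), "L-Forehead" = c(0.10, 0.75),
    "R-Cheek" = c(0.55, 0.20), "L-Cheek" = c(0.55, 0.80),
    "N-Sept" = c(0.62, 0.50), "Chin" = c(0.88, 0.50),
    "R-Chin" = c(0.88, 0.26), "L-Chin" = c(0.88, 0.74),
    "R-POrb" = c(0.28, 0.28), "L-POrb" = c(0.28, 0.72),
    "R-Max" = c(0.72, 0.30), "L-Max" = c(0.72, 0.70))
  colnames(m) <- c("row", "col")
  m
}

face_geometry <- function(frame_size) {
  H <- frame_size[1]; W <- frame_size[2]
  r0 <- round(0.12 * H); r1 <- round(0.88 * H)
  c0 <- round(0.20 * W); c1 <- round(0.80 * W)
  rel <- roi_rel_positions()
  centres <- lapply(stats::setNames(rownames(rel), rownames(rel)), function(nm)
    c(r0 + round(rel[nm, "row"] * (r1 - r0)),
      c0 + round(rel[nm, "col"] * (c1 - c0))))
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1,
       contour = rbind(c(r0 - 0.5, c0 - 0.5), c(r0 - 0.5, c1 + 0.5),
                       c(r1 + 0.5, c1 + 0.5), c(r1 + 0.5, c0 - 0.5)),
       centres = centres,
       n_face = (r1 - r0 + 1L) * (c1 - c0 + 1L))
}

# Nearest-n pixel-offset ball shared with place_rois() geometry.
ball_offsets <- function(n_px) {
  half <- ceiling((sqrt(n_px) - 1) / 2) + 1L
  off <- expand.grid(dr = -half:half, dc = -half:half)
  off <- off[order(off$dr^2 + off$dc^2, off$dr, off$dc), , drop = FALSE]
  as.matrix(off[seq_len(n_px), , drop = FALSE])
}

# Smooth (AR(1), rho = 0.95) temperature fluctuation scaled to unit SD.
smooth_fluctuation <- function(n, rho = 0.95) {
  x <- as.numeric(filter(rnorm(n), rho, method = "recursive"))
  x / sqrt(1 / (1 - rho^2))
}

#' Render a thermal frame stack from ROI temperature trajectories
#'
#' Paints a face rectangle (skin-range temperatures) on a cool background,
#' with each ROI patch carrying its true temperature trajectory plus i.i.d.
#' pixel noise, the whole face translated by the per-frame motion track.
#' Landmark metadata (ROI centres and face contour) follows the motion.
#'
#' @param roi_truth T x 14 matrix of true ROI temperatures, degrees C
#'   (columns named by [roi_names()]).
#' @param motion T x 2 integer matrix of (row, col) translations, px.
#' @param noise_sd pixel noise SD, degrees C.
#' @param config a [cohort_config()].
#' @param face_temp face (non-ROI) skin temperature, degrees C.
#' @return a [thermal_stack()] whose `landmarks[[t]]` holds the 14 ROI
#'   centres plus `face_contour`.
#' @export
generate_thermal_frames <- function(roi_truth, motion, noise_sd, config,
                                    face_temp = NULL) {
  g <- face_geometry(config$frame_size)
  H <- config$frame_size[1]; W <- config$frame_size[2]
  T_ <- nrow(roi_truth)
  stopifnot(nrow(motion) == T_, ncol(roi_truth) == 14L)
  if (any(g$r0 + motion[, 1] < 0) || any(g$r1 + motion[, 1] >= H) ||
      any(g$c0 + motion[, 2] < 0) || any(g$c1 + motion[, 2] >= W))
    stop_ts("motion pushes the face outside the frame", class = "invalid_config")
  if (is.null(face_temp)) face_temp <- config$noise$face_base
  n_px <- max(1L, round(config$area_fraction * g$n_face))
  off <- ball_offsets(n_px)
  frames <- array(config$noise$background, dim = c(H, W, T_))
  if (noise_sd > 0)
    frames <- frames + array(rnorm(length(frames), 0, noise_sd), dim = dim(frames))
  frames <- pmin(frames, 29)          # background stays below threshold
  landmarks <- vector("list", T_)
  fr_rows <- g$r0:g$r1; fr_cols <- g$c0:g$c1
  # Fixed face-local thermal texture (vascular-pattern-like spatial
  # structure) that translates with head motion; it gives the tracker
  # contrast but is excluded from the ROI patches themselves.
  tex <- config$noise$texture_amp *
    outer(sin(2 * pi * fr_rows / 6.3), sin(2 * pi * fr_cols / 4.7))
  for (t in seq_len(T_)) {
    mr <- motion[t, 1]; mc <- motion[t, 2]
    face <- matrix(face_temp, length(fr_rows), length(fr_cols)) + tex
    if (noise_sd > 0)
      face <- face + matrix(rnorm(length(face), 0, noise_sd), nrow(face))
    frames[fr_rows + mr + 1L, fr_cols + mc + 1L, t] <- pmin(pmax(face, 30.5), 37.5)
    lm <- list()
    for (k in seq_along(g$centres)) {
      nm <- names(g$centres)[k]
      ctr <- g$centres[[nm]] + c(mr, mc)
      vals <- roi_truth[t, nm] + if (noise_sd > 0)
        rnorm(n_px, 0, noise_sd) else 0
      frames[cbind(ctr[1] + off[, 1] + 1L, ctr[2] + off[, 2] + 1L, t)] <-
        pmin(pmax(vals, 30.5), 37.5)
      lm[[nm]] <- ctr
    }
    lm$face_contour <- g$contour + matrix(c(mr, mc), 4, 2, byrow = TRUE)
    landmarks[[t]] <- lm
  }
  thermal_stack(frames, config$fs_thermal, landmarks = landmarks)
}

#' Generate a synthetic skin-conductance recording
#'
#' Signal = slow tonic component (baseline plus a band-limited wander below
#' 0.05 Hz) + sum of biexponential skin-conductance responses at Poisson
#' event times + Gaussian noise, floored at a small positive value.
#'
#' @param tonic_level tonic baseline, uS.
#' @param scr_rate SCR event rate, events/min.
#' @param duration_s,fs duration (s) and sampling rate (Hz).
#' @param amp_meanlog,amp_sdlog log-normal SCR amplitude parameters, uS.
#' @param tonic_wander slow-wander amplitude, uS.
#' @param noise_sd additive noise SD, uS.
#' @param tau_rise,tau_decay SCR kernel time constants, s.
#' @return list with `signal`, `fs`, `tonic`, `scr_times`, `scr_amps`.
#' @export
generate_eda_signal <- function(tonic_level, scr_rate, duration_s, fs,
                                amp_meanlog = log(0.4), amp_sdlog = 0.4,
                                tonic_wander = 0.2, noise_sd = 0.01,
                                tau_rise = 0.7, tau_decay = 2.0) {
  if (scr_rate < 0) stop_ts("scr_rate must be >= 0", class = "invalid_config")
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  f_w <- runif(1, 0.005, 0.03)
  tonic <- tonic_level + tonic_wander * sin(2 * pi * f_w * tt + runif(1, 0, 2 * pi))
  n_ev <- rpois(1, scr_rate / 60 * duration_s)
  scr_times <- sort(runif(n_ev, 0, duration_s - 5))
  scr_amps <- rlnorm(n_ev, amp_meanlog, amp_sdlog)
  phasic <- numeric(n)
  if (n_ev > 0) {
    imp <- numeric(n)
    idx <- pmin(n, floor(scr_times * fs) + 1L)
    for (i in seq_len(n_ev)) imp[idx[i]] <- imp[idx[i]] + scr_amps[i]
    phasic <- bateman_apply(imp, bateman_coefs(fs, tau_rise, tau_decay))
  }
  signal <- tonic + phasic + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  list(signal = pmax(signal, 1e-6), fs = fs, tonic = tonic,
       scr_times = scr_times, scr_amps = scr_amps)
}

#' Generate a synthetic RR series and respiration signal
#'
#' Beat-to-beat intervals follow
#' `RR(t) = mean_rr + lf_amp sin(2 pi 0.1 t) + hf_amp sin(2 pi f_resp t) +
#' noise`, i.e. a 0.1 Hz low-frequency (baroreflex-like) modulation and a
#' high-frequency modulation locked to respiration; beat times accumulate
#' the intervals.  The respiration signal is a unit sinusoid at `resp_freq`
#' plus noise.
#'
#' @param mean_rr mean RR, ms, in (300, 1500).
#' @param lf_amp,hf_amp modulation amplitudes, ms.
#' @param resp_freq respiratory frequency, Hz.
#' @param duration_s session duration, s.
#' @param fs_resp respiration sampling rate, Hz.
#' @param rr_noise_sd,resp_noise_sd additive noise SDs.
#' @return list with `r_peak_times` (s), `rr` (an [rr_series()]), `resp`,
#'   `fs_resp`, `resp_freq`.
#' @export
generate_rr_and_resp <- function(mean_rr, lf_amp, hf_amp, resp_freq,
                                 duration_s, fs_resp = 500,
                                 rr_noise_sd = 5, resp_noise_sd = 0.1) {
  check_scalar(mean_rr, "mean_rr", 300, 1500, strict = TRUE)
  if (mean_rr - lf_amp - hf_amp - 6 * rr_noise_sd <= 0)
    stop_ts("modulation amplitudes would drive RR to zero", class = "invalid_config")
  times <- numeric(ceiling(duration_s / (mean_rr / 1000)) + 10L)
  t <- 0; k <- 0L
  while (t < duration_s) {
    rr_ms <- mean_rr + lf_amp * sin(2 * pi * 0.1 * t) +
      hf_amp * sin(2 * pi * resp_freq * t) +
      if (rr_noise_sd > 0) rnorm(1, 0, rr_noise_sd) else 0
    if (rr_ms <= 0) stop_ts("generated RR <= 0", class = "invalid_config")
    t <- t + rr_ms / 1000
    if (t >= duration_s) break
    k <- k + 1L
    times[k] <- t
  }
  times <- times[seq_len(k)]
  nr <- round(duration_s * fs_resp)
  tr <- (seq_len(nr) - 1) / fs_resp
  resp <- sin(2 * pi * resp_freq * tr) +
    if (resp_noise_sd > 0) rnorm(nr, 0, resp_noise_sd) else 0
  list(r_peak_times = times, rr = rr_series(beat_times = times),
       resp = resp, fs_resp = fs_resp, resp_freq = resp_freq)
}

bounded_walk <- function(n, p_step = 0.05, bound = 3L) {
  x <- integer(n)
  for (t in 2:n) {
    step <- sample(c(-1L, 0L, 1L), 1, prob = c(p_step, 1 - 2 * p_step, p_step))
    x[t] <- x[t - 1] + step
    if (abs(x[t]) > bound) x[t] <- x[t - 1] - step
  }
  x
}

# Subject-level random baselines drawn once per subject (shared by both
# sessions, giving realistic between-subject variability for LOSO).
draw_subject_params <- function(config) {
  nz <- config$noise
  list(temp_offset = rnorm(1, 0, nz$subj_temp_sd),
       roi_offset = stats::setNames(rnorm(14, 0, nz$roi_temp_sd), roi_names()),
       traj_scale = rlnorm(1, 0, 0.15),
       tonic = max(0.5, rnorm(1, nz$tonic_base, nz$tonic_sd)),
       rr_offset = rnorm(1, 0, nz$rr_subj_sd),
       amp_scale = rlnorm(1, 0, nz$amp_subj_sdlog),
       resp_jitter = rnorm(2, 0, nz$resp_sd))
}

# Fixed per-ROI baseline offsets from the face mean (degrees C): nose and
# septum cooler, periorbital warmer, the usual facial pattern.
roi_baseline_offsets <- function() {
  stats::setNames(c(-0.5, 0.3, 0.3, 0.3, 0.0, 0.0, -0.3,
                    -0.2, -0.2, -0.2, 0.5, 0.5, 0.1, 0.1), roi_names())
}

generate_session <- function(config, sp, session, seeds,
                             include = c("thermal", "eda", "cardioresp")) {
  nz <- config$noise
  eff <- config$effect
  stress <- session == "Stroop"
  dur <- config$session_duration_s
  T_ <- round(dur * config$fs_thermal)
  cond <- if (stress) "stress" else "rest"

  set.seed(seeds[1])                        # trajectories + motion
  base <- nz$face_base + sp$temp_offset + roi_baseline_offsets() + sp$roi_offset +
    if (stress) eff$roi_mean_shift else 0
  sdv <- nz$traj_sd * sp$traj_scale *
    (if (stress) eff$roi_std_mult else rep(1, 14))
  traj <- vapply(seq_len(14), function(k)
    base[k] + sdv[k] * smooth_fluctuation(T_), numeric(T_))
  colnames(traj) <- roi_names()
  traj <- pmin(pmax(traj, 31), 37)
  motion <- if (config$motion == "walk")
    cbind(bounded_walk(T_), bounded_walk(T_)) else matrix(0L, T_, 2)

  out <- list(session = session, truth = list(
    roi_traj = traj, motion = motion,
    resp_freq = NA_real_, scr_times = NULL, r_peak_times = NULL))

  if ("thermal" %in% include) {
    set.seed(seeds[2])
    out$thermal <- generate_thermal_frames(traj, motion, nz$pixel_sd, config,
                                           face_temp = nz$face_base + sp$temp_offset)
    g <- face_geometry(config$frame_size)
    out$truth$face_contour <- g$contour
    out$truth$centres <- g$centres
  }
  if ("eda" %in% include) {
    set.seed(seeds[3])
    eda <- generate_eda_signal(
      tonic_level = sp$tonic + if (stress) eff$tonic_shift else 0,
      scr_rate = eff$scr_rate[[cond]], duration_s = dur,
      fs = config$fs_physio, amp_meanlog = nz$scr_amp_meanlog,
      amp_sdlog = nz$scr_amp_sdlog, tonic_wander = nz$tonic_wander,
      noise_sd = nz$eda_sd)
    out$eda <- eda
    out$truth$scr_times <- eda$scr_times
  }
  if ("cardioresp" %in% include) {
    set.seed(seeds[4])
    rf <- eff$resp_freq[[cond]] + sp$resp_jitter[1 + stress]
    rf <- min(max(rf, 0.08), 0.9)
    cr <- generate_rr_and_resp(
      mean_rr = eff$mean_rr[[cond]] + sp$rr_offset,
      lf_amp = eff$lf_amp[[cond]] * sp$amp_scale,
      hf_amp = eff$hf_amp[[cond]] * sp$amp_scale,
      resp_freq = rf, duration_s = dur, fs_resp = config$fs_physio,
      rr_noise_sd = nz$rr_sd, resp_noise_sd = nz$resp_noise_sd)
    out$cardio <- cr
    out$truth$resp_freq <- rf
    out$truth$r_peak_times <- cr$r_peak_times
  }
  out
}

#' Generate a synthetic cohort
#'
#' Every subject contributes one Rest and one Stroop session, each carrying
#' a thermal frame stack, an EDA recording, R-peak times and a respiration
#' signal, together with the generating ground truth (ROI trajectories,
#' motion track, SCR event times, beat times, respiratory frequency).
#' Identical configurations (including the seed) produce identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @param include which signal families to render (ground truth is always
#'   produced); subset of `c("thermal", "eda", "cardioresp")`.
#' @return object of class `cohort`: list with `sessions` (list of session
#'   records with `subject`, `session`, `thermal`, `eda`, `cardio`,
#'   `truth`) and `config`.
#' @export
generate_cohort <- function(config,
                            include = c("thermal", "eda", "cardioresp")) {
  stopifnot(inherits(config, "cohort_config"))
  subj_seeds <- matrix(derive_seeds(config$seed, 2L * config$n_subjects),
                       nrow = 2)
  sessions <- list()
  for (i in seq_len(config$n_subjects)) {
    set.seed(subj_seeds[1, i])
    sp <- draw_subject_params(config)
    sess_seeds <- matrix(derive_seeds(subj_seeds[2, i], 8L), nrow = 2)
    for (s in 1:2) {
      session <- c("Rest", "Stroop")[s]
      rec <- generate_session(config, sp, session, sess_seeds[s, ], include)
      rec$subject <- sprintf("S%02d", i)
      sessions[[length(sessions) + 1L]] <- rec
    }
  }
  structure(list(sessions = sessions, config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x 2 sessions (%g s @ %g Hz thermal, %g Hz physio)\n",
              x$config$n_subjects, x$config$session_duration_s,
              x$config$fs_thermal, x$config$fs_physio))
  invisible(x)
}
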