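# Shared fixtures, built in code.  Expensive objects are computed once per
# test session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# Small cohort configuration: sizes chosen so every stage runs in seconds
# while all preconditions (>= 120 s for spectral HRV, 11x11 tracking patch
# inside the frame under the motion walk) hold.
small_config <- function(n = 4, duration = 120, effect = effect_sizes(),
                         seed = 1, ...) {
  cohort_config(n, session_duration_s = duration, frame_size = c(40, 40),
                effect = effect, seed = seed, ...)
}

# Deterministic ROI trajectory matrix (T x 14).
flat_traj <- function(T_, value = 33) {
  m <- matrix(value, T_, 14)
  colnames(m) <- roi_names()
  m
}

# Rendered noiseless static test stack with a known constant temperature.
test_stack <- function(T_ = 20, value = 33, frame = c(48, 48)) {
  cfg <- cohort_config(2, session_duration_s = T_ / 5, frame_size = frame,
                       seed = 1, motion = "none", noise = list(pixel_sd = 0))
  generate_thermal_frames(flat_traj(T_, value), matrix(0L, T_, 2), 0, cfg)
}

# Feature table of the default-preset 19-subject cohort (the study-sized
# run); cached because it drives several classifier checks.
preset_feature_table <- function() {
  cached("preset_ft", cohort_feature_table(cohort_config(19, seed = 0)))
}

# Synthetic gaussian feature table with planted informative columns:
# n_subjects x 2 sessions, informative columns shifted by `effect` under
# Stroop (in SD units).
toy_feature_table <- function(n_subjects, n_noise = 8, n_inf = 2, effect = 2,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_subjects
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = 2)
  session <- rep(c("Rest", "Stroop"), n_subjects)
  df <- data.frame(subject = subj, session = session, check.names = FALSE)
  for (i in seq_len(n_inf))
    df[[paste0("inf", i)]] <- rnorm(n) + effect * (session == "Stroop")
  for (i in seq_len(n_noise)) df[[paste0("noise", i)]] <- rnorm(n)
  assemble_feature_table(df)
}
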