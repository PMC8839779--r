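# Synthetic cohort generator: determinism, structure, planted signal
# content, null indistinguishability.

test_that("a cohort has two sessions per subject and is seed-deterministic", {
  cfg <- small_config(n = 3, duration = 20, seed = 7)
  co1 <- generate_cohort(cfg, include = "cardioresp")
  expect_length(co1$sessions, 6L)
  expect_equal(sort(unique(vapply(co1$sessions, `[[`, "", "session"))),
               c("Rest", "Stroop"))
  co2 <- generate_cohort(cfg, include = "cardioresp")
  expect_identical(co1, co2)
  co3 <- generate_cohort(small_config(n = 3, duration = 20, seed = 8),
                         include = "cardioresp")
  expect_false(identical(co1$sessions, co3$sessions))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(1), class = "invalid_config")
  expect_error(cohort_config(4, session_duration_s = 0), class = "invalid_config")
  expect_error(effect_sizes(roi_std_mult = c(Nose = -1)), class = "invalid_config")
  expect_error(effect_sizes(resp_freq = c(rest = 0.02, stress = 0.3)),
               class = "invalid_config")
})

test_that("thermal frames respect the temperature contract", {
  st <- test_stack(T_ = 5, value = 33)
  f <- st$frames[, , 1]
  lm <- st$landmarks[[1]]
  mask <- segment_face(f, contour = lm$face_contour)
  expect_true(all(f[mask] > 30 & f[mask] < 38))
  expect_true(all(f[!mask] < 30))
  # zero motion + zero noise: every frame identical
  expect_true(all(apply(st$frames, 3, identical, st$frames[, , 1])))
})

test_that("motion outside the frame is an error and tracks follow the truth", {
  cfg <- cohort_config(2, session_duration_s = 4, frame_size = c(48, 48),
                       seed = 1, motion = "none", noise = list(pixel_sd = 0))
  T_ <- 20
  too_far <- matrix(c(rep(0L, T_), seq_len(T_) + 10L), T_, 2)
  expect_error(generate_thermal_frames(flat_traj(T_), too_far, 0, cfg),
               class = "invalid_config")
  mo <- cbind(as.integer(seq_len(T_) %/% 5), 0L)   # +1 px row every 5 frames
  st <- generate_thermal_frames(flat_traj(T_), mo, 0, cfg)
  ctr0 <- st$landmarks[[1]][["Nose"]]
  lm_tracks <- t(vapply(st$landmarks, function(l) l[["Nose"]], c(0, 0)))
  expect_equal(unname(sweep(lm_tracks, 2, ctr0 - c(mo[1, ]))), unname(mo))
})

test_that("EDA generator: tonic-only limit and Poisson event counts", {
  set.seed(1)
  g0 <- generate_eda_signal(2, 0, 60, fs = 25, noise_sd = 0, tonic_wander = 0.1)
  expect_equal(g0$signal, g0$tonic)
  expect_length(g0$scr_times, 0L)
  # Monte-Carlo: 10 min at 6 events/min
  counts <- vapply(1:100, function(s) {
    set.seed(s)
    length(generate_eda_signal(2, 6, 600, fs = 5)$scr_times)
  }, 1L)
  expect_gt(mean(counts), 60 - 1.96 * sqrt(60 / 100) - 1)
  expect_lt(mean(counts), 60 + 1.96 * sqrt(60 / 100) + 1)
})

test_that("RR generator follows the stated modulation model", {
  set.seed(1)
  g <- generate_rr_and_resp(800, 0, 0, 0.25, 60, fs_resp = 25,
                            rr_noise_sd = 0, resp_noise_sd = 0)
  expect_equal(max(abs(g$rr$rr - 800)), 0)
  # modulated, noiseless: RR at beat k equals the closed form at t_{k-1}
  g2 <- generate_rr_and_resp(800, 30, 20, 0.25, 60, fs_resp = 25,
                             rr_noise_sd = 0, resp_noise_sd = 0)
  tprev <- c(0, head(g2$r_peak_times, -1))
  expected <- 800 + 30 * sin(2 * pi * 0.1 * tprev) +
    20 * sin(2 * pi * 0.25 * tprev)
  expect_equal(diff(c(0, g2$r_peak_times)) * 1000, expected, tolerance = 1e-9)
  expect_error(generate_rr_and_resp(400, 300, 200, 0.25, 60),
               class = "invalid_config")
})

test_that("with zero effects, Rest and Stroop truth distributions are
           indistinguishable (KS p values approximately uniform)", {
  feats <- function(co) {
    # cheap per-session summaries straight from the ground truth
    t(vapply(co$sessions, function(s) c(
      nose_mean = mean(s$truth$roi_traj[, "Nose"]),
      porb_sd = sd(s$truth$roi_traj[, "R-POrb"]),
      n_scr = length(s$truth$scr_times),
      rr = 1000 * mean(diff(s$truth$r_peak_times)),
      resp = s$truth$resp_freq), numeric(5)))
  }
  # compare Rest of one subject half against Stroop of the other half:
  # sessions of the same subject share its baselines, so the independent-
  # samples comparison needs disjoint subjects
  pvals <- t(vapply(1:50, function(sd) {
    co <- generate_cohort(small_config(n = 10, duration = 60,
                                       effect = null_effects(),
                                       seed = 1000 + sd),
                          include = c("eda", "cardioresp"))
    f <- feats(co)
    stroop <- vapply(co$sessions, `[[`, "", "session") == "Stroop"
    subj <- vapply(co$sessions, `[[`, "", "subject")
    half_a <- subj %in% sprintf("S%02d", 1:5)
    vapply(colnames(f), function(cn)
      suppressWarnings(stats::ks.test(f[!stroop & half_a, cn],
                                      f[stroop & !half_a, cn])$p.value),
      1.0)
  }, numeric(5)))
  # approximate uniformity: mean near 1/2, no excess of small p values
  expect_true(all(abs(colMeans(pvals) - 0.5) < 0.2))
  expect_true(all(colMeans(pvals < 0.05) <= 0.15))
})

test_that("a larger planted tonic effect improves the TonicMean rank
           through the whole pipeline", {
  med_rank <- vapply(c(0.25, 1, 3), function(shift) {
    ranks <- vapply(1:2, function(s) {
      eff <- effect_sizes(tonic_shift = shift)
      cfg <- small_config(n = 6, duration = 120, effect = eff,
                          seed = 40 + s)
      ft <- cohort_feature_table(cfg)
      red <- suppressWarnings(filter_select(ft))
      rk <- svm_rfe_cbr_rank(red)
      p_all <- length(feature_names("full"))
      pos <- match("TonicMean", rk$feature)
      if (is.na(pos)) p_all + 1 else pos   # filtered out = worst rank
    }, 1.0)
    median(ranks)
  }, 1.0)
  expect_true(all(diff(med_rank) <= 0))
})
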