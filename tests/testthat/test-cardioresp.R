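# HRV and respiration: correction, resampling, 10 features, resp frequency.

test_that("rr_series enforces its consistency invariants", {
  rr <- rr_series(beat_times = cumsum(rep(0.8, 10)))
  expect_equal(rr$rr, rep(800, 9))
  expect_error(rr_series(rr = c(800, -5)), class = "invalid_config")
  expect_error(rr_series(rr = c(800, 810), beat_times = c(1, 1.9)),
               class = "invalid_config")
})

test_that("artefact correction replaces ectopic beats and preserves counts", {
  set.seed(8)
  g <- generate_rr_and_resp(800, 30, 20, 0.25, 120, fs_resp = 25,
                            rr_noise_sd = 2, resp_noise_sd = 0)
  clean <- correct_rr(g$rr)
  expect_equal(clean$rr, g$rr$rr, tolerance = 1e-12)   # artefact-free input
  corrupted <- g$rr
  k <- 60
  true_val <- corrupted$rr[k]
  corrupted$rr[k] <- true_val / 2                       # ectopic-like halving
  corrupted <- rr_series(rr = corrupted$rr)
  fixed <- correct_rr(corrupted)
  expect_true(fixed$flagged[k])
  expect_length(fixed$rr, length(g$rr$rr))
  expect_lt(abs(fixed$rr[k] - true_val) / true_val, 0.05)
  # beat times consistent with corrected intervals
  expect_lt(max(abs(diff(fixed$beat_times) * 1000 - fixed$rr[-1])), 1e-9)
  # unusable series: majority wild
  wild <- rep(c(400, 1200), 30)
  expect_error(correct_rr(rr_series(rr = wild)), class = "unusable_series")
})

test_that("4 Hz resampling matches an independent interpolation oracle", {
  rr <- rr_series(rr = rep(800, 224))
  h <- rr_to_hrv_series(rr, duration_s = 180)
  expect_length(h$values, 720L)
  expect_equal(unique(round(h$values, 9)), 75)          # 60000/800 bpm
  h_ms <- rr_to_hrv_series(rr, duration_s = 180, unit = "ms")
  expect_equal(unique(round(h_ms$values, 9)), 800)
  # smooth tachogram: values match stats::spline on a dense grid
  set.seed(9)
  g <- generate_rr_and_resp(800, 40, 25, 0.25, 120, fs_resp = 25,
                            rr_noise_sd = 0, resp_noise_sd = 0)
  h2 <- rr_to_hrv_series(g$rr, duration_s = 120, unit = "ms")
  oracle <- spline(g$rr$beat_times, g$rr$rr, xout = h2$time_s,
                   method = "natural")$y
  expect_equal(h2$values, oracle, tolerance = 1e-9)
  # resampling preserves the time-weighted tachogram mean on smooth series
  tw_mean <- sum(g$rr$rr^2) / sum(g$rr$rr)
  expect_lt(abs(mean(h2$values) - tw_mean), 1)
  # coverage gap
  gap <- rr_series(beat_times = c(cumsum(rep(0.8, 50)), 50 + cumsum(rep(0.8, 50))))
  expect_error(rr_to_hrv_series(gap, duration_s = 90), class = "coverage_gap")
})

test_that("time-domain features match hand-worked values", {
  rr <- rr_series(rr = rep(800, 100))
  h <- rr_to_hrv_series(rr, duration_s = 80)
  f <- hrv_time_features(rr, h)
  expect_equal(unname(f[c("RMSSD", "pNN50")]), c(0, 0))
  f2 <- hrv_time_features(rr_series(rr = c(800, 810, 790, 805)),
                          rr_to_hrv_series(rr_series(rr = rep(800, 10)),
                                           duration_s = 8))
  expect_equal(unname(f2["RMSSD"]), sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-12)
  f3 <- hrv_time_features(rr_series(rr = c(800, 860, 800)),
                          rr_to_hrv_series(rr_series(rr = rep(800, 10)),
                                           duration_s = 8))
  expect_equal(unname(f3["pNN50"]), 100)
})

test_that("spectral features separate LF- and HF-dominant modulation", {
  mk <- function(lf, hf) {
    set.seed(10)
    g <- generate_rr_and_resp(800, lf, hf, 0.3, 300, fs_resp = 25,
                              rr_noise_sd = 0, resp_noise_sd = 0)
    hrv_freq_features(rr_to_hrv_series(g$rr, duration_s = 300, unit = "ms"))
  }
  lf_only <- mk(40, 0)
  expect_gt(lf_only[["LF"]], 95)
  expect_lt(lf_only[["HF"]], 5)
  expect_gt(lf_only[["LF/HF"]], 10)
  hf_only <- mk(0, 40)
  expect_gt(hf_only[["HF"]], 95)
  expect_lt(hf_only[["LF/HF"]], 0.1)
  both <- mk(40, 40)
  expect_equal(both[["LF/HF"]], 1, tolerance = 0.1)
  expect_lte(both[["LF"]] + both[["HF"]], 100 + 1e-9)
})

test_that("Poincare axes and sample entropy match brute-force oracles", {
  rrv <- rr_series(rr = rep(800, 60))
  f0 <- hrv_nonlinear_features(rrv)
  expect_equal(unname(f0), c(0, 0, 0))
  set.seed(11)
  x <- 800 + cumsum(rnorm(120, 0, 8))
  rr <- rr_series(rr = x)
  f <- hrv_nonlinear_features(rr)
  h <- hrv_time_features(rr, rr_to_hrv_series(rr, duration_s = floor(sum(x) / 1000)))
  # exact identity SD1 = RMSSD/sqrt(2) (population-SD convention)
  expect_equal(unname(f["SD1"]), unname(h["RMSSD"]) / sqrt(2),
               tolerance = 1e-9)
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  expect_equal(unname(f["SD2"]), sqrt(2 * pop_sd(x)^2 - f[["SD1"]]^2),
               tolerance = 1e-9)
  # SampEn: exhaustive O(n^2) template counting
  sampen_oracle <- function(z, m = 2, r = 0.2 * pop_sd(z)) {
    n <- length(z)
    A <- 0; B <- 0
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (j <= i) next
      if (max(abs(z[i:(i + m - 1)] - z[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(z[i + m] - z[j + m]) <= r &&
            max(abs(z[i:(i + m)] - z[j:(j + m)])) <= r) A <- A + 1
      }
    }
    -log(A / B)
  }
  expect_equal(f[["SampEn"]], sampen_oracle(x), tolerance = 1e-12)
  # invariance to affine rescaling
  expect_equal(sample_entropy(3 * x + 100), sample_entropy(x), tolerance = 1e-12)
})

test_that("respiratory frequency finds the dominant in-band peak", {
  fs <- 25
  tt <- (0:(300 * fs - 1)) / fs
  bin <- 1 / 64
  for (f0 in c(0.25, 0.40)) {
    est <- resp_frequency(sin(2 * pi * f0 * tt), fs)
    expect_lt(abs(est - f0), bin + 1e-9)
  }
  two <- sin(2 * pi * 0.2 * tt) + 0.3 * sin(2 * pi * 0.35 * tt)
  expect_lt(abs(resp_frequency(two, fs) - 0.2), bin + 1e-9)
  set.seed(12)
  expect_error(resp_frequency(rnorm(300 * fs), fs), class = "no_peak")
  expect_error(resp_frequency(sin(2 * pi * 0.25 * tt[1:100]), fs),
               class = "insufficient_data")
})
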