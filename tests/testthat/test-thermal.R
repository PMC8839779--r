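# Thermal imaging stage: registration, synchronisation, segmentation, ROI
# placement, tracking, median extraction, cleaning.

test_that("affine estimation recovers exact transforms and rejects
           degenerate geometry", {
  src <- cbind(c(0, 10, 0, 7), c(0, 0, 10, 3))
  expect_equal(estimate_affine(src, src)$A, cbind(diag(2), c(0, 0)),
               tolerance = 1e-12)
  shifted <- sweep(src, 2, c(5, 3), "+")
  at <- estimate_affine(src, shifted)
  expect_lt(max(abs(apply_affine(at, src) - shifted)), 1e-9)
  expect_lt(at$rmse, 1e-9)
  # general affine, construct-and-invert
  A <- rbind(c(1.2, 0.1, -4), c(-0.3, 0.9, 2))
  dst <- t(A %*% t(cbind(src, 1)))
  at2 <- estimate_affine(src, dst)
  expect_equal(at2$A, A, tolerance = 1e-9)
  back <- apply_affine(invert_affine(at2), apply_affine(at2, src))
  expect_lt(max(abs(back - src)), 1e-9)
  collinear <- cbind(1:3, (1:3) * 2)
  expect_error(estimate_affine(collinear, collinear),
               class = "degenerate_geometry")
  expect_error(estimate_affine(src[1:2, ], src[1:2, ]),
               class = "degenerate_geometry")
})

test_that("stream synchronisation pairs nearest timestamps", {
  rgb <- (0:899) / 30
  ir <- (0:149) / 5
  pairs <- synchronize_streams(rgb, ir)
  expect_equal(nrow(pairs), 150L)
  expect_equal(pairs$rgb_index, seq(1, 900, by = 6))
  expect_true(all(pairs$paired))
  # offset start: gaps bounded by half the RGB period, matches brute force
  pairs2 <- synchronize_streams(rgb + 0.01, ir)
  brute <- vapply(ir, function(t) which.min(abs(rgb + 0.01 - t)), 1L)
  expect_equal(pairs2$rgb_index, brute)
  expect_true(all(pairs2$gap_s <= 1 / 60 + 1e-12))
  # IR stream longer: trailing frames kept but flagged
  ir_long <- (0:154) / 5
  pairs3 <- synchronize_streams(rgb, ir_long)
  expect_equal(nrow(pairs3), 155L)
  expect_true(all(!pairs3$paired[152:155]))
  expect_error(synchronize_streams(rgb, ir + 1000), class = "disjoint_streams")
})

test_that("face segmentation applies strict thresholds and the contour", {
  expect_error(segment_face(matrix(25, 8, 8)), class = "no_face")
  fr <- matrix(22, 20, 20)
  fr[5:10, 6:12] <- 33
  mask <- segment_face(fr)
  expect_equal(which(mask), which(fr == 33))
  # boundary pixel at exactly the threshold is excluded
  fr[5, 6] <- 30
  expect_false(segment_face(fr)[5, 6])
  fr[5, 6] <- 38
  expect_false(segment_face(fr)[5, 6])
  # contour separates face from a same-temperature torso
  fr2 <- matrix(22, 20, 20)
  fr2[2:18, 4:16] <- 33
  contour <- rbind(c(1.5, 3.5), c(1.5, 16.5), c(9.5, 16.5), c(9.5, 3.5))
  m2 <- segment_face(fr2, contour = contour)
  expect_true(all(which(m2, arr.ind = TRUE)[, 1] <= 10))
})

test_that("ROI placement is proportional to face size", {
  fr <- matrix(33, 50, 50)
  mask <- fr > 30
  lms <- lapply(thermostress:::face_geometry(c(50, 50))$centres, identity)
  rois <- place_rois(lms, mask, area_fraction = 0.02)
  expect_length(rois, 14L)
  expect_setequal(names(rois), roi_names())
  expect_equal(unique(vapply(rois, `[[`, 1L, "n_px")), round(0.02 * 2500))
  # 1000-pixel face at fraction 0.02 -> 20-pixel ROI; doubling the face
  # area doubles the pixel count (+- 1)
  mask20 <- matrix(FALSE, 50, 50)
  mask20[11:35, 11:50] <- TRUE     # 25 x 40 = 1000 px
  lms20 <- lapply(lms, function(p) c(20, 30))
  expect_equal(place_rois(lms20, mask20)[["Nose"]]$n_px, 20L)
  mask10 <- matrix(FALSE, 50, 50)
  mask10[11:35, 21:40] <- TRUE     # 25 x 20 = 500 px
  expect_lte(abs(2 * place_rois(lms20, mask10)[["Nose"]]$n_px -
                 place_rois(lms20, mask20)[["Nose"]]$n_px), 1)
  # centre outside the face mask
  lms_bad <- lms
  lms_bad$Nose <- c(0, 0)
  mask2 <- mask
  mask2[1, 1] <- FALSE
  expect_error(place_rois(lms_bad, mask2), class = "placement_error")
})

test_that("tracking is exact on static and integer-translated stacks and
           flags escapes", {
  st <- test_stack(T_ = 10)
  ctr <- st$landmarks[[1]][roi_names()]
  tr <- track_centres(st, ctr)
  expect_true(all(tr$lost == 0L))
  for (nm in roi_names())
    expect_true(all(sweep(tr$tracks[[nm]], 2, ctr[[nm]]) == 0))
  # planted (+1, 0) px/frame translation up to the walk bound
  cfg <- cohort_config(2, session_duration_s = 2, frame_size = c(48, 48),
                       seed = 1, motion = "none", noise = list(pixel_sd = 0))
  T_ <- 5
  mo <- cbind(0:(T_ - 1), 0L)
  st2 <- generate_thermal_frames(flat_traj(T_), mo, 0, cfg)
  tr2 <- track_centres(st2, st2$landmarks[[1]][roi_names()])
  for (nm in roi_names())
    expect_equal(unname(sweep(tr2$tracks[[nm]], 2,
                              st2$landmarks[[1]][[nm]])), unname(mo))
  # a track pushed to the frame edge is flagged lost at the right frame
  esc <- track_centres(st, list(Edge = c(24, 7)), patch_half = 5, radius = 5)
  expect_equal(esc$lost[["Edge"]], 0L)
  esc2 <- track_centres(st, list(Edge = c(24, 4)))
  expect_equal(esc2$lost[["Edge"]], 1L)
})

test_that("median extraction matches a sort-based oracle and is robust", {
  st <- test_stack(T_ = 6, value = 33)
  lm1 <- st$landmarks[[1]]
  mask <- segment_face(st$frames[, , 1], contour = lm1$face_contour)
  rois <- place_rois(lm1[roi_names()], mask, 0.02)
  sigs <- extract_roi_signals(st, rois, NULL)
  expect_length(sigs$signals, 14L)
  expect_true(all(vapply(sigs$signals, length, 1L) == 6L))
  for (nm in roi_names()) expect_equal(sigs$signals[[nm]], rep(33, 6))
  # one hot pixel cannot move the median
  st$frames[rois$Nose$centre[1] + 1, rois$Nose$centre[2] + 1, 3] <- 40
  sigs2 <- extract_roi_signals(st, rois, NULL)
  expect_equal(sigs2$signals$Nose[3], 33)
  # oracle on an arbitrary ROI patch
  vals <- st$frames[rois$Chin$offsets[, 1] + rois$Chin$centre[1] + 1 +
                    nrow(st$frames[, , 1]) *
                      (rois$Chin$offsets[, 2] + rois$Chin$centre[2])]
  expect_equal(sigs2$signals$Chin[1], median(sort(vals)))
})

test_that("median extraction tolerates <50% corrupted pixels", {
  st <- test_stack(T_ = 3, value = 33)
  lm1 <- st$landmarks[[1]]
  mask <- segment_face(st$frames[, , 1], contour = lm1$face_contour)
  rois <- place_rois(lm1[roi_names()], mask, 0.02)
  roi <- rois$Nose
  n_c <- floor((roi$n_px - 1) / 2)
  idx <- cbind(roi$offsets[seq_len(n_c), 1] + roi$centre[1] + 1,
               roi$offsets[seq_len(n_c), 2] + roi$centre[2] + 1, 1)
  st$frames[idx] <- 36.9
  sigs <- extract_roi_signals(st, rois, NULL)
  expect_equal(sigs$signals$Nose[1], 33)
})

test_that("signal cleaning removes spikes, handles adjacent outliers, and
           is idempotent on realistic signals", {
  expect_equal(clean_signal(rep(33, 50))$values, rep(33, 50))
  set.seed(4)
  x <- 33 + 0.05 * sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.01)
  spiked <- x
  spiked[100] <- 43
  cl <- clean_signal(spiked)
  expect_lt(max(abs(cl$values - 33)), 0.5)
  # brute-force oracle for the moving-median step (symmetric edge shrink)
  med_oracle <- function(z, k = 5) {
    h <- k %/% 2
    vapply(seq_along(z), function(i) {
      hh <- min(h, i - 1, length(z) - i)
      median(z[(i - hh):(i + hh)])
    }, 1.0)
  }
  # the cleaned signal is a fixed point (root) of the one-pass filter
  expect_equal(med_oracle(cl$values), cl$values)
  # a single spike never survives one 5-point median pass
  expect_equal(med_oracle(spiked)[100], median(spiked[98:102]))
  # adjacent outliers (run long enough to survive the 5-point median)
  # are all replaced by the nearest valid value
  y <- rep(33, 60)
  y[30:32] <- 39
  cl2 <- clean_signal(y)
  expect_true(all(cl2$replaced[30:32]))
  expect_equal(cl2$values[30:32], rep(33, 3))
  # idempotence
  cl_a <- clean_signal(spiked)$values
  expect_equal(clean_signal(cl_a)$values, cl_a)
  expect_error(clean_signal(rep(33, 3), window = 5),
               class = "insufficient_data")
})

test_that("end-to-end thermal recovery is exact at zero noise under motion", {
  cfg <- cohort_config(2, session_duration_s = 12, frame_size = c(48, 48),
                       seed = 3, motion = "none", noise = list(pixel_sd = 0))
  T_ <- 60
  set.seed(9)
  traj <- flat_traj(T_)
  for (k in 1:14) traj[, k] <- 33 + k / 20 +
      0.3 * sin(seq(0, 4 * pi, length.out = T_) + k)
  mo <- cbind(as.integer(round(cumsum(rnorm(T_, 0, 0.4)))),
              as.integer(round(cumsum(rnorm(T_, 0, 0.4)))))
  mo[, 1] <- pmax(pmin(mo[, 1], 3L), -3L)
  mo[, 2] <- pmax(pmin(mo[, 2], 3L), -3L)
  st <- generate_thermal_frames(traj, mo, 0, cfg)
  lm1 <- st$landmarks[[1]]
  mask <- segment_face(st$frames[, , 1], contour = lm1$face_contour)
  rois <- place_rois(lm1[roi_names()], mask, cfg$area_fraction)
  tracks <- track_centres(st, lm1[roi_names()])
  sigs <- extract_roi_signals(st, rois, tracks)
  err <- max(vapply(roi_names(), function(nm)
    max(abs(sigs$signals[[nm]] - traj[, nm])), 1.0))
  expect_lt(err, 1e-9)
})
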