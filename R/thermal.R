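#' Thermal frame-stack container
#'
#' Bundles a stack of temperature frames with its timing and per-frame
#' facial-landmark metadata.  Frames use 0-based (row, col) pixel
#' coordinates and temperatures in degrees C.
#'
#' @param frames numeric array, dim `c(H, W, T)`.
#' @param fs frame rate, Hz.
#' @param timestamps frame times in seconds (default `0:(T-1)/fs`).
#' @param landmarks list of length `T`; each element a named list of
#'   2-vectors `c(row, col)` (ROI centres, face-contour corners, ...).
#' @return object of class `thermal_stack`.
#' @export
thermal_stack <- function(frames, fs, timestamps = NULL, landmarks = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  check_scalar(fs, "fs", 0, Inf, strict = TRUE)
  T_ <- dim(frames)[3]
  if (T_ < 1L) stop_ts("stack needs at least one frame", class = "invalid_config")
  if (any(!is.finite(frames)))
    stop_ts("non-finite temperatures in stack", class = "invalid_config")
  if (is.null(timestamps)) timestamps <- (seq_len(T_) - 1) / fs
  if (any(diff(timestamps) <= 0))
    stop_ts("timestamps must be strictly increasing", class = "invalid_config")
  structure(list(frames = frames, fs = fs, timestamps = timestamps,
                 landmarks = landmarks),
            class = "thermal_stack")
}

#' @export
print.thermal_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_stack> %d frames of %dx%d px @ %g Hz, %.1f-%.1f C\n",
              d[3], d[1], d[2], x$fs, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Least-squares 2-D affine registration from point pairs
#'
#' Estimates the 2x3 affine matrix mapping source fiducial points onto
#' destination points (e.g., RGB landmarks onto the infrared frame), as the
#' minimiser of the summed squared residuals.
#'
#' @param src,dst n x 2 matrices of (row, col) points, n >= 3.
#' @return object of class `affine_transform` with elements `A` (2x3
#'   matrix) and `rmse`.
#' @export
estimate_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || nrow(dst) != nrow(src))
    stop_ts("need >= 3 point pairs with equal counts", class = "degenerate_geometry")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stop_ts("source points are collinear", class = "degenerate_geometry")
  B <- qr.solve(X, dst)                 # 3 x 2
  A <- t(B)                              # 2 x 3
  if (abs(det(A[, 1:2])) < 1e-12)
    stop_ts("estimated linear part is singular", class = "degenerate_geometry")
  res <- X %*% B - dst
  structure(list(A = A, rmse = sqrt(mean(res^2))), class = "affine_transform")
}

#' Apply an affine transform to points
#' @param transform an `affine_transform`.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_affine <- function(transform, pts) {
  pts <- rbind(as.matrix(pts))
  t(transform$A %*% t(cbind(pts, 1)))
}

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  Ainv <- solve(transform$A[, 1:2])
  structure(list(A = cbind(Ainv, -Ainv %*% transform$A[, 3]), rmse = 0),
            class = "affine_transform")
}

#' Pair RGB and infrared frames by nearest timestamp
#'
#' The higher-rate RGB stream is effectively downsampled to the infrared
#' rate by assigning to each IR frame the RGB frame with the nearest
#' timestamp.  IR frames outside the RGB time range (beyond half an RGB
#' frame period) are kept but flagged unpaired rather than dropped.
#'
#' @param rgb_times,ir_times frame timestamps in seconds, or objects with a
#'   `timestamps` element.
#' @return data.frame with `ir_index`, `rgb_index`, `gap_s`, `paired`.
#' @export
synchronize_streams <- function(rgb_times, ir_times) {
  if (is.list(rgb_times)) rgb_times <- rgb_times$timestamps
  if (is.list(ir_times)) ir_times <- ir_times$timestamps
  if (min(ir_times) > max(rgb_times) || max(ir_times) < min(rgb_times))
    stop_ts("RGB and IR streams do not overlap in time", class = "disjoint_streams")
  idx <- vapply(ir_times, function(t) which.min(abs(rgb_times - t)), 1L)
  gap <- abs(rgb_times[idx] - ir_times)
  period <- median(diff(rgb_times))
  data.frame(ir_index = seq_along(ir_times), rgb_index = idx, gap_s = gap,
             paired = gap <= period / 2 + 1e-12)
}

# Ray-casting point-in-polygon; poly is n x 2 (row, col), pts m x 2.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pts[, 1]) != (yj > pts[, 1])) &
      (pts[, 2] < (xj - xi) * (pts[, 1] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Threshold-based face segmentation of a thermal frame
#'
#' Keeps pixels whose temperature lies strictly inside `(t_low, t_high)`,
#' the physiological skin range that separates the face from hair and
#' background, optionally intersected with the face-contour polygon that
#' separates the face from neck and torso.
#'
#' @param frame H x W temperature matrix, degrees C.
#' @param t_low,t_high segmentation thresholds, degrees C (strict
#'   inequalities).
#' @param contour optional polygon, n x 2 matrix of (row, col) vertices
#'   (0-based, as in landmark metadata).
#' @return logical H x W mask.
#' @export
segment_face <- function(frame, t_low = 30, t_high = 38, contour = NULL) {
  if (t_low >= t_high)
    stop_ts("t_low must be below t_high", class = "invalid_config")
  mask <- frame > t_low & frame < t_high
  if (!is.null(contour)) {
    idx <- which(mask, arr.ind = TRUE) - 1L   # 0-based (row, col)
    if (nrow(idx) > 0L) {
      keep <- points_in_polygon(idx, as.matrix(contour))
      mask[which(mask)[!keep]] <- FALSE
    }
  }
  if (!any(mask))
    stop_ts("no face pixels in (%g, %g) C", t_low, t_high, class = "no_face")
  mask
}

#' Place the 14 ROIs proportionally to the face size
#'
#' Each ROI receives `round(area_fraction * face_pixels)` pixels: the
#' nearest pixels to its centre landmark (squared-distance order, row/col
#' tie-break), clipped to the face mask.
#'
#' @param landmarks named list of ROI centre landmarks `c(row, col)`,
#'   0-based; must contain all names in [roi_names()].
#' @param face_mask logical H x W face mask.
#' @param area_fraction single fraction or named vector per ROI.
#' @return named list of ROI specs: `name`, `centre`, `area_fraction`,
#'   `offsets` (m x 2 integer matrix of pixel offsets relative to the
#'   centre), `n_px`.
#' @export
place_rois <- function(landmarks, face_mask, area_fraction = 0.02) {
  need <- roi_names()
  if (!all(need %in% names(landmarks)))
    stop_ts("missing centre landmarks: %s",
            paste(setdiff(need, names(landmarks)), collapse = ", "),
            class = "placement_error")
  if (!any(face_mask)) stop_ts("empty face mask", class = "no_face")
  fracs <- if (length(area_fraction) == 1L)
    stats::setNames(rep(area_fraction, 14L), need) else area_fraction
  n_face <- sum(face_mask)
  lapply(stats::setNames(need, need), function(nm) {
    ctr <- round(landmarks[[nm]])
    if (ctr[1] < 0 || ctr[1] >= nrow(face_mask) ||
        ctr[2] < 0 || ctr[2] >= ncol(face_mask) ||
        !face_mask[ctr[1] + 1L, ctr[2] + 1L])
      stop_ts("ROI '%s' centre is outside the face mask", nm,
              class = "placement_error")
    n_px <- max(1L, round(fracs[[nm]] * n_face))
    half <- ceiling((sqrt(n_px) - 1) / 2) + 1L
    off <- expand.grid(dr = -half:half, dc = -half:half)
    ord <- order(off$dr^2 + off$dc^2, off$dr, off$dc)
    off <- off[ord, , drop = FALSE]
    r <- ctr[1] + off$dr; c <- ctr[2] + off$dc
    ok <- r >= 0 & r < nrow(face_mask) & c >= 0 & c < ncol(face_mask)
    ok[ok] <- face_mask[cbind(r[ok] + 1L, c[ok] + 1L)]
    off <- off[ok, , drop = FALSE][seq_len(min(n_px, sum(ok))), , drop = FALSE]
    list(name = nm, centre = ctr, area_fraction = fracs[[nm]],
         offsets = as.matrix(off), n_px = nrow(off))
  })
}

#' Track ROI centres through a frame stack
#'
#' Frame-to-frame integer-displacement block matching: the patch around the
#' previous centre is matched (sum of squared differences) against
#' displacements within `radius` pixels in the next frame.  A track whose
#' patch leaves the image is flagged lost at that frame and frozen.
#'
#' @param stack a [thermal_stack()].
#' @param initial_centres named list of `c(row, col)` 0-based centres.
#' @param patch_half half-width of the matching patch (patch is
#'   `2*patch_half+1` squared; default 5 gives 11 x 11).
#' @param radius search radius in pixels per frame step.
#' @return list with `tracks` (named list of T x 2 integer matrices) and
#'   `lost` (named integer vector: first lost frame, 1-based, 0 = never).
#' @export
track_centres <- function(stack, initial_centres, patch_half = 5L, radius = 5L) {
  d <- dim(stack$frames)
  cmat <- do.call(rbind, initial_centres)
  if (any(cmat[, 1] < 0 | cmat[, 1] >= d[1] | cmat[, 2] < 0 | cmat[, 2] >= d[2]))
    stop_ts("initial centre outside frame", class = "placement_error")
  res <- cpp_track_centres(as.numeric(stack$frames), as.integer(d),
                           cmat, as.integer(patch_half), as.integer(radius))
  names(res$tracks) <- names(initial_centres)
  names(res$lost) <- names(initial_centres)
  res
}

#' Extract per-ROI median temperature signals
#'
#' For every frame, the ROI pixel set is re-centred on the tracked centre
#' and the median temperature over its pixels is recorded, yielding one
#' thermal signal per ROI.  Samples where no ROI pixel falls in the face
#' temperature range are flagged.
#'
#' @param stack a [thermal_stack()].
#' @param rois ROI specs from [place_rois()].
#' @param tracks per-ROI tracks from [track_centres()], or `NULL` for
#'   static centres.
#' @param t_low,t_high face temperature range used for flagging.
#' @return object of class `roi_signal_set`: list with `time_s`, `fs`,
#'   `signals` (named list of numeric vectors), `flags`.
#' @export
extract_roi_signals <- function(stack, rois, tracks = NULL,
                                t_low = 30, t_high = 38) {
  d <- dim(stack$frames)
  T_ <- d[3]
  sv <- as.numeric(stack$frames)
  signals <- list(); flags <- list()
  for (nm in names(rois)) {
    roi <- rois[[nm]]
    tr <- if (is.null(tracks)) {
      matrix(rep(roi$centre, each = T_), ncol = 2)
    } else tracks$tracks[[nm]]
    stopifnot(nrow(tr) == T_)
    res <- cpp_roi_median_series(sv, as.integer(d),
                                 matrix(as.integer(tr), ncol = 2),
                                 as.integer(roi$offsets[, 1]),
                                 as.integer(roi$offsets[, 2]), t_low, t_high)
    signals[[nm]] <- res$values
    flags[[nm]] <- res$flag
  }
  structure(list(time_s = stack$timestamps, fs = stack$fs,
                 signals = signals, flags = flags),
            class = "roi_signal_set")
}

#' @export
print.roi_signal_set <- function(x, ...) {
  cat(sprintf("<roi_signal_set> %d ROI signals, %d samples @ %g Hz\n",
              length(x$signals), length(x$time_s), x$fs))
  invisible(x)
}

#' Clean a ROI temperature signal
#'
#' Two-step cleaning: a moving-median filter (window `window`, symmetric
#' edge shrink) removes high-frequency noise, then samples deviating more
#' than `n_sd` standard deviations from the filtered signal's mean are
#' replaced by the nearest-in-time non-outlier value (earlier sample on
#' ties).  Both steps are iterated to a joint fixed point (Tukey-style
#' repeated median smoothing), so cleaning is idempotent: cleaning a
#' cleaned signal changes nothing.
#'
#' @param signal numeric temperature signal.
#' @param window odd moving-median window length in samples (default 5,
#'   i.e. 1 s at 5 Hz).
#' @param n_sd outlier threshold in standard deviations.
#' @param max_pass iteration cap for the fixed point.
#' @return list with `values` (cleaned signal) and `replaced` (logical
#'   flags of outlier-replaced samples).
#' @export
clean_signal <- function(signal, window = 5L, n_sd = 3, max_pass = 30L) {
  if (length(signal) < window)
    stop_ts("signal shorter than the filter window", class = "insufficient_data")
  if (window %% 2L == 0L) stop_ts("window must be odd", class = "invalid_config")
  h <- window %/% 2L
  n <- length(signal)
  medfilt <- function(z) {
    out <- as.numeric(runmed(z, window, endrule = "keep"))
    for (i in c(seq_len(h), n - seq_len(h) + 1L)) {  # symmetric edge shrink
      hh <- min(h, i - 1L, n - i)
      out[i] <- median(z[(i - hh):(i + hh)])
    }
    out
  }
  x <- as.numeric(signal)
  replaced <- rep(FALSE, n)
  for (pass in seq_len(max_pass)) {
    x_new <- medfilt(x)
    m <- mean(x_new); s <- sd(x_new)
    out <- s > 0 & abs(x_new - m) > n_sd * s
    if (all(out))
      stop_ts("all samples are outliers; signal unrecoverable",
              class = "unrecoverable_signal")
    if (any(out)) {
      valid <- which(!out)
      for (i in which(out)) {
        j <- valid[which.min(abs(valid - i))] # which.min -> earlier on ties
        x_new[i] <- x_new[j]
      }
      replaced <- replaced | out
    }
    done <- identical(x_new, x)
    x <- x_new
    if (done) break
  }
  list(values = x, replaced = replaced)
}
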