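# Standard-format I/O: multi-page float TIFF thermal stacks with a JSON
# sidecar, and CSV signal files.

#' Write a thermal stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float page per frame.  TIFF floats are stored in `[0, 1]`,
#' so temperatures are divided by `scale` (default 100, i.e. degrees C /
#' 100); the sidecar records the scale, the frame rate, timestamps and the
#' per-frame landmarks in 0-based (row, col) pixel convention.
#'
#' @param stack a [thermal_stack()].
#' @param tiff_path,json_path output paths.
#' @param scale temperature divisor for TIFF storage.
#' @return invisibly, the two paths.
#' @export
write_thermal_stack <- function(stack, tiff_path,
                                json_path = sub("\\.tiff?$", ".json", tiff_path),
                                scale = 100) {
  T_ <- dim(stack$frames)[3]
  pages <- lapply(seq_len(T_), function(t) stack$frames[, , t] / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(scale = scale, fs = stack$fs, timestamps = stack$timestamps,
                  pixel_convention = "0-based (row, col)",
                  landmarks = stack$landmarks)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff_path, json_path))
}

#' Read a thermal stack written by [write_thermal_stack()]
#' @param tiff_path,json_path input paths.
#' @return a [thermal_stack()].
#' @export
read_thermal_stack <- function(tiff_path,
                               json_path = sub("\\.tiff?$", ".json", tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  side <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * side$scale
  landmarks <- NULL
  if (!is.null(side$landmarks))
    landmarks <- lapply(side$landmarks, function(lm) lapply(lm, function(p) {
      if (is.list(p[[1]])) do.call(rbind, lapply(p, unlist)) else unlist(p)
    }))
  thermal_stack(frames, fs = side$fs, timestamps = unlist(side$timestamps),
                landmarks = landmarks)
}

#' Write a (time, value) signal CSV
#' @param time_s,values numeric vectors.
#' @param path output path.
#' @param value_name column name for the values.
#' @export
write_signal_csv <- function(time_s, values, path, value_name = "value") {
  df <- data.frame(time_s = time_s, v = values)
  names(df)[2] <- value_name
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a ROI signal set as CSV
#'
#' Columns: `time_s`, one temperature column per ROI label, and one
#' `flag_<label>` column per ROI.
#' @param signals a `roi_signal_set` from [extract_roi_signals()].
#' @param path output path.
#' @export
write_roi_signals_csv <- function(signals, path) {
  df <- data.frame(time_s = signals$time_s, check.names = FALSE)
  for (nm in names(signals$signals)) df[[roi_label(nm)]] <- signals$signals[[nm]]
  for (nm in names(signals$flags))
    df[[paste0("flag_", roi_label(nm))]] <- signals$flags[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
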