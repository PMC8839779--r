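# Pipeline orchestration: per-session feature extraction, feature-table
# assembly with Full / Thermo / No-Thermo views, and a reproducible
# simulate -> extract -> features -> stats -> classify run with a manifest.

#' Thermal features of one session record
#'
#' Full thermal stage: face segmentation of the first frame (temperature
#' thresholds intersected with the contour landmarks), proportional ROI
#' placement, centre tracking, median-signal extraction, cleaning, and the
#' 4 features per ROI signal.
#'
#' @param rec session record from [generate_cohort()] (or any list with a
#'   `thermal` [thermal_stack()] whose landmarks hold the 14 ROI centres
#'   and a `face_contour`).
#' @param area_fraction per-ROI size fraction.
#' @param track use the block-matching tracker (`TRUE`) or static centres.
#' @return named numeric vector of 56 features.
#' @export
session_thermal_features <- function(rec, area_fraction = 0.02, track = TRUE) {
  stack <- rec$thermal
  lm1 <- stack$landmarks[[1]]
  mask <- segment_face(stack$frames[, , 1], contour = lm1$face_contour)
  centres <- lm1[roi_names()]
  rois <- place_rois(centres, mask, area_fraction)
  tracks <- if (track) track_centres(stack, centres) else NULL
  sigset <- extract_roi_signals(stack, rois, tracks)
  cleaned <- lapply(sigset$signals, function(x) clean_signal(x)$values)
  thermal_feature_row(cleaned, stack$fs)
}

# One 75-feature row for a session record (all modalities present).
session_features <- function(rec, config) {
  th <- session_thermal_features(rec, area_fraction = config$area_fraction)
  decomp <- decompose_eda(rec$eda$signal, fs = rec$eda$fs)
  ed <- eda_features(decomp)
  cr <- cardioresp_feature_row(rec$cardio$rr, rec$cardio$resp,
                               rec$cardio$fs_resp, config$session_duration_s)
  c(th, ed, cr)
}

#' Assemble the observations-by-features table
#'
#' Merges per-modality feature tables on the (subject, session) key into
#' one row per session with the class label (1 = Stroop, 2 = Rest).  Every
#' modality must cover exactly the same subject-session pairs, and no pair
#' may appear twice.
#'
#' @param ... per-modality data.frames, each with `subject`, `session`
#'   (`"Rest"`/`"Stroop"`) and feature columns.
#' @return data.frame with `subject`, `session`, `label` and all feature
#'   columns (original column order, names kept verbatim).
#' @export
assemble_feature_table <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  key <- function(df) paste(df$subject, df$session, sep = "/")
  k0 <- key(parts[[1]])
  if (anyDuplicated(k0))
    stop_ts("duplicate subject-session rows: %s",
            paste(unique(k0[duplicated(k0)]), collapse = ", "),
            class = "key_mismatch")
  out <- parts[[1]][order(k0), , drop = FALSE]
  for (p in parts[-1]) {
    kp <- key(p)
    if (anyDuplicated(kp) || length(setdiff(k0, kp)) || length(setdiff(kp, k0)))
      stop_ts("subject-session keys differ across modalities (%s)",
              paste(union(setdiff(k0, kp), setdiff(kp, k0)), collapse = ", "),
              class = "key_mismatch")
    p <- p[match(sort(k0), kp), , drop = FALSE]
    feats <- setdiff(names(p), c("subject", "session"))
    out[, feats] <- p[, feats, drop = FALSE]
  }
  out$label <- ifelse(out$session == "Stroop", 1, 2)
  feats <- setdiff(names(out), c("subject", "session", "label"))
  rownames(out) <- NULL
  out[, c("subject", "session", "label", feats), drop = FALSE]
}

#' Restrict a feature table to a named feature set
#'
#' `"thermo"` keeps exactly the 56 thermal columns, `"nothermo"` the 19
#' autonomic columns (8 EDA + 10 HRV + respiratory frequency), `"full"`
#' everything.
#'
#' @param table assembled feature table.
#' @param set `"full"`, `"thermo"` or `"nothermo"`.
#' @return the table with only the requested feature columns.
#' @export
feature_set_view <- function(table, set = c("full", "thermo", "nothermo")) {
  set <- match.arg(set)
  keep <- intersect(feature_names(set), names(table))
  table[, c(meta_cols, keep), drop = FALSE]
}

#' Compute the feature table of a synthetic cohort
#'
#' Runs the full extraction pipeline (thermal, EDA, cardiorespiratory) on
#' every session.  When given a [cohort_config()], sessions are generated
#' and processed one at a time so only one frame stack is ever held in
#' memory.
#'
#' @param x a `cohort` from [generate_cohort()] or a [cohort_config()].
#' @return assembled feature table (75 feature columns).
#' @export
cohort_feature_table <- function(x) {
  if (inherits(x, "cohort_config")) {
    config <- x
    subj_seeds <- matrix(derive_seeds(config$seed, 2L * config$n_subjects),
                         nrow = 2)
    rows <- list()
    for (i in seq_len(config$n_subjects)) {
      set.seed(subj_seeds[1, i])
      sp <- draw_subject_params(config)
      sess_seeds <- matrix(derive_seeds(subj_seeds[2, i], 8L), nrow = 2)
      for (s in 1:2) {
        session <- c("Rest", "Stroop")[s]
        rec <- generate_session(config, sp, session, sess_seeds[s, ])
        f <- session_features(rec, config)
        rows[[length(rows) + 1L]] <-
          c(list(subject = sprintf("S%02d", i), session = session),
            as.list(f))
      }
    }
  } else {
    stopifnot(inherits(x, "cohort"))
    config <- x$config
    rows <- lapply(x$sessions, function(rec)
      c(list(subject = rec$subject, session = rec$session),
        as.list(session_features(rec, config))))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  assemble_feature_table(df)
}

config_digest <- function(config) {
  raw <- serialize(unclass(config)[c("n_subjects", "session_duration_s",
                                     "fs_thermal", "fs_physio", "frame_size",
                                     "seed", "area_fraction", "motion")],
                   connection = NULL)
  paste0(format(sum(as.integer(raw) * seq_along(raw)) %% 2147483647L),
         "-", length(raw))
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> features -> statistics -> classification, writing
#' every stage output and a run manifest (configuration snapshot, seed,
#' file digests) under `out_dir`.  If a previous run left a feature table
#' with a matching configuration digest, the simulation/extraction stage is
#' reused.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param sets feature sets to classify.
#' @param mode LOSO ranking protocol, see [loso_accuracy_curve()].
#' @return invisibly, a list with `features`, `stats`, `loso` (per set) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         sets = c("full", "thermo", "nothermo"),
                         mode = "paper") {
  stopifnot(inherits(config, "cohort_config"))
  sets <- match.arg(sets, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(out_dir, "features.csv")
  mpath <- file.path(out_dir, "manifest.json")
  dg <- config_digest(config)
  features <- NULL
  if (file.exists(fpath) && file.exists(mpath)) {
    prev <- tryCatch(jsonlite::read_json(mpath), error = function(e) NULL)
    if (!is.null(prev) && identical(prev$config_digest, dg) &&
        identical(unname(tools::md5sum(fpath)), prev$digests$features.csv))
      features <- read.csv(fpath, check.names = FALSE)
  }
  if (is.null(features)) {
    features <- cohort_feature_table(config)
    write.csv(features, fpath, row.names = FALSE)
  }

  stats <- compare_sessions(features)
  write.csv(stats, file.path(out_dir, "stats.csv"), row.names = FALSE)

  loso <- list()
  for (s in sets) {
    view <- feature_set_view(features, s)
    res <- loso_accuracy_curve(view, mode = mode)
    loso[[s]] <- res
    write.csv(res$accuracy, file.path(out_dir, sprintf("accuracy_%s.csv", s)),
              row.names = FALSE)
    if (!is.null(res$ranking))
      write.csv(res$ranking, file.path(out_dir, sprintf("ranking_%s.csv", s)),
                row.names = FALSE)
    jsonlite::write_json(
      list(set = s, mode = mode, best_k = res$best_k,
           max_accuracy = res$max_accuracy,
           confusion_at_best = as.data.frame(res$confusion[[res$best_k]])),
      file.path(out_dir, sprintf("confusion_%s.json", s)),
      auto_unbox = TRUE, digits = NA)
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "thermostress",
    version = as.character(utils::packageVersion("thermostress")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed, config_digest = dg,
    config = unclass(config)[c("n_subjects", "session_duration_s",
                               "fs_thermal", "fs_physio", "frame_size",
                               "seed", "area_fraction", "motion")],
    sets = sets, mode = mode,
    digests = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(features = features, stats = stats, loso = loso,
                 manifest = manifest))
}
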