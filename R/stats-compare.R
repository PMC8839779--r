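# Paired Rest-vs-Stroop comparison of every feature with FDR control.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on `a - b`.  Zero differences are discarded
#' (classic Wilcoxon treatment); the exact null distribution is used for up
#' to `exact_n` non-zero pairs when there are no rank ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_n largest n for which the exact distribution is used.
#' @return list with `W` (sum of positive ranks), `p` (two-sided), `n`
#'   (non-zero pairs), `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_n = 25L) {
  if (length(a) != length(b))
    stop_ts("paired vectors must have equal length", class = "invalid_config")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop_ts("all differences are zero; test undefined", class = "undefined_test")
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- n <= exact_n && !ties
  res <- suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = !use_exact)
  )
  list(W = unname(res$statistic), p = res$p.value, n = n, exact = use_exact)
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' @param p raw p values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `adjusted` (BH-adjusted p values, input order) and
#'   `rejected` (logical).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_ts("p values must lie in [0, 1]", class = "invalid_config")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

#' Compare every feature between Rest and Stroop sessions
#'
#' Runs a paired Wilcoxon signed-rank test per feature across subjects
#' (Rest vs Stroop values of the same subject) and controls the false
#' discovery rate across all features of the call with the
#' Benjamini-Hochberg step-up procedure.  Features whose test is undefined
#' (all differences zero) get `p = NA` and are never rejected.
#'
#' @param table a feature table from [assemble_feature_table()] (or any
#'   data.frame with `subject`, `session` in `c("Rest", "Stroop")` and
#'   feature columns).
#' @param features feature columns to test (default: all).
#' @param alpha FDR level.
#' @return data.frame: `feature`, `W`, `p`, `p_adj`, `rejected`,
#'   `median_rest`, `mad_rest`, `median_stroop`, `mad_stroop`.
#' @export
compare_sessions <- function(table, features = NULL, alpha = 0.05) {
  stopifnot(all(c("subject", "session") %in% names(table)))
  if (is.null(features))
    features <- setdiff(names(table), c("subject", "session", "label"))
  subjects <- unique(table$subject)
  if (length(subjects) < 2L)
    stop_ts("need at least 2 subjects for a paired comparison",
            class = "insufficient_data")
  rest <- table[table$session == "Rest", , drop = FALSE]
  stroop <- table[table$session == "Stroop", , drop = FALSE]
  bad <- subjects[!(subjects %in% rest$subject & subjects %in% stroop$subject)]
  if (length(bad))
    stop_ts("unpaired subject(s): %s", paste(bad, collapse = ", "),
            class = "unpaired_subject")
  rest <- rest[match(subjects, rest$subject), , drop = FALSE]
  stroop <- stroop[match(subjects, stroop$subject), , drop = FALSE]
  res <- lapply(features, function(f) {
    w <- tryCatch(wilcoxon_signed_rank(stroop[[f]], rest[[f]]),
                  thermostress_error = function(e) list(W = NA_real_, p = NA_real_))
    data.frame(feature = f, W = w$W, p = w$p,
               median_rest = median(rest[[f]]), mad_rest = mad(rest[[f]]),
               median_stroop = median(stroop[[f]]), mad_stroop = mad(stroop[[f]]))
  })
  out <- do.call(rbind, res)
  fdr <- bh_fdr(out$p, alpha)
  out$p_adj <- fdr$adjusted
  out$rejected <- !is.na(fdr$rejected) & fdr$rejected
  out[, c("feature", "W", "p", "p_adj", "rejected", "median_rest", "mad_rest",
          "median_stroop", "mad_stroop")]
}
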