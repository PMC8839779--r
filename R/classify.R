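# Two-stage feature selection and subject-independent classification:
# correlation pre-filter, nu-SVM (RBF) recursive feature elimination with
# correlation-bias reduction, leave-one-subject-out evaluation.

meta_cols <- c("subject", "session", "label")

feature_cols <- function(table) setdiff(names(table), meta_cols)

label_factor <- function(label) {
  factor(label, levels = c(1, 2), labels = c("Stroop", "Rest"))
}

check_paired_table <- function(table) {
  stopifnot(all(meta_cols %in% names(table)))
  split_lab <- split(table$label, table$subject)
  bad <- names(split_lab)[vapply(split_lab, function(l)
    length(l) != 2L || length(unique(l)) != 2L, TRUE)]
  if (length(bad))
    stop_ts("subject(s) without exactly one Rest and one Stroop row: %s",
            paste(bad, collapse = ", "), class = "unpaired_subject")
  invisible(table)
}

#' Correlation-based pre-filter of the feature table
#'
#' First selection stage: each feature's Pearson (point-biserial)
#' correlation with the class label is tested and only features with
#' `p <= alpha` are retained, preserving column order.  Zero-variance
#' features are excluded with a warning (their correlation is undefined).
#' If nothing reaches `alpha`, the single smallest-p feature is kept so the
#' downstream classifier is always defined.
#'
#' @param table feature table (`subject`, `session`, `label` + features).
#' @param alpha significance level of the correlation test.
#' @return the table restricted to retained features, with attribute
#'   `filter_p` (named vector of the correlation p values).
#' @export
filter_select <- function(table, alpha = 0.05) {
  feats <- feature_cols(table)
  if (length(feats) < 1L)
    stop_ts("no feature columns", class = "invalid_config")
  if (nrow(table) < 8L)
    stop_ts("need at least 8 observations", class = "insufficient_data")
  y <- as.numeric(table$label)
  pvals <- vapply(feats, function(f) {
    x <- table[[f]]
    if (sd(x) == 0) {
      warning(sprintf("feature '%s' has zero variance; excluded", f))
      return(NA_real_)
    }
    cor.test(x, y)$p.value
  }, 1.0)
  keep <- !is.na(pvals) & pvals <= alpha
  if (!any(keep)) keep[which.min(pvals)] <- TRUE
  out <- table[, c(meta_cols, feats[keep]), drop = FALSE]
  attr(out, "filter_p") <- pvals
  out
}

rbf_kernel_sq <- function(SV) {
  s <- rowSums(SV^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(SV)
  pmax(d2, 0)
}

# ||W||^2 in feature space: sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j),
# with e1071's coefs = alpha_i * y_i for the support vectors.
w2_from_kernel <- function(coefs, K) as.numeric(crossprod(coefs, K %*% coefs))

# Single-linkage clusters over |r| > threshold via union-find.
correlation_clusters <- function(X, threshold) {
  p <- ncol(X)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (p > 1L) {
    R <- suppressWarnings(abs(cor(X)))
    R[!is.finite(R)] <- 0
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      if (R[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  }
  vapply(seq_len(p), find, 1L)
}

#' Recursive feature elimination with a nu-SVM-RBF criterion and
#' correlation-bias reduction
#'
#' Features are removed one per iteration.  At each step a nu-SVM with RBF
#' kernel (`gamma = 1/p` for the current feature count, LIBSVM defaults) is
#' trained on the standardised features, and each feature's criterion is
#' the decrease in the squared weight-vector magnitude when that feature is
#' dropped from the kernel with the dual coefficients held fixed:
#' `c_f = W2 - W2_(-f)` (the retraining-free sensitivity of the margin
#' objective; the feature with the least influence is removed).
#' Correlation-bias reduction (CBR) then corrects the criteria inside
#' clusters of highly correlated features (single linkage over
#' `|r| > cbr_threshold`): mutually redundant features make each other look
#' dispensable one at a time, so the cluster's joint contribution
#' `W2 - W2_(-cluster)` is evaluated by removing the whole cluster from
#' the kernel, and each member's criterion is raised to at least its equal
#' share of that joint contribution.  The minimum-criterion feature is then
#' eliminated (ties broken by original column order); the feature
#' eliminated last has rank 1.
#'
#' @param table feature table (typically after [filter_select()]).
#' @param nu nu-SVM margin parameter.
#' @param cbr apply correlation-bias reduction?
#' @param cbr_threshold absolute-correlation clustering threshold.
#' @return data.frame with `rank`, `feature`, `criterion` (criterion value
#'   at the step the feature was eliminated; `NA` for rank 1), and
#'   attribute `clusters` (initial cluster assignment of each feature).
#' @export
svm_rfe_cbr_rank <- function(table, nu = 0.5, cbr = TRUE, cbr_threshold = 0.7) {
  feats <- feature_cols(table)
  X0 <- scale(as.matrix(table[, feats, drop = FALSE]))
  y <- label_factor(table$label)
  clusters0 <- correlation_clusters(X0, cbr_threshold)
  names(clusters0) <- feats
  remaining <- feats
  eliminated <- character(0)
  crit_at_elim <- numeric(0)
  step_i <- 0L
  while (length(remaining) > 1L) {
    step_i <- step_i + 1L
    X <- X0[, remaining, drop = FALSE]
    p <- ncol(X)
    fit <- tryCatch(
      e1071::svm(X, y, type = "nu-classification", kernel = "radial",
                 gamma = 1 / p, nu = nu, scale = FALSE),
      error = function(e) stop_ts(
        "SVM training failed at elimination step %d (%d features): %s",
        step_i, p, conditionMessage(e), class = "ranking_error"))
    coefs <- fit$coefs[, 1]
    SV <- as.matrix(fit$SV)
    D2 <- rbf_kernel_sq(SV)
    K <- exp(-(1 / p) * D2)
    W2 <- w2_from_kernel(coefs, K)
    crit <- vapply(seq_len(p), function(f) {
      d2f <- outer(SV[, f], SV[, f], "-")^2
      W2 - w2_from_kernel(coefs, K * exp((1 / p) * d2f))
    }, 1.0)
    if (cbr && p > 2L) {
      cl <- correlation_clusters(X, cbr_threshold)
      for (g in unique(cl)) {
        mem <- which(cl == g)
        if (length(mem) > 1L) {
          d2C <- Reduce(`+`, lapply(mem, function(f)
            outer(SV[, f], SV[, f], "-")^2))
          share <- (W2 - w2_from_kernel(coefs, K * exp((1 / p) * d2C))) /
            length(mem)
          crit[mem] <- pmax(crit[mem], share)
        }
      }
    }
    drop_i <- which.min(crit)          # first index on ties = column order
    eliminated <- c(eliminated, remaining[drop_i])
    crit_at_elim <- c(crit_at_elim, crit[drop_i])
    remaining <- remaining[-drop_i]
  }
  ranking <- c(remaining, rev(eliminated))
  out <- data.frame(rank = seq_along(ranking), feature = ranking,
                    criterion = c(NA_real_, rev(crit_at_elim)))
  attr(out, "clusters") <- clusters0
  out
}

scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sg, "/"),
       test = sweep(sweep(test, 2, mu), 2, sg, "/"))
}

#' Leave-one-subject-out accuracy as a function of feature rank
#'
#' For each fold, all observations of one subject form the test set and
#' everything else the training set; both sessions of a subject therefore
#' always share a fold.  For every cut-off `k`, a nu-SVM-RBF is trained on
#' the top-`k` ranked features (z-scored with training-fold statistics) and
#' the held-out sessions are predicted.  Two ranking protocols:
#'
#' * `"paper"`: the correlation filter and the RFE ranking are computed
#'   once on the full table, then only the SVM is refit per fold — this
#'   reconstructs a single accuracy-vs-rank curve over one ranked axis.
#' * `"strict"`: filter and ranking are recomputed inside every training
#'   fold, so the test subject never influences feature selection
#'   (leakage-free); at cut-off `k` each fold uses its own top `k`.
#'
#' @param table feature table (unfiltered; the filter stage runs inside).
#' @param mode ranking protocol, `"paper"` or `"strict"`.
#' @param nu,cbr,cbr_threshold passed to [svm_rfe_cbr_rank()].
#' @param alpha filter significance level.
#' @return object of class `loso_result`: `accuracy` (data.frame `k`,
#'   `accuracy`), `best_k`, `max_accuracy`, `confusion` (per-`k` list of
#'   2x2 row-percentage matrices, rows = actual Stroop/Rest),
#'   `predictions`, `ranking` (`"paper"` mode), `mode`.
#' @export
loso_accuracy_curve <- function(table, mode = c("paper", "strict"), nu = 0.5,
                                cbr = TRUE, cbr_threshold = 0.7, alpha = 0.05) {
  mode <- match.arg(mode)
  check_paired_table(table)
  subjects <- unique(table$subject)
  if (length(subjects) < 4L)
    stop_ts("need at least 4 subjects for LOSO", class = "insufficient_data")
  y_all <- label_factor(table$label)

  global_ranking <- NULL
  if (mode == "paper") {
    filtered <- filter_select(table, alpha = alpha)
    global_ranking <- svm_rfe_cbr_rank(filtered, nu = nu, cbr = cbr,
                                       cbr_threshold = cbr_threshold)
  }
  fold_rankings <- lapply(subjects, function(s) {
    if (mode == "paper") return(global_ranking$feature)
    train <- table[table$subject != s, , drop = FALSE]
    f <- filter_select(train, alpha = alpha)
    svm_rfe_cbr_rank(f, nu = nu, cbr = cbr, cbr_threshold = cbr_threshold)$feature
  })
  p_max <- max(lengths(fold_rankings))
  preds <- matrix(NA_character_, nrow = p_max, ncol = nrow(table))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    te <- which(table$subject == s)
    tr <- which(table$subject != s)
    stopifnot(length(intersect(te, tr)) == 0L)   # grouping invariant
    rk <- fold_rankings[[si]]
    for (k in seq_len(p_max)) {
      use <- rk[seq_len(min(k, length(rk)))]
      sc <- scale_train_test(as.matrix(table[tr, use, drop = FALSE]),
                             as.matrix(table[te, use, drop = FALSE]))
      fit <- e1071::svm(sc$train, y_all[tr], type = "nu-classification",
                        kernel = "radial", gamma = 1 / length(use), nu = nu,
                        scale = FALSE)
      preds[k, te] <- as.character(predict(fit, sc$test))
    }
  }
  actual <- as.character(y_all)
  acc <- vapply(seq_len(p_max), function(k) mean(preds[k, ] == actual), 1.0)
  confusion <- lapply(seq_len(p_max), function(k) {
    m <- sapply(c("Stroop", "Rest"), function(cls) {
      idx <- actual == cls
      100 * c(mean(preds[k, idx] == "Stroop"), mean(preds[k, idx] == "Rest"))
    })
    m <- t(m)
    dimnames(m) <- list(actual = c("Stroop", "Rest"),
                        predicted = c("Stroop", "Rest"))
    m
  })
  best_k <- which.max(acc)
  structure(list(accuracy = data.frame(k = seq_len(p_max), accuracy = acc),
                 best_k = best_k, max_accuracy = acc[best_k],
                 confusion = confusion, predictions = preds,
                 actual = actual, subjects = table$subject,
                 ranking = global_ranking, mode = mode),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> mode '%s': max accuracy %.2f%% at k = %d of %d\n",
              x$mode, 100 * x$max_accuracy, x$best_k, nrow(x$accuracy)))
  invisible(x)
}

#' Accuracy and error rates from a confusion matrix
#'
#' Accepts either per-class percentage rates (rows summing to 100) or raw
#' counts, rows = actual class (stress first), columns = predicted.
#' Accuracy is total correct over total observations — with equal class
#' sizes, the mean of the diagonal percentages.  The type-II error is the
#' stress-row false-negative percentage.
#'
#' @param m 2x2 matrix, rows = actual `c("S", "N-S")`, columns = predicted.
#' @param class_sizes observations per actual class (length 2).
#' @param rates `TRUE` if `m` holds row percentages, `FALSE` for counts.
#' @param tol row-sum check tolerance.
#' @return list with `accuracy` (%), `per_class_error` (%, named),
#'   `type_II` (%), `counts`.
#' @export
evaluate_confusion <- function(m, class_sizes, rates = TRUE, tol = 0.02) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2L, 2L)), length(class_sizes) == 2L)
  if (any(m < 0) || any(class_sizes <= 0))
    stop_ts("negative rates/counts or empty class", class = "invalid_config")
  if (rates) {
    if (any(abs(rowSums(m) - 100) > tol))
      stop_ts("confusion rows must sum to 100%%", class = "invalid_config")
    counts <- m / 100 * class_sizes
  } else {
    if (any(abs(rowSums(m) - class_sizes) > tol))
      stop_ts("confusion rows must sum to their class totals",
              class = "invalid_config")
    counts <- m
  }
  accuracy <- 100 * sum(diag(counts)) / sum(class_sizes)
  per_class_error <- 100 * (1 - diag(counts) / class_sizes)
  names(per_class_error) <- c("S", "N-S")
  list(accuracy = accuracy, per_class_error = per_class_error,
       type_II = per_class_error[["S"]], counts = counts)
}

#' Two-sided binomial confidence band around chance accuracy
#'
#' Normal-approximation band for the proportion of correct predictions
#' expected from a chance-level classifier on `n` observations.
#'
#' @param n observation count.
#' @param p chance level.
#' @param conf coverage.
#' @return numeric `c(lower, upper)`.
#' @export
binomial_band <- function(n, p = 0.5, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = p - half, upper = p + half)
}
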