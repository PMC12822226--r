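#' Fit a nearest-centroid classifier
#'
#' Features are z-scored on the training data (the scaling statistics are
#' stored for reuse at prediction time) and each class centroid is the mean
#' profile of the training samples of that class.
#'
#' @param m imputed training matrix.
#' @param y class labels aligned with rows (every class needs >= 1 sample).
#' @return a `centroid_model` with `centroids` (classes x features),
#'   `classes` (prediction tie-break order), and `stats` (scaling).
#' @export
centroid_fit <- function(m, y) {
  check_matrix(m, allow_missing = FALSE)
  y <- droplevels(as.factor(y))
  if (length(y) != nrow(m)) stop("labels must align with matrix rows")
  if (any(table(y) == 0L)) stop("empty class")
  sc <- zscore_scale(m)
  z <- sc$matrix
  classes <- levels(y)
  centroids <- t(vapply(classes, function(c) colMeans(z[y == c, , drop = FALSE]),
                        numeric(ncol(z))))
  rownames(centroids) <- classes
  structure(list(centroids = centroids, classes = classes, stats = sc$stats),
            class = "centroid_model")
}

#' Predict with a nearest-centroid model
#'
#' Samples are scaled with the stored training statistics and assigned to
#' the class whose centroid is closest in Euclidean distance; exact ties go
#' to the first class in the stored class order.
#'
#' @param model a `centroid_model` from [centroid_fit()].
#' @param m matrix with the same features as the training data.
#' @return factor of predicted labels with the model's class levels.
#' @export
centroid_predict <- function(model, m) {
  check_matrix(m, allow_missing = FALSE)
  if (!setequal(colnames(m), model$stats$feature_id) ||
      ncol(m) != nrow(model$stats)) {
    stop("feature set does not match the fitted model")
  }
  m <- m[, model$stats$feature_id, drop = FALSE]
  z <- zscore_scale(m, stats = model$stats)$matrix
  cent <- model$centroids[, model$stats$feature_id, drop = FALSE]
  # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
  cross <- z %*% t(cent)
  d2 <- matrix(rowSums(z^2), nrow(z), nrow(cent)) - 2 * cross +
    matrix(rowSums(cent^2), nrow(z), nrow(cent), byrow = TRUE)
  pick <- apply(d2, 1L, which.min)  # which.min takes the first on ties
  factor(model$classes[pick], levels = model$classes)
}

#' Confusion matrix
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param classes class order; defaults to the sorted union of levels. Any
#'   label outside `classes` is an error.
#' @return integer matrix `counts[true, pred]` with class dimnames.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("prediction length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tab <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- matrix(as.integer(tab), length(classes), length(classes),
               dimnames = list(true = classes, pred = classes))
  cm
}

#' Row-normalize a confusion matrix
#'
#' Each row (true class) is divided by its total so entries read as per-class
#' rates; rows with zero count stay zero, with a warning.
#'
#' @param cm confusion matrix from [confusion()].
#' @return real matrix whose non-empty rows sum to 1.
#' @export
row_normalize <- function(cm) {
  totals <- rowSums(cm)
  if (any(totals == 0)) {
    warning("class(es) with no true samples left as zero rows: ",
            paste(rownames(cm)[totals == 0], collapse = ", "))
  }
  out <- cm / ifelse(totals == 0, 1, totals)
  out
}

#' Binary metrics from a confusion matrix
#'
#' One-vs-rest reduction against the given positive class, then
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R),
#' accuracy = correct/total. Zero denominators yield 0 with a warning.
#'
#' @param cm confusion matrix.
#' @param positive name of the positive class.
#' @return list with `precision`, `recall`, `f1`, `accuracy`.
#' @export
basic_metrics <- function(cm, positive) {
  if (!positive %in% rownames(cm)) stop("unknown positive class: ", positive)
  tp <- cm[positive, positive]
  fp <- sum(cm[, positive]) - tp
  fn <- sum(cm[positive, ]) - tp
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (precision + recall = 0); reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = sum(diag(cm)) / sum(cm))
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what))
    return(0)
  }
  num / den
}

#' Multiclass Matthews correlation coefficient
#'
#' Covariance-form generalization over the confusion matrix:
#' \deqn{MCC = \frac{c \cdot s - \sum_k p_k t_k}
#'   {\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}}
#' with \eqn{c} the trace, \eqn{s} the total, and \eqn{t_k}/\eqn{p_k} the
#' row/column sums. A zero denominator (a degenerate matrix) yields 0.
#'
#' @param cm confusion matrix.
#' @return value in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Rank-based AUC (Mann-Whitney, ties averaged)
#'
#' @param scores numeric score vector (higher = more positive).
#' @param positive logical vector marking the positive class.
#' @return AUC in `[0, 1]`, or `NA` when either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest expected calibration error
#'
#' Probabilities are cut into `n_bins` equal-width bins on `[0, 1]`; the ECE
#' is the count-weighted mean absolute gap between mean predicted
#' probability and observed positive frequency over non-empty bins.
#'
#' @param prob predicted positive-class probabilities.
#' @param positive logical outcome vector.
#' @param n_bins number of equal-width bins (default 10).
#' @return list with `ece` and a `curve` data frame (`bin_mid`, `mean_prob`,
#'   `obs_freq`, `count`).
#' @export
calibration_ece <- function(prob, positive, n_bins = 10L) {
  positive <- as.logical(positive)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(prob, breaks = edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    in_bin <- bin == b
    n_b <- sum(in_bin)
    if (n_b == 0L) return(NULL)
    data.frame(bin_mid = mids[b], mean_prob = mean(prob[in_bin]),
               obs_freq = mean(positive[in_bin]), count = n_b)
  })
  curve <- do.call(rbind, rows)
  ece <- sum(curve$count / length(prob) * abs(curve$obs_freq - curve$mean_prob))
  list(ece = ece, curve = curve)
}

#' Full multi-class metrics report
#'
#' Computes the evaluation surface for a probabilistic multi-class
#' classifier: overall accuracy, per-class and macro precision/recall/F1,
#' balanced accuracy (mean per-class recall), multiclass MCC, macro
#' one-vs-rest rank-based AUC (classes absent from `y_true` are skipped with
#' a warning), and macro expected calibration error with 10 equal-width
#' one-vs-rest bins, plus the per-class calibration curves.
#'
#' @param y_true true labels.
#' @param probs samples x classes probability matrix with class colnames;
#'   rows must sum to 1 within `1e-6`.
#' @param y_pred optional predicted labels; defaults to the argmax of
#'   `probs` (ties to the first class in column order).
#' @param n_bins calibration bins (default 10).
#' @return a `metrics_report` list: `confusion`, `confusion_normalized`,
#'   `accuracy`, `per_class` (data frame), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `balanced_accuracy`, `mcc`, `macro_auc_ovr`, `macro_ece`,
#'   `calibration` (per-class curves).
#' @export
multiclass_metrics <- function(y_true, probs, y_pred = NULL, n_bins = 10L) {
  if (!is.matrix(probs) || is.null(colnames(probs))) {
    stop("'probs' must be a matrix with class colnames")
  }
  if (length(y_true) != nrow(probs)) stop("y_true must align with probs rows")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 (within 1e-6)")
  }
  classes <- colnames(probs)
  y_true <- as.character(y_true)
  if (is.null(y_pred)) {
    y_pred <- classes[apply(probs, 1L, which.max)]
  } else {
    y_pred <- as.character(y_pred)
  }
  cm <- confusion(y_true, y_pred, classes = classes)

  per_class <- do.call(rbind, lapply(classes, function(c) {
    bm <- suppressWarnings(basic_metrics(cm, positive = c))
    data.frame(class = c, precision = bm$precision, recall = bm$recall,
               f1 = bm$f1, stringsAsFactors = FALSE)
  }))

  present <- classes[classes %in% y_true]
  if (length(present) < length(classes)) {
    warning("class(es) absent from y_true skipped for AUC/balanced accuracy: ",
            paste(setdiff(classes, present), collapse = ", "))
  }
  recalls <- per_class$recall[per_class$class %in% present]
  aucs <- vapply(present, function(c) auc_rank(probs[, c], y_true == c), numeric(1))
  cal <- lapply(stats::setNames(present, present), function(c) {
    calibration_ece(probs[, c], y_true == c, n_bins = n_bins)
  })
  eces <- vapply(cal, `[[`, numeric(1), "ece")

  structure(list(
    confusion = cm,
    confusion_normalized = suppressWarnings(row_normalize(cm)),
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_class,
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1),
    balanced_accuracy = mean(recalls),
    mcc = mcc_multiclass(cm),
    macro_auc_ovr = mean(aucs),
    macro_ece = mean(eces),
    calibration = lapply(cal, `[[`, "curve")
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy           %.4f\n", x$accuracy))
  cat(sprintf("  balanced accuracy  %.4f\n", x$balanced_accuracy))
  cat(sprintf("  macro F1           %.4f\n", x$macro_f1))
  cat(sprintf("  MCC                %.4f\n", x$mcc))
  cat(sprintf("  macro AUC (OvR)    %.4f\n", x$macro_auc_ovr))
  cat(sprintf("  macro ECE          %.4f\n", x$macro_ece))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Scalar metrics, the per-class table, the raw and row-normalized confusion
#' matrices, and the calibration curves.
#'
#' @param report a `metrics_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  obj <- list(
    accuracy = report$accuracy,
    balanced_accuracy = report$balanced_accuracy,
    macro_precision = report$macro_precision,
    macro_recall = report$macro_recall,
    macro_f1 = report$macro_f1,
    mcc = report$mcc,
    macro_auc_ovr = report$macro_auc_ovr,
    macro_ece = report$macro_ece,
    per_class = report$per_class,
    confusion = list(classes = rownames(report$confusion),
                     counts = unname(apply(report$confusion, 1L, as.integer,
                                           simplify = FALSE)),
                     row_normalized = unname(apply(report$confusion_normalized,
                                                   1L, as.numeric,
                                                   simplify = FALSE))),
    calibration = report$calibration
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
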