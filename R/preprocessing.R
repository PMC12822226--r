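#' Per-feature and per-sample missingness
#'
#' @param m omics matrix (missing values allowed).
#' @return list with numeric vectors `feature` and `sample`: the fraction of
#'   missing cells per column and per row.
#' @examples
#' m <- omics_matrix(matrix(c(1, NA, 3, 4), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2"))))
#' compute_missingness(m)$feature
#' @export
compute_missingness <- function(m) {
  check_matrix(m)
  na <- is.na(m)
  list(feature = colMeans(na), sample = rowMeans(na))
}

#' Drop features exceeding a missingness threshold
#'
#' Applied before imputation so that features observed in too few samples do
#' not contaminate nearest-neighbour estimates.
#'
#' @param m omics matrix.
#' @param max_rate maximum tolerated per-feature missing fraction (default
#'   0.5); features with a strictly greater rate are removed.
#' @return the filtered matrix, feature order preserved.
#' @export
filter_missing_features <- function(m, max_rate = 0.5) {
  check_matrix(m)
  stopifnot(max_rate >= 0, max_rate <= 1)
  keep <- colMeans(is.na(m)) <= max_rate
  if (!any(keep)) stop("no features left after missingness filtering")
  m[, keep, drop = FALSE]
}

# Population variance per column over observed values.
col_pop_var <- function(m) {
  n_obs <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  ss <- colSums(sweep(m, 2L, mu, "-")^2, na.rm = TRUE)
  v <- ss / n_obs
  v[n_obs == 0L] <- NA_real_
  v
}

#' Remove zero-variance features
#'
#' Variance is the population variance over observed values; the test is
#' exact (a feature is dropped iff every observed value is identical).
#'
#' @param m omics matrix.
#' @return matrix containing only features with variance > 0, order preserved.
#' @export
drop_zero_variance <- function(m) {
  check_matrix(m)
  keep <- col_pop_var(m) > 0
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no informative features: all features have zero variance")
  m[, keep, drop = FALSE]
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean of the feature over the `k`
#' samples nearest to the incomplete sample. Distance between two samples is
#' the root mean squared difference over their mutually observed features,
#' which keeps distances comparable across pairs with different overlap.
#' Only samples with the target feature observed are eligible neighbours.
#' Observed cells are never altered.
#'
#' @param m omics matrix with missing values.
#' @param k number of neighbours (default 5); must satisfy `k < nrow(m)`.
#' @return completed matrix with no missing entries.
#' @export
knn_impute <- function(m, k = 5L) {
  check_matrix(m)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(m)
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of samples (%d)", k, n))
  fully_missing <- colSums(!is.na(m)) == 0L
  if (any(fully_missing)) {
    stop("feature(s) fully missing: ", paste(colnames(m)[fully_missing], collapse = ", "))
  }
  if (!anyNA(m)) return(m)

  obs <- !is.na(m)
  out <- m
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    oi <- obs[i, ]
    # squared distances to every other sample over mutually observed features
    others <- setdiff(seq_len(n), i)
    d2 <- rep(NA_real_, n)
    for (j in others) {
      shared <- oi & obs[j, ]
      ns <- sum(shared)
      if (ns > 0L) d2[j] <- sum((m[i, shared] - m[j, shared])^2) / ns
    }
    for (jcol in which(!oi)) {
      cand <- which(obs[, jcol] & !is.na(d2))
      if (length(cand) == 0L) {
        stop("cannot impute feature '", colnames(m)[jcol],
             "' for sample '", rownames(m)[i], "': no comparable neighbour")
      }
      nb <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, jcol] <- mean(m[nb, jcol])
    }
  }
  out
}

#' Log2 transform
#'
#' Applies `log2(x + offset)` elementwise to reduce the right skew of
#' expression-scale data.
#'
#' @param m omics matrix with all values >= 0.
#' @param offset nonnegative pseudo-count added before the log (default 1).
#' @return transformed matrix.
#' @export
log2_transform <- function(m, offset = 1) {
  check_matrix(m)
  stopifnot(offset >= 0)
  neg <- colSums(m < 0, na.rm = TRUE) > 0
  if (any(neg)) {
    stop("negative values in feature(s): ", paste(colnames(m)[neg], collapse = ", "))
  }
  out <- log2(m + offset)
  attr(out, "omics_tag") <- attr(m, "omics_tag", exact = TRUE)
  out
}

#' Z-score scaling with train/test discipline
#'
#' Standardizes each feature to mean 0 and unit population standard
#' deviation. When `stats` is supplied (learned on training data) it is
#' applied as-is, so test data are scaled on the training scale. Features
#' with zero standard deviation map to 0.
#'
#' @param m imputed omics matrix.
#' @param stats optional scaling statistics from a previous call (a
#'   `scaling_stats` data frame with columns `feature_id`, `mean`, `sd`).
#' @return list with elements `matrix` (scaled) and `stats` (the statistics
#'   used, reusable on new data).
#' @export
zscore_scale <- function(m, stats = NULL) {
  check_matrix(m, allow_missing = FALSE)
  if (is.null(stats)) {
    mu <- colMeans(m)
    sd <- sqrt(colMeans(sweep(m, 2L, mu, "-")^2))
    stats <- data.frame(feature_id = colnames(m), mean = mu, sd = sd,
                        row.names = NULL, stringsAsFactors = FALSE)
    class(stats) <- c("scaling_stats", class(stats))
  } else {
    if (!all(c("feature_id", "mean", "sd") %in% names(stats))) {
      stop("'stats' must have columns feature_id, mean, sd")
    }
    if (!setequal(stats$feature_id, colnames(m)) ||
        length(stats$feature_id) != ncol(m)) {
      stop("scaling stats feature set does not match the matrix")
    }
    stats <- stats[match(colnames(m), stats$feature_id), , drop = FALSE]
    mu <- stats$mean
    sd <- stats$sd
  }
  scaled <- sweep(m, 2L, mu, "-")
  denom <- ifelse(sd > 0, sd, 1)
  scaled <- sweep(scaled, 2L, denom, "/")
  scaled[, sd == 0] <- 0
  attr(scaled, "omics_tag") <- attr(m, "omics_tag", exact = TRUE)
  list(matrix = scaled, stats = stats)
}

#' Write/read scaling statistics as JSON
#'
#' Serialized as `{feature_id: {mean, sd}}` so trained scalers can be reused
#' across runs.
#'
#' @param stats a `scaling_stats` data frame.
#' @param path JSON file path.
#' @return `path` (write) or the stats data frame (read).
#' @export
write_scaling_stats <- function(stats, path) {
  obj <- lapply(seq_len(nrow(stats)), function(i) {
    list(mean = stats$mean[i], sd = stats$sd[i])
  })
  names(obj) <- stats$feature_id
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling_stats
#' @export
read_scaling_stats <- function(path) {
  obj <- jsonlite::read_json(path)
  stats <- data.frame(
    feature_id = names(obj),
    mean = vapply(obj, function(x) as.numeric(x$mean), numeric(1)),
    sd = vapply(obj, function(x) as.numeric(x$sd), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(stats) <- c("scaling_stats", class(stats))
  stats
}

#' Match an omics matrix to clinical labels
#'
#' Retains the samples present in both the matrix and the clinical table and,
#' if `keep_labels` is given, whose label is among the allowed set (e.g. the
#' Stage I / Stage II restriction of a staging task).
#'
#' @param m omics matrix.
#' @param clinical data frame with `sample_id` and `label` columns.
#' @param keep_labels optional character vector of labels to keep.
#' @return list with `matrix` (matched rows) and `labels` (factor in matrix
#'   row order).
#' @export
match_clinical <- function(m, clinical, keep_labels = NULL) {
  check_matrix(m)
  if (!all(c("sample_id", "label") %in% names(clinical))) {
    stop("clinical table must have 'sample_id' and 'label' columns")
  }
  idx <- match(rownames(m), clinical$sample_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlap between matrix samples and clinical table")
  labels <- clinical$label[idx]
  if (!is.null(keep_labels)) keep <- keep & labels %in% keep_labels
  if (!any(keep)) stop("no samples left after restricting to the requested labels")
  list(matrix = m[keep, , drop = FALSE], labels = factor(labels[keep]))
}

#' Align a matrix to a trained feature list
#'
#' Reorders columns to exactly match `trained_features`; features absent from
#' the matrix are filled with `fill` (zero-fill keeps a trained model's input
#' layout valid on an external cohort measuring fewer features), and features
#' not in the list are dropped.
#'
#' @param m omics matrix.
#' @param trained_features ordered character vector of feature ids.
#' @param fill value used for absent features (default 0).
#' @return list with `matrix` (columns == `trained_features`, in order),
#'   `n_filled` (number of absent features), and `filled_features` (their ids).
#' @export
align_to_feature_list <- function(m, trained_features, fill = 0) {
  check_matrix(m)
  trained_features <- as.character(trained_features)
  if (anyDuplicated(trained_features)) stop("trained feature list contains duplicates")
  idx <- match(trained_features, colnames(m))
  absent <- is.na(idx)
  out <- matrix(fill, nrow = nrow(m), ncol = length(trained_features),
                dimnames = list(rownames(m), trained_features))
  if (any(!absent)) out[, !absent] <- m[, idx[!absent], drop = FALSE]
  if (all(absent)) {
    warning("none of the trained features are present in the matrix; all columns filled")
  }
  attr(out, "omics_tag") <- attr(m, "omics_tag", exact = TRUE)
  list(matrix = out, n_filled = sum(absent), filled_features = trained_features[absent])
}
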