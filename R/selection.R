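#' Ordered feature set
#'
#' @param features ordered character vector of feature ids (no duplicates).
#' @param name set name.
#' @param provenance how the set was produced: `"sdcfe"`, `"importance"`, or
#'   `"manual"`.
#' @return a `feature_set` list with elements `name`, `features`,
#'   `provenance`.
#' @export
feature_set <- function(features, name = "set",
                        provenance = c("manual", "sdcfe", "importance")) {
  provenance <- match.arg(provenance)
  features <- as.character(features)
  if (anyDuplicated(features)) stop("feature set contains duplicate ids")
  structure(list(name = name, features = features, provenance = provenance),
            class = "feature_set")
}

#' @export
length.feature_set <- function(x) length(x$features)

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s' (%s): %d features>\n",
              x$name, x$provenance, length(x$features)))
  invisible(x)
}

#' Default gradient-boosting configuration
#'
#' Hyperparameters for the tree-booster importance ranking: 200 estimators,
#' maximum depth 5, learning rate 0.1, row subsample 0.8, column subsample
#' per tree 0.8, log-loss evaluation, fixed seed 42.
#'
#' @param n_estimators,max_depth,learning_rate,subsample,colsample_bytree,seed
#'   booster hyperparameters.
#' @param objective `"multiclass_softprob"` or `"binary_logistic"`.
#' @param eval_metric evaluation metric name.
#' @return a `booster_config` list.
#' @export
booster_config <- function(n_estimators = 200L, max_depth = 5L,
                           learning_rate = 0.1, subsample = 0.8,
                           colsample_bytree = 0.8, seed = 42L,
                           objective = c("multiclass_softprob", "binary_logistic"),
                           eval_metric = "logloss") {
  objective <- match.arg(objective)
  stopifnot(n_estimators > 0, max_depth > 0, learning_rate > 0,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample_bytree = colsample_bytree, seed = as.integer(seed),
                 objective = objective, eval_metric = eval_metric),
            class = "booster_config")
}

#' Importance-based feature ranking via gradient boosting
#'
#' Adapter around the xgboost tree booster: a classifier is trained with the
#' configured hyperparameters and the features with positive total-gain
#' importance are returned in descending importance order. The booster
#' itself is an external dependency; this module owns only the retention
#' rule (importance > 0), the ordering, and the set contract.
#'
#' @param m imputed omics matrix.
#' @param y class labels aligned with rows.
#' @param cfg a [booster_config()].
#' @return a [feature_set()] with provenance `"importance"` and an
#'   `importance` attribute holding the per-feature gain values.
#' @export
importance_rank <- function(m, y, cfg = booster_config()) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("importance_rank() needs the optional dependency 'xgboost'; ",
         "install it with install.packages(\"xgboost\")")
  }
  check_matrix(m, allow_missing = FALSE)
  y <- droplevels(as.factor(y))
  if (length(y) != nrow(m)) stop("labels must align with matrix rows")
  n_class <- nlevels(y)
  params <- list(max_depth = cfg$max_depth, eta = cfg$learning_rate,
                 subsample = cfg$subsample,
                 colsample_bytree = cfg$colsample_bytree,
                 eval_metric = cfg$eval_metric, nthread = 1L,
                 seed = cfg$seed)
  if (cfg$objective == "binary_logistic") {
    if (n_class != 2L) stop("binary objective requires exactly 2 classes")
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- n_class
    params$eval_metric <- "mlogloss"
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  dtrain <- xgboost::xgb.DMatrix(unname(m), label = as.integer(y) - 1L)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = cfg$n_estimators, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  if (is.null(imp) || nrow(imp) == 0L) {
    fs <- feature_set(character(0), name = "importance_positive",
                      provenance = "importance")
    attr(fs, "importance") <- numeric(0)
    return(fs)
  }
  # xgb.DMatrix built from an unnamed matrix yields positional feature names
  pos <- suppressWarnings(as.integer(sub("^f", "", imp$Feature)))
  ids <- if (all(!is.na(pos))) colnames(m)[pos + 1L] else imp$Feature
  gain <- imp$Gain
  keep <- gain > 0
  ord <- order(-gain[keep], ids[keep])
  fs <- feature_set(ids[keep][ord], name = "importance_positive",
                    provenance = "importance")
  attr(fs, "importance") <- stats::setNames(gain[keep][ord], ids[keep][ord])
  fs
}

#' Intersection of two feature sets with Venn counts
#'
#' @param a,b [feature_set()] objects (or character vectors).
#' @return list with `shared` (a [feature_set()] in `a`'s order) and `venn`
#'   (list `only_a`, `only_b`, `shared`, `union` satisfying
#'   `union == only_a + only_b + shared`).
#' @export
intersect_sets <- function(a, b) {
  fa <- as_feature_ids(a); fb <- as_feature_ids(b)
  shared_ids <- fa[fa %in% fb]
  venn <- list(only_a = length(fa) - length(shared_ids),
               only_b = length(fb) - length(shared_ids),
               shared = length(shared_ids),
               union = length(fa) + length(fb) - length(shared_ids))
  list(shared = feature_set(shared_ids, name = "shared", provenance = "manual"),
       venn = venn)
}

#' Non-redundant union of two feature sets
#'
#' @param a,b [feature_set()] objects (or character vectors).
#' @return a [feature_set()] containing `a`'s features followed by `b`'s
#'   features not already present (deterministic A-first order).
#' @export
nonredundant_union <- function(a, b) {
  fa <- as_feature_ids(a); fb <- as_feature_ids(b)
  feature_set(c(fa, fb[!fb %in% fa]), name = "union", provenance = "manual")
}

as_feature_ids <- function(x) {
  if (inherits(x, "feature_set")) x$features else as.character(x)
}

#' Late fusion of two omics matrices
#'
#' Concatenates per-omics selected feature columns on the samples present in
#' both matrices (fusion after independent per-omics selection). Columns are
#' namespaced with an omics prefix (`rna:ID`, `meth:ID`, ...) so the same
#' identifier appearing in both assays stays distinguishable.
#'
#' @param a,b omics matrices sharing at least one sample id.
#' @param feats_a,feats_b selected features, each present in its matrix.
#' @param tag_a,tag_b column prefixes; default to each matrix's `omics_tag`
#'   (with `"methylation"` shortened to `"meth"`).
#' @return list with `matrix` (fused, rows = shared samples in `a`'s order),
#'   `counts` (selected feature count per omics), and `samples`.
#' @export
late_fusion <- function(a, feats_a, b, feats_b,
                        tag_a = NULL, tag_b = NULL) {
  check_matrix(a, what = "a"); check_matrix(b, what = "b")
  fa <- as_feature_ids(feats_a); fb <- as_feature_ids(feats_b)
  miss_a <- setdiff(fa, colnames(a)); miss_b <- setdiff(fb, colnames(b))
  if (length(miss_a)) stop("selected feature(s) absent from matrix a: ",
                           paste(miss_a, collapse = ", "))
  if (length(miss_b)) stop("selected feature(s) absent from matrix b: ",
                           paste(miss_b, collapse = ", "))
  samples <- rownames(a)[rownames(a) %in% rownames(b)]
  if (length(samples) == 0L) stop("the two matrices share no sample ids")
  if (is.null(tag_a)) tag_a <- short_tag(omics_tag(a, "rna"))
  if (is.null(tag_b)) tag_b <- short_tag(omics_tag(b, "methylation"))
  fused <- cbind(a[samples, fa, drop = FALSE], b[samples, fb, drop = FALSE])
  colnames(fused) <- c(paste0(tag_a, ":", fa), paste0(tag_b, ":", fb))
  attr(fused, "omics_tag") <- "fused"
  counts <- stats::setNames(c(length(fa), length(fb)), c(tag_a, tag_b))
  list(matrix = fused, counts = counts, samples = samples)
}

short_tag <- function(tag) if (identical(tag, "methylation")) "meth" else tag

#' Read/write feature sets as plain text
#'
#' One feature id per line.
#'
#' @param x a [feature_set()].
#' @param path file path.
#' @param name,provenance metadata attached on read.
#' @return `path` (write) or a [feature_set()] (read).
#' @export
write_feature_set <- function(x, path) {
  writeLines(as_feature_ids(x), path)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path, name = basename(path),
                             provenance = "manual") {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  feature_set(ids, name = name, provenance = provenance)
}
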