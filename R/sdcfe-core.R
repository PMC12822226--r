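#' Parameters for sDCFE scoring
#'
#' @param alpha synergy weight in `[0, 1]` balancing the discriminative
#'   variance score against the cluster-separation score (default 0.7, the
#'   value that emphasizes supervised discrimination while retaining the
#'   unsupervised signal).
#' @param lam nonnegative MAD regularization weight in the score denominator
#'   (default 0.1), damping genes whose high dispersion would otherwise
#'   dominate the ranking.
#' @param K number of K-means clusters (default `NULL` = number of classes).
#' @param seed integer seed for the clustering initialization (default 42).
#' @param clustering_mode `"global"` (one K-means over samples on the
#'   standardized matrix; default) or `"per_gene"` (an independent 1-D
#'   K-means per gene).
#' @param component_norm `"minmax"` (default: each component rescaled to
#'   `[0, 1]` across genes before combination) or `"raw"`.
#' @param n_init number of random K-means restarts (default 10).
#' @return a `sdcfe_params` list.
#' @export
sdcfe_params <- function(alpha = 0.7, lam = 0.1, K = NULL, seed = 42L,
                         clustering_mode = c("global", "per_gene"),
                         component_norm = c("minmax", "raw"), n_init = 10L) {
  clustering_mode <- match.arg(clustering_mode)
  component_norm <- match.arg(component_norm)
  stopifnot(alpha >= 0, alpha <= 1, lam >= 0, n_init >= 1)
  if (!is.null(K) && K < 2) stop("K must be >= 2")
  structure(list(alpha = alpha, lam = lam, K = K, seed = as.integer(seed),
                 clustering_mode = clustering_mode,
                 component_norm = component_norm, n_init = as.integer(n_init)),
            class = "sdcfe_params")
}

# Guard against division by zero for genes constant within every class.
DENOM_EPS <- 1e-12
CS_CAP <- 1e12

#' Per-class summary statistics
#'
#' Computes, for every gene, the class means, population class variances, the
#' grand mean, and the class sizes/weights that enter the discriminative
#' variance score.
#'
#' @param m imputed omics matrix.
#' @param y class labels aligned with the rows of `m`.
#' @return list with `means` and `vars` (classes x genes matrices),
#'   `grand_mean` (per gene), `n_c`, `w_c` (= `n_c / N`), `classes`, `C`, `N`.
#' @export
class_stats <- function(m, y) {
  check_matrix(m, allow_missing = FALSE)
  y <- as.factor(y)
  y <- droplevels(y)
  if (length(y) != nrow(m)) stop("labels must align with matrix rows")
  n_c <- table(y)
  if (nlevels(y) < 2L) stop("at least two classes are required")
  if (any(n_c < 2L)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(n_c)[n_c < 2L], collapse = ", "))
  }
  classes <- levels(y)
  C <- length(classes)
  N <- nrow(m)
  means <- matrix(NA_real_, C, ncol(m), dimnames = list(classes, colnames(m)))
  vars <- means
  for (c in classes) {
    sub <- m[y == c, , drop = FALSE]
    mu <- colMeans(sub)
    means[c, ] <- mu
    vars[c, ] <- colMeans(sweep(sub, 2L, mu, "-")^2)
  }
  w_c <- as.numeric(n_c) / N
  names(w_c) <- classes
  list(means = means, vars = vars, grand_mean = colMeans(m),
       n_c = stats::setNames(as.integer(n_c), classes), w_c = w_c,
       classes = classes, C = C, N = N)
}

#' Median absolute deviation per gene
#'
#' `MAD_i = median(|x - median(x)|)` over all samples, unscaled (no normal
#' consistency constant): it is used as a robust dispersion penalty, not a
#' standard-deviation estimate.
#'
#' @param m imputed omics matrix.
#' @return named nonnegative vector, one entry per gene.
#' @export
mad_per_gene <- function(m) {
  check_matrix(m, allow_missing = FALSE)
  apply(m, 2L, function(x) stats::median(abs(x - stats::median(x))))
}

#' Discriminative class feature extraction (DCFE) scores
#'
#' For each gene the weighted between-class variance is divided by the
#' weighted within-class variance plus a MAD penalty:
#' \deqn{DCFE_i = \frac{\sum_c w_c (\mu_{ic} - \mu_i)^2}
#'   {\sum_c w_c \sigma_c^2(i) + \lambda \cdot MAD_i + \epsilon}}
#' with class weights \eqn{w_c = n_c / N}, population class variances
#' \eqn{\sigma_c^2}, and a numerical guard \eqn{\epsilon = 10^{-12}}. At
#' \eqn{\lambda = 0} this is the weighted Fisher-like variance ratio; the MAD
#' term regularizes against highly dispersed genes. Genes with zero
#' between-class variance score exactly 0.
#'
#' @param m imputed omics matrix.
#' @param y class labels.
#' @param lam nonnegative regularization weight (default 0.1).
#' @param cs optional precomputed [class_stats()] result.
#' @return named nonnegative score vector, one entry per gene.
#' @export
dcfe_scores <- function(m, y, lam = 0.1, cs = NULL) {
  stopifnot(lam >= 0)
  if (is.null(cs)) cs <- class_stats(m, y)
  between <- colSums(cs$w_c * sweep(cs$means, 2L, cs$grand_mean, "-")^2)
  within <- colSums(cs$w_c * cs$vars)
  mad <- mad_per_gene(m)
  score <- between / (within + lam * mad + DENOM_EPS)
  score[between == 0] <- 0
  score
}

#' K-means partition of samples (or per-gene values)
#'
#' In `"global"` mode one K-means clustering of the samples is computed on
#' the z-scored matrix, reading hidden heterogeneity as sample subtypes. In
#' `"per_gene"` mode each gene's values are clustered independently in 1-D.
#' The partition is deterministic given `seed` and `n_init`. Genes (or
#' matrices) with fewer distinct values than `K` are clustered at the number
#' of distinct values they have.
#'
#' @param m imputed omics matrix.
#' @param K number of clusters (>= 2, <= number of samples).
#' @param seed integer seed.
#' @param mode `"global"` or `"per_gene"`.
#' @param n_init number of random restarts.
#' @return `"global"`: named integer vector of cluster assignments;
#'   `"per_gene"`: samples x genes integer matrix of assignments.
#' @export
kmeans_partition <- function(m, K, seed = 42L, mode = c("global", "per_gene"),
                             n_init = 10L) {
  mode <- match.arg(mode)
  check_matrix(m, allow_missing = FALSE)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (nrow(m) < K) stop(sprintf("K (%d) exceeds the number of samples (%d)", K, nrow(m)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  if (mode == "global") {
    z <- zscore_scale(m)$matrix
    cl <- kmeans_safe(z, K, n_init)
    stats::setNames(cl, rownames(m))
  } else {
    out <- vapply(seq_len(ncol(m)), function(j) kmeans_safe(m[, j], K, n_init),
                  integer(nrow(m)))
    dimnames(out) <- dimnames(m)
    out
  }
}

# kmeans that tolerates data with fewer distinct points than centers by
# reducing K to the number of distinct points (constant data -> one cluster).
kmeans_safe <- function(x, K, n_init) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  key <- do.call(paste, c(as.data.frame(xm), sep = "\r"))
  ukey <- unique(key)
  k_eff <- min(K, length(ukey))
  if (k_eff < 2L) return(rep(1L, nrow(xm)))
  if (k_eff == length(ukey)) {
    # saturated case: the zero-cost optimum puts each distinct point alone
    return(match(key, ukey))
  }
  fit <- stats::kmeans(xm, centers = k_eff, nstart = n_init, iter.max = 100L)
  as.integer(fit$cluster)
}

#' Cluster-separation scores (one-way ANOVA F across clusters)
#'
#' For each gene the one-way ANOVA F-statistic of its values across the
#' non-empty clusters:
#' \deqn{CS_i = \frac{\sum_k n_k (m_k - m)^2 / (K' - 1)}
#'   {\sum_k \sum_j (x_{jk} - m_k)^2 / (N - K') + \epsilon}}
#' Constant genes score 0; perfectly separated genes (zero within-cluster
#' variance) are capped at `1e12`.
#'
#' @param m imputed omics matrix.
#' @param clusters cluster assignment: a vector (one global partition, from
#'   [kmeans_partition()] in `"global"` mode) or a samples x genes matrix
#'   (`"per_gene"` mode).
#' @return named nonnegative score vector, one entry per gene.
#' @export
cluster_separation_scores <- function(m, clusters) {
  check_matrix(m, allow_missing = FALSE)
  if (is.matrix(clusters)) {
    if (!identical(dim(clusters), dim(m))) {
      stop("per-gene cluster matrix must have the same dimensions as the data")
    }
    score <- vapply(seq_len(ncol(m)), function(j) anova_f(m[, j], clusters[, j]),
                    numeric(1))
    return(stats::setNames(score, colnames(m)))
  }
  if (length(clusters) != nrow(m)) stop("cluster assignment must align with matrix rows")
  cl <- as.integer(factor(clusters))
  if (max(cl) < 2L) stop("fewer than 2 non-empty clusters")
  stats::setNames(vapply(seq_len(ncol(m)), function(j) anova_f(m[, j], cl), numeric(1)),
                  colnames(m))
}

# One-way ANOVA F with the zero-numerator and cap conventions of the score.
anova_f <- function(x, cl) {
  cl <- as.integer(factor(cl))
  Kp <- max(cl)
  if (Kp < 2L) return(0)
  N <- length(x)
  if (N <= Kp) stop("need more samples than non-empty clusters")
  gm <- mean(x)
  n_k <- tabulate(cl, Kp)
  m_k <- vapply(seq_len(Kp), function(k) mean(x[cl == k]), numeric(1))
  between <- sum(n_k * (m_k - gm)^2) / (Kp - 1L)
  if (between == 0) return(0)
  within <- sum((x - m_k[cl])^2) / (N - Kp)
  min(between / (within + DENOM_EPS), CS_CAP)
}

#' Combine DCFE and cluster-separation scores
#'
#' \deqn{sDCFE_i = \alpha \cdot DCFE_i + (1 - \alpha) \cdot CS_i}
#' The two components live on incommensurate scales (a regularized variance
#' ratio vs an ANOVA F), so with `norm = "minmax"` (the default) each is
#' first rescaled to `[0, 1]` across genes (a constant component maps to all
#' zeros); `norm = "raw"` combines the raw values.
#'
#' @param dcfe,cs equal-length score vectors.
#' @param alpha synergy weight in `[0, 1]`.
#' @param norm `"minmax"` or `"raw"`.
#' @return named combined score vector.
#' @export
combine_scores <- function(dcfe, cs, alpha = 0.7, norm = c("minmax", "raw")) {
  norm <- match.arg(norm)
  stopifnot(alpha >= 0, alpha <= 1)
  if (length(dcfe) != length(cs)) stop("score vectors must have equal length")
  if (norm == "minmax") {
    dcfe <- minmax(dcfe)
    cs <- minmax(cs)
  }
  alpha * dcfe + (1 - alpha) * cs
}

minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Rank features by their sDCFE score
#'
#' @param feature_id feature identifiers.
#' @param dcfe,cs,sdcfe,mad per-feature score components (same order).
#' @return a `score_table` data frame with columns `feature_id`, `dcfe`,
#'   `cs`, `sdcfe`, `rank`, `mad`, sorted by descending `sdcfe` with ties
#'   broken by ascending `feature_id` (deterministic).
#' @export
rank_features <- function(feature_id, dcfe, cs, sdcfe, mad) {
  n <- length(feature_id)
  if (any(lengths(list(dcfe, cs, sdcfe, mad)) != n)) stop("score vectors must align")
  if (any(!is.finite(sdcfe))) stop("non-finite sDCFE score(s); cannot rank")
  ord <- order(-sdcfe, as.character(feature_id))
  out <- data.frame(feature_id = as.character(feature_id)[ord],
                    dcfe = as.numeric(dcfe)[ord], cs = as.numeric(cs)[ord],
                    sdcfe = as.numeric(sdcfe)[ord], rank = seq_len(n),
                    mad = as.numeric(mad)[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_table", class(out))
  out
}

#' Score every gene with sDCFE
#'
#' Runs the full scorer: class statistics, MAD, DCFE, K-means clustering,
#' cluster-separation F, combination, ranking.
#'
#' @param m imputed omics matrix.
#' @param y class labels aligned with rows.
#' @param params a [sdcfe_params()] object; `K = NULL` defaults to the number
#'   of classes.
#' @return a ranked `score_table` (see [rank_features()]).
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_classes = 2, n_per_class = 10, n_genes = 20, n_informative = 3,
#'   n_subtypes = 0, seed = 1))
#' head(sdcfe_score(sim$matrix, sim$labels))
#' @export
sdcfe_score <- function(m, y, params = sdcfe_params()) {
  y <- droplevels(as.factor(y))
  K <- if (is.null(params$K)) nlevels(y) else params$K
  cs_stats <- class_stats(m, y)
  mad <- mad_per_gene(m)
  dcfe <- dcfe_scores(m, y, lam = params$lam, cs = cs_stats)
  clusters <- kmeans_partition(m, K = K, seed = params$seed,
                               mode = params$clustering_mode,
                               n_init = params$n_init)
  cs <- cluster_separation_scores(m, clusters)
  combined <- combine_scores(dcfe, cs, alpha = params$alpha,
                             norm = params$component_norm)
  rank_features(colnames(m), dcfe, cs, combined, mad)
}

#' Select the top-ranked fraction of features
#'
#' Retains the `ceiling(fraction * n)` top-ranked features (ceiling so a 50%
#' cutoff of an odd-sized table keeps the extra feature).
#'
#' @param ranked a `score_table` from [sdcfe_score()] or [rank_features()].
#' @param fraction fraction in `(0, 1]`.
#' @return a [feature_set()] with provenance `"sdcfe"`.
#' @export
select_top_fraction <- function(ranked, fraction) {
  if (!is.data.frame(ranked) || !"feature_id" %in% names(ranked)) {
    stop("'ranked' must be a score table")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  k <- as.integer(ceiling(fraction * nrow(ranked)))
  feature_set(ranked$feature_id[seq_len(k)], name = sprintf("top_%d", k),
              provenance = "sdcfe")
}

#' Select the top k ranked features
#'
#' @param ranked a `score_table`.
#' @param k number of features, `1 <= k <= nrow(ranked)`.
#' @return a [feature_set()] with provenance `"sdcfe"`.
#' @export
select_top_k <- function(ranked, k) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranked)) stop("k out of range")
  feature_set(ranked$feature_id[seq_len(k)], name = sprintf("top_%d", k),
              provenance = "sdcfe")
}

#' Stability/accuracy plateau cutoff
#'
#' Chooses how many top-ranked genes to keep by examining, over a grid of
#' candidate sizes `k`, (a) the stability of the top-`k` set under
#' resampling — the mean pairwise Jaccard similarity of the top-`k` sets from
#' `B` stratified 50% subsample rescoring runs — and (b) the nearest-centroid
#' cross-validated accuracy on the top-`k` features of the full-data ranking.
#' The chosen `k` is the smallest grid value whose next-step relative gain is
#' below 1% on both curves (falling back to the largest grid value if no
#' plateau is reached).
#'
#' @param m imputed omics matrix.
#' @param y class labels.
#' @param params [sdcfe_params()].
#' @param k_grid increasing vector of candidate set sizes.
#' @param B number of subsample rescoring runs (default 10).
#' @param cv_folds stratified cross-validation folds (default 5).
#' @param seed seed for subsampling and fold assignment (default 1).
#' @return list with `k_grid`, `stability`, `cv_accuracy`, `chosen_k`.
#' @export
stability_cutoff <- function(m, y, params = sdcfe_params(), k_grid,
                             B = 10L, cv_folds = 5L, seed = 1L) {
  y <- droplevels(as.factor(y))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0L) stop("k_grid is empty")
  if (any(k_grid < 1L) || any(k_grid > ncol(m))) stop("k_grid must lie in [1, n_features]")
  if (B < 2L) stop("B must be >= 2")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  # B stratified 50% subsample rescoring runs
  rankings <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(levels(y), function(c) {
      cls <- which(y == c)
      sample(cls, max(2L, floor(length(cls) / 2)))
    }), use.names = FALSE)
    rankings[[b]] <- sdcfe_score(m[idx, , drop = FALSE], y[idx], params)$feature_id
  }
  stability <- vapply(k_grid, function(k) {
    sets <- lapply(rankings, utils::head, k)
    pairs <- utils::combn(B, 2L)
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      a <- sets[[pairs[1, p]]]; b <- sets[[pairs[2, p]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1)))
  }, numeric(1))

  # CV accuracy of the nearest-centroid classifier on top-k features
  ranking <- sdcfe_score(m, y, params)$feature_id
  folds <- make_stratified_folds(y, cv_folds)
  cv_accuracy <- vapply(k_grid, function(k) {
    feats <- ranking[seq_len(k)]
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      model <- centroid_fit(m[!test, feats, drop = FALSE], y[!test])
      pred <- centroid_predict(model, m[test, feats, drop = FALSE])
      correct <- correct + sum(pred == y[test])
    }
    correct / length(y)
  }, numeric(1))

  chosen_k <- k_grid[length(k_grid)]
  if (length(k_grid) > 1L) {
    for (i in seq_len(length(k_grid) - 1L)) {
      gain_s <- (stability[i + 1L] - stability[i]) / max(stability[i], DENOM_EPS)
      gain_a <- (cv_accuracy[i + 1L] - cv_accuracy[i]) / max(cv_accuracy[i], DENOM_EPS)
      if (gain_s < 0.01 && gain_a < 0.01) { chosen_k <- k_grid[i]; break }
    }
  }
  list(k_grid = k_grid, stability = stability, cv_accuracy = cv_accuracy,
       chosen_k = chosen_k)
}

# Stratified fold assignment: within each class, folds are dealt round-robin
# over a random permutation.
make_stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (c in levels(y)) {
    idx <- sample(which(y == c))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Write a score table as TSV
#'
#' @param tab a `score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(tab) <- c("score_table", class(tab))
  tab
}
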