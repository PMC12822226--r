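test_that("class statistics match hand arithmetic", {
  toy <- toy_two_class()
  cs <- class_stats(toy$m, toy$y)
  expect_equal(unname(cs$means[, 1]), c(1, 5))
  expect_equal(unname(cs$grand_mean), 3)
  expect_equal(unname(cs$w_c), c(0.5, 0.5))
  expect_equal(sum(cs$w_c), 1)
  # grand mean is the weight-mixture of class means, per gene
  expect_equal(colSums(cs$w_c * cs$means), cs$grand_mean)

  y3 <- factor(rep(c("a", "b", "c"), each = 2))
  m3 <- mk_matrix(matrix(rnorm(12), 6, 2), n_samples = 6)
  expect_equal(unname(class_stats(m3, y3)$w_c), rep(1 / 3, 3))

  expect_error(class_stats(toy$m, factor(rep("A", 4))), "two classes")
  expect_error(class_stats(toy$m, factor(c("A", "B", "B", "B"))), "fewer than 2")
})

test_that("per-gene MAD follows the unscaled definition", {
  expect_equal(unname(mad_per_gene(mk_matrix(c(0, 2, 4, 6), n_samples = 4))), 2)
  expect_equal(unname(mad_per_gene(mk_matrix(rep(3, 5), n_samples = 5))), 0)
  expect_equal(unname(mad_per_gene(mk_matrix(7, n_samples = 1))), 0)
})

test_that("DCFE reproduces the worked toy and the zero rules", {
  toy <- toy_two_class()
  # between = 4, within = 1, MAD = 2 -> 4 / (1 + 0.1 * 2)
  expect_equal(unname(dcfe_scores(toy$m, toy$y, lam = 0.1)), 4 / 1.2,
               tolerance = 1e-9)
  expect_equal(unname(dcfe_scores(toy$m, toy$y, lam = 0)), 4, tolerance = 1e-9)

  const <- mk_matrix(cbind(rep(1, 4), c(0, 2, 4, 6)), n_samples = 4)
  expect_equal(unname(dcfe_scores(const, toy$y)[1]), 0)
})

test_that("DCFE at lambda = 0 agrees with a brute-force Fisher-ratio oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 60; p <- 50
    m <- mk_matrix(matrix(rnorm(n * p), n, p), n_samples = n)
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)))
    while (any(table(y) < 2)) y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    expect_equal(dcfe_scores(m, y, lam = 0), fisher_ratio_oracle(m, y),
                 tolerance = 1e-9)
  }
})

test_that("DCFE is invariant to sample order and class relabeling, and scale-invariant at lambda 0", {
  set.seed(7)
  n <- 30
  m <- mk_matrix(matrix(rnorm(n * 8), n, 8), n_samples = n)
  y <- factor(rep(c("x", "y", "z"), each = 10))
  base <- dcfe_scores(m, y)

  perm <- sample(n)
  mp <- m[perm, ]
  expect_equal(dcfe_scores(mp, y[perm]), base)

  relabeled <- factor(c(x = "III", y = "I", z = "II")[as.character(y)])
  expect_equal(dcfe_scores(m, relabeled), base)

  # scaling a gene by s > 0 cancels exactly when lambda = 0
  s <- 3.7
  ms <- m; ms[, 2] <- ms[, 2] * s
  expect_equal(dcfe_scores(ms, y, lam = 0)[2], dcfe_scores(m, y, lam = 0)[2],
               tolerance = 1e-9)
  # with lambda > 0 the MAD term grows like s, the rest like s^2
  cs <- class_stats(m, y)
  g2 <- m[, 2]
  between <- sum(cs$w_c * (cs$means[, 2] - cs$grand_mean[2])^2)
  within <- sum(cs$w_c * cs$vars[, 2])
  mad2 <- median(abs(g2 - median(g2)))
  expected <- (s^2 * between) / (s^2 * within + 0.1 * s * mad2 + 1e-12)
  expect_equal(unname(dcfe_scores(ms, y, lam = 0.1)[2]), expected,
               tolerance = 1e-9)
})

test_that("widening the class gap strictly increases DCFE", {
  scores <- vapply(c(1, 2, 4, 8), function(delta) {
    m <- mk_matrix(c(0, 1, delta, delta + 1), n_samples = 4)
    unname(dcfe_scores(m, factor(c("A", "A", "B", "B")), lam = 0))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("k-means partition recovers obvious structure deterministically", {
  m <- mk_matrix(c(0, 0, 10, 10), n_samples = 4)
  cl <- kmeans_partition(m, K = 2, seed = 1)
  expect_equal(cl[["s01"]], cl[["s02"]])
  expect_equal(cl[["s03"]], cl[["s04"]])
  expect_false(cl[["s01"]] == cl[["s03"]])

  # K = n on distinct samples gives singleton clusters
  distinct <- mk_matrix(c(0, 3, 10, 14), n_samples = 4)
  expect_equal(sort(unname(kmeans_partition(distinct, K = 4, seed = 1))), 1:4)

  # two blobs at +-5 sd are recovered exactly
  set.seed(3)
  blob <- rbind(matrix(rnorm(50 * 5, -5), 50, 5), matrix(rnorm(50 * 5, 5), 50, 5))
  bm <- mk_matrix(blob, n_samples = 100)
  cl2 <- kmeans_partition(bm, K = 2, seed = 9)
  truth <- rep(1:2, each = 50)
  agreement <- max(mean(cl2 == truth), mean(cl2 == 3 - truth))
  expect_equal(agreement, 1)

  # deterministic given the seed
  expect_identical(kmeans_partition(bm, K = 2, seed = 9),
                   kmeans_partition(bm, K = 2, seed = 9))
  expect_error(kmeans_partition(m, K = 5, seed = 1), "exceeds")
})

test_that("cluster-separation score is the one-way ANOVA F with cap and zero rules", {
  m <- mk_matrix(c(0, 2, 10, 12), n_samples = 4)
  cl <- c(1, 1, 2, 2)
  # between MS = 100, within MS = 2
  expect_equal(unname(cluster_separation_scores(m, cl)), 50, tolerance = 1e-9)

  const <- mk_matrix(rep(4, 4), n_samples = 4)
  expect_equal(unname(cluster_separation_scores(const, cl)), 0)

  sep <- mk_matrix(c(0, 0, 1, 1), n_samples = 4)
  expect_equal(unname(cluster_separation_scores(sep, cl)), 1e12)

  # invariant to permutation of cluster labels
  m2 <- mk_matrix(matrix(rnorm(40), 10, 4), n_samples = 10)
  cl10 <- rep(1:2, 5)
  expect_equal(cluster_separation_scores(m2, cl10),
               cluster_separation_scores(m2, 3 - cl10))
  expect_error(cluster_separation_scores(m, rep(1, 4)), "fewer than 2")
})

minmax_ref <- function(x) (x - min(x)) / (max(x) - min(x))

test_that("score combination respects alpha endpoints and min-max scaling", {
  dcfe <- c(a = 4, b = 0); cs <- c(a = 50, b = 0)
  expect_equal(combine_scores(dcfe, cs, alpha = 0.7, norm = "minmax"),
               c(a = 1, b = 0))
  expect_equal(combine_scores(dcfe, cs, alpha = 1, norm = "raw"), dcfe)
  expect_equal(combine_scores(dcfe, cs, alpha = 0, norm = "raw"), cs)

  set.seed(5)
  d <- runif(30); f <- runif(30) * 100
  out <- combine_scores(d, f, alpha = 0.3)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(combine_scores(d, f, alpha = 1), minmax_ref(d))
  expect_error(combine_scores(1:3, 1:4), "equal length")
})

test_that("ranking is a deterministic permutation with id tie-breaks", {
  tab <- rank_features(c("g2", "g1"), dcfe = c(1, 2), cs = c(1, 2),
                       sdcfe = c(5, 7), mad = c(0, 0))
  expect_equal(tab$feature_id, c("g1", "g2"))
  expect_equal(tab$rank, 1:2)

  tie <- rank_features(c("b", "a"), c(0, 0), c(0, 0), sdcfe = c(3, 3), c(0, 0))
  expect_equal(tie$feature_id, c("a", "b"))

  set.seed(13)
  n <- 921
  ids <- sprintf("f%04d", sample(n))
  tab2 <- rank_features(ids, runif(n), runif(n), runif(n), runif(n))
  expect_equal(sort(tab2$rank), 1:n)
  expect_true(all(diff(tab2$sdcfe) <= 0))
  expect_error(rank_features("a", 1, 1, NaN, 1), "non-finite")
})

test_that("top-fraction selection uses ceiling rounding", {
  tab <- rank_features(sprintf("f%03d", 1:921), numeric(921), numeric(921),
                       sort(runif(921), decreasing = TRUE), numeric(921))
  expect_equal(length(select_top_fraction(tab, 0.5)), 461)
  small <- tab[1:7, ]
  expect_equal(length(select_top_fraction(small, 0.5)), 4)
  expect_equal(length(select_top_fraction(small, 1)), 7)
  expect_error(select_top_fraction(tab, 0), "fraction")
  expect_error(select_top_fraction(tab, 1.2), "fraction")
})

test_that("full scorer separates class-block from subtype-block genes as alpha moves", {
  # subtype structure made dominant (more genes, larger shift) so the global
  # K = 2 clustering tracks subtypes, which are orthogonal to the class labels
  sim <- simulate_expression(simulation_config(
    n_classes = 2, n_per_class = 25, n_genes = 120, n_informative = 10,
    n_subtypes = 2, subtype_effect = 5, n_subtype_genes = 25,
    effect_size = 2.5, seed = 21))
  tab_sup <- sdcfe_score(sim$matrix, sim$labels, sdcfe_params(alpha = 1, K = 2))
  tab_uns <- sdcfe_score(sim$matrix, sim$labels, sdcfe_params(alpha = 0, K = 2))
  expect_gte(length(intersect(tab_sup$feature_id[1:10], sim$planted)), 9)
  expect_gte(length(intersect(tab_uns$feature_id[1:25], sim$subtype_genes)), 23)

  # the mean rank of subtype genes improves monotonically as alpha drops
  ranks_at <- function(alpha) {
    tab <- sdcfe_score(sim$matrix, sim$labels, sdcfe_params(alpha = alpha, K = 2))
    mean(match(sim$subtype_genes, tab$feature_id))
  }
  r <- vapply(c(1, 0.7, 0.3, 0), ranks_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_gt(r[1] - r[4], 10)
})

test_that("scoring is byte-identical across repeated runs with one config", {
  sim <- simulate_expression(simulation_config(
    n_classes = 3, n_per_class = 15, n_genes = 80, n_informative = 8, seed = 5))
  p <- sdcfe_params(seed = 42)
  t1 <- sdcfe_score(sim$matrix, sim$labels, p)
  t2 <- sdcfe_score(sim$matrix, sim$labels, p)
  expect_identical(t1, t2)
})

test_that("stability cutoff finds a plateau when signal is confined to few genes", {
  sim <- simulate_expression(simulation_config(
    n_classes = 2, n_per_class = 25, n_genes = 120, n_informative = 20,
    effect_size = 3, n_subtypes = 0, seed = 1))
  rep <- stability_cutoff(sim$matrix, sim$labels,
                          params = sdcfe_params(K = 2),
                          k_grid = c(10, 20, 40, 80), B = 4, cv_folds = 3,
                          seed = 2)
  expect_true(all(rep$stability >= 0 & rep$stability <= 1))
  expect_true(all(rep$cv_accuracy >= 0 & rep$cv_accuracy <= 1))
  expect_true(rep$chosen_k %in% rep$k_grid)
  expect_lte(rep$chosen_k, 40)
  expect_error(stability_cutoff(sim$matrix, sim$labels, k_grid = integer(0)),
               "empty")
})
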