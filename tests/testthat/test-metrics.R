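test_that("confusion matrix and row normalization follow the definitions", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(sum(cm), 3)

  perfect <- confusion(c("a", "b"), c("a", "b"))
  expect_equal(unname(row_normalize(perfect)), diag(2))

  one_col <- confusion(c("a", "b", "b"), c("a", "a", "a"))
  expect_equal(unname(colSums(one_col)), c(3, 0))

  cm3 <- confusion(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_warning(rn <- row_normalize(cm3), "zero rows")
  expect_equal(unname(rn["b", ]), c(0, 0))

  expect_error(confusion("a", "z", classes = "a"), "unknown label")
})

test_that("binary metrics recover the printed staging confusion-matrix accuracy", {
  # counts [[TN, FP], [FN, TP]] = [[31, 4], [7, 20]]
  cm <- matrix(c(31L, 7L, 4L, 20L), 2, 2,
               dimnames = list(true = c("I", "II"), pred = c("I", "II")))
  bm <- basic_metrics(cm, positive = "II")
  expect_equal(bm$accuracy, 51 / 62)
  expect_equal(round(100 * bm$accuracy, 2), 82.26)
  expect_equal(bm$precision, 20 / 24)
  expect_equal(bm$recall, 20 / 27)

  perfect <- confusion(c("a", "b"), c("a", "b"))
  pm <- basic_metrics(perfect, "a")
  expect_equal(unlist(pm), c(precision = 1, recall = 1, f1 = 1, accuracy = 1))

  degenerate <- confusion(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  w <- capture_warnings(z <- basic_metrics(degenerate, "b"))
  expect_match(w, "undefined", all = TRUE)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("multiclass MCC matches hand values and its symmetries", {
  indep <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mcc_multiclass(indep), 0)

  perfect <- diag(3L) * 10L
  dimnames(perfect) <- list(letters[1:3], letters[1:3])
  expect_equal(mcc_multiclass(perfect), 1)

  set.seed(2)
  y1 <- sample(letters[1:3], 60, replace = TRUE)
  y2 <- sample(letters[1:3], 60, replace = TRUE)
  cm <- confusion(y1, y2)
  expect_equal(mcc_multiclass(cm), mcc_multiclass(t(cm)))
  perm <- c(2, 3, 1)
  expect_equal(mcc_multiclass(cm[perm, perm]), mcc_multiclass(cm))
  expect_gte(mcc_multiclass(cm), -1)
  expect_lte(mcc_multiclass(cm), 1)
})

test_that("rank AUC handles separation, ties, and monotone transforms", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_rank(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(auc_rank(c(1, 1, 1, 1), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
  set.seed(6)
  s <- rnorm(100); pos <- runif(100) < 0.4
  expect_equal(auc_rank(exp(s), pos), auc_rank(s, pos))  # monotone invariance
  expect_true(is.na(auc_rank(s, rep(FALSE, 100))))
})

test_that("ECE vanishes for perfectly calibrated bins and flags miscalibration", {
  # construct outcomes whose frequency equals the predicted probability
  prob <- rep(c(0.25, 0.75), each = 8)
  pos <- c(rep(c(TRUE, FALSE, FALSE, FALSE), 2),
           rep(c(TRUE, TRUE, TRUE, FALSE), 2))
  res <- calibration_ece(prob, pos)
  expect_equal(res$ece, 0)
  expect_equal(sum(res$curve$count), 16)

  over <- calibration_ece(rep(0.95, 20), rep(FALSE, 20))
  expect_equal(over$ece, 0.95)
})

test_that("the full metrics report is coherent on perfect and null classifiers", {
  classes <- c("a", "b", "c")
  y <- rep(classes, each = 10)
  probs <- matrix(0.001, 30, 3, dimnames = list(NULL, classes))
  probs[cbind(seq_len(30), rep(1:3, each = 10))] <- 0.998
  rep_perfect <- multiclass_metrics(y, probs)
  expect_equal(rep_perfect$accuracy, 1)
  expect_equal(rep_perfect$balanced_accuracy, 1)
  expect_equal(rep_perfect$mcc, 1)
  expect_equal(rep_perfect$macro_auc_ovr, 1)
  expect_lt(rep_perfect$macro_ece, 0.005)
  # accuracy from the confusion matrix equals the label agreement rate
  pred <- classes[apply(probs, 1, which.max)]
  expect_equal(rep_perfect$accuracy, mean(pred == y))

  set.seed(7)
  n <- 3000
  raw <- matrix(runif(n * 3), n, 3)
  null_probs <- raw / rowSums(raw)
  colnames(null_probs) <- classes
  y_null <- sample(classes, n, replace = TRUE)
  rep_null <- multiclass_metrics(y_null, null_probs)
  expect_lt(abs(rep_null$macro_auc_ovr - 0.5), 0.03)

  bad <- null_probs * 2
  expect_error(multiclass_metrics(y_null, bad), "sum to 1")
})

test_that("nearest centroid fits, predicts, and breaks ties by class order", {
  m <- mk_matrix(rbind(c(0, 0), c(4, 4)), n_samples = 2)
  model <- centroid_fit(m, factor(c("a", "b")))
  expect_equal(unname(centroid_predict(model, m)), factor(c("a", "b")))

  # equidistant sample goes to the first class in stored order
  mid <- mk_matrix(rbind(c(2, 2)), n_samples = 1)
  colnames(mid) <- colnames(m)
  expect_equal(as.character(centroid_predict(model, mid)), "a")

  # two identical classes give identical centroids; ties resolve to the first
  m2 <- mk_matrix(rbind(c(1, 1), c(1, 1)), n_samples = 2)
  model2 <- centroid_fit(m2, factor(c("x", "y")))
  expect_equal(model2$centroids["x", ], model2$centroids["y", ])
  expect_equal(as.character(centroid_predict(model2, m2)), c("x", "x"))

  expect_error(centroid_predict(model, mk_matrix(matrix(1, 1, 3), n_samples = 1)),
               "feature set")
})

test_that("centroid classifier approaches the analytic optimum on spherical Gaussians", {
  # two spherical classes at Euclidean distance 2 in 2-D, unit sd:
  # Bayes accuracy = pnorm(half-distance) = pnorm(1)
  set.seed(12)
  n <- 500
  x <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, sqrt(2)), n, 2))
  m <- mk_matrix(x, n_samples = 2 * n)
  y <- factor(rep(c("a", "b"), each = n))
  model <- centroid_fit(m, y)
  acc <- mean(centroid_predict(model, m) == y)
  expect_lt(abs(acc - pnorm(1)), 0.02)

  # well-separated blobs classify essentially perfectly
  x2 <- rbind(matrix(rnorm(100 * 3, -3), 100, 3), matrix(rnorm(100 * 3, 3), 100, 3))
  m2 <- mk_matrix(x2, n_samples = 200)
  y2 <- factor(rep(c("lo", "hi"), each = 100))
  expect_gte(mean(centroid_predict(centroid_fit(m2, y2), m2) == y2), 0.99)
})
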