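test_that("KNN honors zero-distance neighbors and the documented tie rule", {
  train <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  res <- knn_predict(train, matrix(c(1, 1), 1), k = 1,
                     train_labels = c("a", "b", "c"))
  expect_identical(res$labels, "b")
  # k = 2, votes split 1-1: the nearer neighbor's class wins
  train2 <- matrix(c(0, 0, 3, 0), ncol = 2, byrow = TRUE)
  res2 <- knn_predict(train2, matrix(c(1, 0), 1), k = 2,
                      train_labels = c("a", "b"))
  expect_identical(res2$labels, "a")
  expect_equal(unname(res2$scores[1, ]), c(0.5, 0.5))
  expect_error(knn_predict(train2, matrix(0, 1, 2), k = 3,
                           train_labels = c("a", "b")),
               "exceeds")
  expect_error(knn_predict(matrix(c(NA, 1), 1), matrix(0, 1, 2), k = 1,
                           train_labels = "a"),
               "non-finite")
})

test_that("KNN agrees with the exhaustive neighbor-search oracle", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    d <- sample(2:6, 1)
    k <- sample(c(1, 3, 5), 1)
    tx <- matrix(rnorm(n * d), n, d)
    ty <- sample(c("neutral", "fear", "anger"), n, replace = TRUE)
    qx <- matrix(rnorm(8 * d), 8, d)
    expect_identical(knn_predict(tx, qx, k = k, train_labels = ty)$labels,
                     knn_oracle(tx, ty, qx, k))
  }
})

test_that("k selection scores candidates by pooled CV accuracy", {
  set.seed(30)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(cl) {
    sweep(matrix(rnorm(40, sd = 0.3), 20, 2), 2, centers[cl, ], "+")
  }))
  y <- rep(c("neutral", "fear", "anger"), each = 20)
  fm <- structure(list(features = x, labels = y), class = "feature_matrix")
  expect_identical(select_k(fm, candidates = 5)$k, 5)
  sel <- select_k(fm, candidates = c(1, 3, 5, 7), seed = 4)
  expect_true(all(sel$accuracy >= 0.95))
  expect_identical(sel$k, 1)  # ties resolve to the smallest candidate
  expect_identical(sel, select_k(fm, candidates = c(1, 3, 5, 7), seed = 4))
  expect_error(select_k(fm, candidates = 60), "training-fold")
})

test_that("confusion accounting reproduces the printed per-class arithmetic", {
  mk <- function(correct, n_class = 216) {
    classes <- c("neutral", "fear", "anger")
    true <- rep(classes, each = n_class)
    pred <- character(0)
    for (i in seq_along(classes)) {
      wrong <- rep(classes[-i], length.out = n_class - correct[i])
      pred <- c(pred, rep(classes[i], correct[i]), wrong)
    }
    list(true = true, pred = pred)
  }
  z <- mk(c(208, 162, 142))
  rep_ <- evaluate(z$true, z$pred, levels = c("neutral", "fear", "anger"))
  expect_equal(round(rep_$tp_rate, 1),
               c(neutral = 96.3, fear = 75.0, anger = 65.7))
  expect_equal(round(rep_$overall_accuracy, 1), 79.0)
  expect_equal(unname(rowSums(rep_$confusion)), unname(rep_$class_n))
  expect_equal(rep_$overall_accuracy,
               sum(rep_$class_n * rep_$tp_rate) / sum(rep_$class_n))
})

test_that("evaluation handles perfect, degenerate and invalid predictions", {
  classes <- c("neutral", "fear", "anger")
  true <- rep(classes, each = 10)
  perfect <- evaluate(true, true)
  expect_equal(perfect$overall_accuracy, 100)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  all_neutral <- evaluate(true, rep("neutral", 30))
  expect_equal(all_neutral$overall_accuracy, 100 / 3, tolerance = 1e-12)
  expect_equal(unname(all_neutral$tp_rate[classes]), c(100, 0, 0))
  expect_error(evaluate(true, c(rep("neutral", 29), "joy")), "alphabet")
  expect_error(evaluate(true, true[-1]), "equal length")
})

test_that("relabeling classes permutes the confusion matrix consistently", {
  set.seed(9)
  classes <- c("neutral", "fear", "anger")
  true <- sample(classes, 60, replace = TRUE)
  pred <- sample(classes, 60, replace = TRUE)
  base <- evaluate(true, pred, levels = classes)
  map <- c(neutral = "anger", fear = "neutral", anger = "fear")
  swapped <- evaluate(unname(map[true]), unname(map[pred]), levels = classes)
  for (a in classes) {
    for (b in classes) {
      expect_identical(swapped$confusion[map[[a]], map[[b]]],
                       base$confusion[a, b])
    }
  }
  expect_equal(swapped$overall_accuracy, base$overall_accuracy)
})

test_that("one-vs-rest ROC matches the exhaustive threshold sweep", {
  # perfectly separating scores
  truth <- c(rep("a", 5), rep("b", 5))
  scores <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
                  b = c(rep(0.1, 5), rep(0.9, 5)))
  res <- one_vs_rest_roc(truth, scores)
  expect_equal(unname(res$auc), c(1, 1))
  expect_true(any(res$roc$a$fpr == 0 & res$roc$a$tpr == 1))
  # random scores vs the oracle (and pROC as an extra cross-check)
  set.seed(77)
  truth2 <- sample(c("a", "b"), 40, replace = TRUE)
  s <- runif(40)
  scores2 <- cbind(a = s, b = 1 - s)
  res2 <- one_vs_rest_roc(truth2, scores2)
  expect_equal(unname(res2$auc["a"]), auc_oracle(truth2 == "a", s),
               tolerance = 1e-12)
  expect_equal(unname(res2$auc["a"]),
               as.numeric(pROC::auc(pROC::roc(truth2 == "a", s,
                                              quiet = TRUE))),
               tolerance = 1e-12)
  # inverting the scores flips the area
  res_inv <- one_vs_rest_roc(truth2, cbind(a = 1 - s, b = s))
  expect_equal(unname(res_inv$auc["a"]), 1 - unname(res2$auc["a"]),
               tolerance = 1e-12)
  expect_error(one_vs_rest_roc(rep("a", 10), cbind(a = runif(10))),
               "positives and negatives")
})

test_that("the 2-D projection is an orthonormal top-variance view", {
  set.seed(15)
  basis <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[, 1:2]
  planar <- matrix(rnorm(60), 30, 2) %*% t(basis)  # rank-2 in 4-D
  pr <- project_2d(planar)
  expect_lt(sum(pr$sdev[3:4]), 1e-10)
  expect_equal(crossprod(pr$axes), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  x <- matrix(rnorm(200), 50, 4)
  p2 <- project_2d(x)
  cv <- cov(p2$coords)
  expect_lt(abs(cv[1, 2]), 1e-8)
  expect_lte(sum(diag(cv)), sum(apply(scale(x), 2, var)) + 1e-8)
  rank1 <- outer(rnorm(20), c(1, 2, 3))
  expect_error(project_2d(rank1), "degenerate")
  expect_error(project_2d(matrix(1, 2, 4)), "at least 3 rows")
})

test_that("the band comparison emits one summary row per requested band", {
  recs <- lapply(c("neutral", "fear", "anger"), function(s) {
    generate_recording(default_profiles()[[s]], 30, 128,
                       seed = match(s, c("neutral", "fear", "anger")))
  })
  res <- run_band_comparison(recs, bands = "delta", folds = 3, seed = 1)
  expect_equal(nrow(res$summary), 1L)
  expect_identical(res$summary$band, "delta")
  expect_named(res$reports, "delta")
  expect_equal(sum(res$reports$delta$confusion), res$summary$n_epochs)
  expect_error(run_band_comparison(recs, bands = "mu"), "unknown band")
  expect_error(run_band_comparison(recs[1]), "2 classes")
})
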