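# Stratified folding, the four classifiers, metric arithmetic and the
# experiment grid.

test_that("stratified folds partition the data with proportional classes", {
  y <- rep(c("MI", "healthy"), each = 50)
  folds <- make_folds(y, k = 10, seed = 7)
  expect_length(folds, 100)
  expect_true(all(table(folds) == 10))
  # every sample appears in exactly one test fold
  expect_true(all(sort(unlist(lapply(1:10, function(f) which(folds == f))))
                  == 1:100))
  y2 <- c(rep("MI", 60), rep("healthy", 40))
  f2 <- make_folds(y2, k = 10, seed = 8)
  tab <- table(f2, y2)
  expect_true(all(abs(tab[, "MI"] - 6) <= 1))
  expect_true(all(abs(tab[, "healthy"] - 4) <= 1))
  expect_error(make_folds(c(rep("MI", 5), rep("healthy", 50)), k = 10),
               "fewer")
})

test_that("all four classifiers solve a separable problem perfectly", {
  set.seed(71)
  n <- 60
  X <- rbind(matrix(rnorm(n * 5, 0), n, 5), matrix(rnorm(n * 5, 6), n, 5))
  y <- rep(c("MI", "healthy"), each = n)
  for (cl in c("bt", "svm", "ann", "knn")) {
    cv <- cv_evaluate(X, y, cl, k = 10, seed = 72)
    expect_equal(cv$metrics[["acc"]], 100)
  }
  expect_error(train_predict("bt", X[1:10, ], rep("MI", 10), X[1:2, ]),
               "single class")
})

test_that("1-NN on its own training set is perfect", {
  set.seed(73)
  X <- matrix(rnorm(200), 40, 5)
  y <- rep(c("MI", "healthy"), 20)
  pred <- train_predict("knn", X, y, X, classifier_config(knn_k = 1))
  expect_equal(as.character(pred), y)
})

test_that("metrics follow the confusion-count formulas", {
  m <- compute_metrics(c(TP = 10, FP = 0, TN = 5, FN = 0))
  expect_true(all(m == 100))
  m2 <- round(compute_metrics(c(TP = 90, FP = 10, TN = 40, FN = 10)), 1)
  expect_equal(unname(m2), c(86.7, 90.0, 80.0, 90.0, 80.0))
  m3 <- compute_metrics(c(TP = 0, FP = 0, TN = 40, FN = 10))
  expect_true(is.na(m3[["ppv"]]))
  expect_false(anyNA(m3[c("acc", "spe", "npv")]))
  expect_error(compute_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("pooled accuracy equals the sample-weighted mean of fold accuracies", {
  set.seed(74)
  n <- 90
  X <- matrix(rnorm(2 * n * 4, rep(c(0, 1.2), each = n)), 2 * n, 4)
  y <- rep(c("MI", "healthy"), each = n)
  cv <- cv_evaluate(X, y, "knn", k = 9, seed = 75)
  fold_n <- rowSums(cv$per_fold)
  fold_acc <- (cv$per_fold[, "TP"] + cv$per_fold[, "TN"]) / fold_n
  expect_equal(cv$metrics[["acc"]],
               100 * sum(fold_acc * fold_n) / sum(fold_n), tolerance = 1e-12)
  expect_equal(sum(cv$pooled), length(y))
})

test_that("standardization uses training statistics only", {
  Xtr <- matrix(c(rnorm(50, 5, 2), rnorm(50, -3, 0.5)), 50, 2)
  Xte <- matrix(rnorm(20, 0, 1), 10, 2)
  st <- ecgmi:::.standardize_pair(Xtr, Xte)
  expect_equal(unname(colMeans(st$tr)), c(0, 0), tolerance = 1e-12)
  expect_equal(st$te, sweep(sweep(Xte, 2, colMeans(Xtr)), 2,
                            apply(Xtr, 2, sd), "/"), tolerance = 1e-12)
})

test_that("label-shuffled data scores near chance for every classifier", {
  set.seed(76)
  n <- 200
  X <- matrix(rnorm(n * 15), n, 15)
  X[1:(n / 2), 1:5] <- X[1:(n / 2), 1:5] + 2
  y <- rep(c("MI", "healthy"), each = n / 2)
  y_shuf <- sample(y)
  for (cl in c("bt", "svm", "ann", "knn")) {
    cv <- cv_evaluate(X, y_shuf, cl, k = 10, seed = 77)
    expect_gte(cv$metrics[["acc"]], 40)
    expect_lte(cv$metrics[["acc"]], 60)
  }
})

test_that("experiment grids share folds and report the requested cells", {
  set.seed(78)
  n <- 80
  feats <- data.frame(record_id = "r", segment_index = seq_len(2 * n),
                      label = rep(c("MI", "healthy"), each = n))
  feats$orj_mean <- rnorm(2 * n, rep(c(0, 3), each = n))
  feats$orj_sample <- rnorm(2 * n, rep(c(1, 0), each = n))
  feats$d1_rms <- rnorm(2 * n)
  subsets <- list(informative = c("orj_mean", "orj_sample"),
                  noise = "d1_rms",
                  all = c("orj_mean", "orj_sample", "d1_rms"))
  res <- run_experiment(feats, subsets = subsets,
                        classifiers = c("bt", "knn"), k = 10, seed = 79)
  expect_equal(nrow(res), 6)
  expect_setequal(res$feature_set, names(subsets))
  expect_true(all(res$acc[res$feature_set == "informative"] >
                    res$acc[res$feature_set == "noise"]))
  grid <- accuracy_grid(res)
  expect_equal(dim(grid), c(3, 3))
  expect_equal(res$TP + res$FP + res$TN + res$FN, rep(2 * n, 6))
  # identical seed reproduces the report exactly
  res2 <- run_experiment(feats, subsets = subsets,
                         classifiers = c("bt", "knn"), k = 10, seed = 79)
  expect_identical(res, res2, ignore_attr = TRUE)
})
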