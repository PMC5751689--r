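test_that("a separable toy problem is fit perfectly and deterministically", {
  x <- matrix(c(5, 6, -5, -6), ncol = 1)
  y <- c(1, 1, -1, -1)
  model <- train_svm(x, y)
  expect_equal(as.integer(predict(model, x)), y)
  model2 <- train_svm(x, y)
  expect_identical(attr(predict(model, x), "decision_values"),
                   attr(predict(model2, x), "decision_values"))
  expect_error(train_svm(x, c(1, 1, 1, 1)), "single class")
})

test_that("prediction validates dimensions, handles empty input, ignores row order", {
  set.seed(18)
  x <- rbind(matrix(rnorm(20 * 4, 1), 20, 4), matrix(rnorm(20 * 4, -1), 20, 4))
  y <- rep(c(1, -1), each = 20)
  model <- train_svm(x, y)
  expect_error(predict(model, matrix(0, 2, 3)), "dimension mismatch")
  expect_length(predict(model, x[0, , drop = FALSE]), 0)
  test <- matrix(rnorm(10 * 4), 10, 4)
  p1 <- as.integer(predict(model, test))
  p2 <- as.integer(predict(model, test[10:1, ]))
  expect_equal(p1, rev(p2))
})

test_that("confusion arithmetic reproduces the worked oxy-Hb and total-Hb tables", {
  oxy <- performance_metrics(c(TP = 39, FN = 3, FP = 8, TN = 26))
  expect_equal(100 * oxy$accuracy, 85.5, tolerance = 0.1 / 85.5)
  expect_equal(100 * oxy$sensitivity, 92.857, tolerance = 1e-3)
  expect_equal(100 * oxy$specificity, 76.5, tolerance = 0.1 / 76.5)

  total <- performance_metrics(c(TP = 39, FN = 3, FP = 12, TN = 22))
  expect_equal(100 * total$accuracy, 80.3, tolerance = 0.1 / 80.3)
  expect_equal(100 * total$specificity, 64.7, tolerance = 0.1 / 64.7)

  perfect <- performance_metrics(c(TP = 42, FN = 0, FP = 0, TN = 34))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))

  expect_error(performance_metrics(c(TP = 0, FN = 0, FP = 1, TN = 1)),
               "Sensitivity undefined")
  expect_error(performance_metrics(c(TP = 1, FN = 1, FP = 0, TN = 0)),
               "Specificity undefined")
})

test_that("LOOCV runs one fold per subject with correct marginals", {
  set.seed(19)
  x <- rbind(matrix(rnorm(42 * 5, 3), 42, 5), matrix(rnorm(34 * 5, -3), 34, 5))
  feats <- make_features(x, c(rep(1, 42), rep(-1, 34)))
  res <- loocv_svm(features = feats)
  expect_equal(nrow(res$folds), 76)
  expect_equal(res$confusion[["TP"]] + res$confusion[["FN"]], 42)
  expect_equal(res$confusion[["TN"]] + res$confusion[["FP"]], 34)
  expect_equal(res$accuracy, 1) # 3-SD separation is trivially classifiable
  g <- glance(res)
  expect_equal(g$n_folds, 76)
  # ACC is the class-size weighted combination of SS and TNR
  expect_equal(g$accuracy,
               (42 * g$sensitivity + 34 * g$specificity) / 76)
})

test_that("LOOCV is invariant to subject ordering", {
  set.seed(20)
  x <- rbind(matrix(rnorm(12 * 4, 1.2), 12, 4), matrix(rnorm(10 * 4, -1.2), 10, 4))
  feats <- make_features(x, c(rep(1, 12), rep(-1, 10)))
  res1 <- loocv_svm(features = feats)
  perm <- sample(nrow(feats))
  feats2 <- feats[perm, ]
  class(feats2) <- class(feats)
  res2 <- loocv_svm(features = feats2)
  expect_equal(res1$confusion, res2$confusion)
  m <- match(res1$folds$subject_id, res2$folds$subject_id)
  expect_equal(res1$folds$predicted, res2$folds$predicted[m])
})

test_that("null feature matrices classify at class-prior chance over 20 seeds", {
  accs <- sapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(76 * 52), 76, 52)
    feats <- make_features(x, c(rep(1, 42), rep(-1, 34)))
    loocv_svm(features = feats)$accuracy
  })
  prior <- 42 / 76
  band <- 1.96 * sqrt(prior * (1 - prior) / 76)
  expect_gt(mean(accs), prior - band)
  expect_lt(mean(accs), prior + band)
})

test_that("fold-wise selection reruns the scan inside each training fold", {
  set.seed(21)
  tensor <- make_tensor(12, 10, grid = c(0.1, 0.21, 0.3), n_channels = 8,
                        planted = list(metric = "degree", sparsity = 0.21),
                        effect = 3, n_shift_channels = 8)
  res <- loocv_svm(selection = "fold", tensor = tensor)
  expect_equal(nrow(res$folds), 22)
  expect_true(all(res$folds$chosen_metric == "degree"))
  expect_true(all(abs(res$folds$chosen_sparsity - 0.21) < 1e-9))
  expect_gt(res$accuracy, 0.9)
})

test_that("degenerate LOOCV inputs are rejected with subject context", {
  x <- matrix(rnorm(8), 4, 2)
  feats <- make_features(x, c(1, 1, 1, -1))
  expect_error(loocv_svm(features = feats), "single-class.*S004")
})
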