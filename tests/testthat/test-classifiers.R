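sep_table <- function(n = 30, seed = 1) {
  make_windowed_table(n_sms = n, n_n = n, nprime = 3, seed = seed)
}

feat <- function(t) as.matrix(t[, paste0("CPP", 1:attr(t, "nprime"))])

test_that("model specs validate methods and hyperparameter keys", {
  expect_error(model_spec("gmm"), "arg")
  expect_error(model_spec("rf", list(trees = 10)), "unknown hyperparameter")
  expect_error(model_spec("svm", list(kernel = "laplace")), "kernel")
  expect_error(model_spec("knn", list(weighting = "quadratic")), "weighting")
  spec <- model_spec("svm", list(kernel = "linear", cost = 10))
  expect_equal(spec$hyperparameters$kernel, "linear")
})

test_that("all four methods train and predict through one interface", {
  t <- sep_table()
  x <- feat(t)
  y <- t$Target
  for (m in c("rf", "svm", "lda", "knn")) {
    model <- fit_model(model_spec(m, seed = 4), x, y)
    pred <- predict(model, x)
    expect_s3_class(pred, "factor")
    expect_true(all(pred %in% c("N", "SMS")))
    expect_length(pred, nrow(x))
    # empty input -> empty prediction; width mismatch -> error
    expect_length(predict(model, x[0, , drop = FALSE]), 0)
    expect_error(predict(model, x[, 1:2]), "width")
  }
  expect_error(fit_model(model_spec("lda"), x, rep("SMS", nrow(x))), "single class")
})

test_that("1-NN memorizes its training set", {
  t <- sep_table()
  m <- fit_model(model_spec("knn", list(k = 1)), feat(t), t$Target)
  expect_equal(as.character(predict(m, feat(t))), t$Target)
})

test_that("LDA places its boundary between well-separated 1-D class means", {
  set.seed(8)
  x <- matrix(c(rnorm(100, 0, 1), rnorm(100, 10, 1)), ncol = 1)
  y <- rep(c("N", "SMS"), each = 100)
  m <- fit_model(model_spec("lda"), x, y)
  # closed-form equal-covariance threshold is the midpoint of the means
  grid <- matrix(seq(-2, 12, by = 0.25), ncol = 1)
  pred <- predict(m, grid)
  crossing <- grid[max(which(pred == "N"))]
  expect_lt(abs(crossing - mean(c(mean(x[1:100]), mean(x[101:200])))), 1)
})

test_that("fixed seeds make random-forest fits reproducible", {
  t <- sep_table(n = 25, seed = 2)
  x <- feat(t)
  m1 <- fit_model(model_spec("rf", seed = 11), x, t$Target)
  m2 <- fit_model(model_spec("rf", seed = 11), x, t$Target)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("a linear-kernel SVM separates linearly separable classes exactly", {
  t <- sep_table(n = 40, seed = 3)  # 2.5 sd per-feature gap: separable
  m <- fit_model(model_spec("svm", list(kernel = "linear", cost = 100)), feat(t), t$Target)
  expect_equal(mean(predict(m, feat(t)) == t$Target), 1)
})

test_that("weighted KNN favours the nearest neighbours", {
  # query next to a lone N point, with 3 SMS points further away: uniform
  # k = 4 votes SMS, inverse-distance weighting votes N
  x <- rbind(c(0, 0), c(5, 0), c(5.2, 0), c(5.4, 0))
  y <- c("N", "SMS", "SMS", "SMS")
  q <- matrix(c(0.1, 0), ncol = 2)
  uni <- fit_model(model_spec("knn", list(k = 4, weighting = "uniform")), x, y)
  wtd <- fit_model(model_spec("knn", list(k = 4, weighting = "weighted")), x, y)
  expect_equal(as.character(predict(uni, q)), "SMS")
  expect_equal(as.character(predict(wtd, q)), "N")
})

test_that("grid search scores every combination and returns the best spec", {
  t <- sep_table(n = 30, seed = 5)
  gs <- grid_search("knn", list(k = c(1, 5), weighting = c("uniform", "weighted")),
                    feat(t), t$Target, folds = 3, seed = 1)
  expect_equal(nrow(gs$results), 4)
  expect_true(all(is.finite(gs$results$cv_accuracy)))
  expect_s3_class(gs$best_spec, "model_spec")
  expect_equal(gs$results$cv_accuracy[which.max(gs$results$cv_accuracy)],
               max(gs$results$cv_accuracy))
})

test_that("model specs serialize to JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  write_model_spec_json(model_spec("svm", list(kernel = "poly", degree = 2)), p)
  j <- jsonlite::read_json(p)
  expect_equal(j$method, "svm")
  expect_equal(j$hyperparameters$degree, 2)
})
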