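test_that("LOSO builds one leak-free fold per speaker", {
  t <- make_windowed_table(n_sms = 6, n_n = 5, speakers_per_class = 3)
  folds <- loso_folds(t)
  expect_length(folds, 6)
  for (f in folds) {
    expect_setequal(unique(windowed_speakers(f$validation)), f$speaker)
    expect_false(f$speaker %in% windowed_speakers(f$train))
    expect_equal(nrow(f$train) + nrow(f$validation), nrow(t))
    expect_length(intersect(f$train$Name, f$validation$Name), 0)
  }

  one <- structure(t[windowed_speakers(t) == "SMS1", ], nprime = attr(t, "nprime"))
  expect_error(loso_folds(one), "at least 2 speakers")

  # holding out the only speaker of one class leaves a single-class train set
  two <- make_windowed_table(n_sms = 5, n_n = 5, speakers_per_class = 1)
  expect_error(loso_folds(two), "single-class")
})

test_that("without SMOTE, deterministic models repeat identically across iterations", {
  t <- make_windowed_table(n_sms = 8, n_n = 7, speakers_per_class = 2)
  cfg <- case_study_config(use_smote = FALSE, n_iterations = 4,
                           model_specs = default_model_specs(c("lda", "knn")))
  rep1 <- run_case_study(t, cfg)
  for (m in c("lda", "knn")) {
    expect_equal(apply(rep1$accuracy[[m]], 1, sd), rep(0, 4),
                 ignore_attr = TRUE)
  }
  expect_equal(dim(rep1$accuracy$lda), c(4, 4))
  expect_true(all(rep1$accuracy$lda >= 0 & rep1$accuracy$lda <= 1))
  # bit-identical reports under identical seeds
  rep2 <- run_case_study(t, cfg)
  expect_identical(rep1$accuracy, rep2$accuracy)
})

test_that("SMOTE iterations stay confined to the training folds", {
  t <- make_windowed_table(n_sms = 12, n_n = 6, speakers_per_class = 2)
  cfg <- case_study_config(use_smote = TRUE, n_iterations = 2,
                           model_specs = default_model_specs("lda"))
  rep <- run_case_study(t, cfg)
  expect_false(any(grepl("^synth\\.", rep$speakers)))
  expect_equal(dim(rep$accuracy$lda), c(4, 2))
})

test_that("rank-sum statistic and exact p match hand enumeration", {
  r1 <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$u_statistic, 0)
  expect_equal(r1$sum_ranks_1, 6)
  expect_equal(r1$p_value, 0.1)

  r2 <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r2$u_statistic, 0)
  expect_equal(r2$p_value, 1 / 3)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("identical constant samples give NA, per the degenerate-distance rule", {
  r <- rank_sum_test(rep(1, 10), rep(1, 10))
  expect_true(is.na(r$p_value))
  expect_equal(r$u_statistic, 50)  # midranks: U sits at its null mean
  # identical but non-constant samples still get a p-value
  r2 <- rank_sum_test(c(0, 1), c(0, 1))
  expect_false(is.na(r2$p_value))
})

test_that("exact p-values agree with the permutation oracle on tie-free samples", {
  set.seed(21)
  for (n in 2:6) {
    for (rep in 1:8) {
      pool <- sample(seq_len(50), 2 * n)  # distinct values: tie-free
      x <- pool[seq_len(n)]
      y <- pool[-seq_len(n)]
      ours <- rank_sum_test(x, y)
      expect_equal(ours$p_value, enum_ranksum_p(x, y), tolerance = 1e-12)
      expect_equal(ours$u_statistic, enum_u(x, y))
      # cross-check against the reference implementation
      ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      expect_true(ours$p_value > 0 && ours$p_value <= 1)
      expect_true(ours$u_statistic >= 0 && ours$u_statistic <= n * n)
    }
  }
})

test_that("the tie-corrected normal approximation matches the reference", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(seq(0, 1, by = 0.1), 10, replace = TRUE)
    y <- sample(seq(0, 1, by = 0.1), 10, replace = TRUE)
    if (all(c(x, y) == x[1])) next
    ours <- rank_sum_test(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("comparison tables cover every method pair for every speaker", {
  t <- make_windowed_table(n_sms = 8, n_n = 7, speakers_per_class = 2, seed = 3)
  cfg <- case_study_config(use_smote = TRUE, n_iterations = 6,
                           model_specs = default_model_specs())
  rep <- run_case_study(t, cfg)
  cmp <- comparison_table(rep)
  expect_equal(nrow(cmp), 4)
  expect_equal(names(cmp),
               c("Speaker", "RF_vs_SVM", "RF_vs_KNN", "RF_vs_LDA",
                 "SVM_vs_KNN", "SVM_vs_LDA", "KNN_vs_LDA"))
  sig <- attr(cmp, "significant")
  expect_true(is.data.frame(sig))

  # a speaker at uniform 100% under every method gets NA in all six columns
  rep$accuracy <- lapply(rep$accuracy, function(a) { a[1, ] <- 1; a })
  cmp2 <- comparison_table(rep)
  expect_true(all(is.na(unlist(cmp2[1, -1]))))
})

test_that("report summaries agree with brute-force recomputation", {
  t <- make_windowed_table(n_sms = 8, n_n = 7, speakers_per_class = 2, seed = 4)
  rep <- run_case_study(t, case_study_config(
    use_smote = TRUE, n_iterations = 5, model_specs = default_model_specs("rf")))
  s <- summarize_report(rep)
  for (sp in rep$speakers) {
    row <- rep$accuracy$rf[sp, ]
    brute_mean <- sum(row) / length(row)
    brute_sd <- sqrt(sum((row - brute_mean)^2) / (length(row) - 1))
    expect_equal(s$per_speaker$rf_mean[s$per_speaker$Speaker == sp], brute_mean,
                 tolerance = 1e-12)
    expect_equal(s$per_speaker$rf_sd[s$per_speaker$Speaker == sp], brute_sd,
                 tolerance = 1e-12)
  }
  expect_equal(s$overall[["rf"]], mean(rowMeans(rep$accuracy$rf)), tolerance = 1e-12)

  # constant-perfect matrix: 100% overall, zero sd
  rep$accuracy$rf[] <- 1
  s2 <- summarize_report(rep)
  expect_equal(s2$overall[["rf"]], 1)
  expect_true(all(s2$per_speaker$rf_sd == 0))
})

test_that("percent formatting follows the report style", {
  expect_equal(format_pct(0.8833, 2), "88.33%")
  expect_equal(format_pct(0.711, 1), "71.1%")
  expect_equal(format_pct(NA_real_), "NA")
})

test_that("report CSVs carry per-speaker rows, an overall row, and NA literals", {
  t <- make_windowed_table(n_sms = 8, n_n = 7, speakers_per_class = 2, seed = 6)
  rep <- run_case_study(t, case_study_config(
    use_smote = FALSE, n_iterations = 3,
    model_specs = default_model_specs(c("rf", "lda"))))
  dir <- withr::local_tempdir()
  paths <- write_report_csv(rep, dir)
  acc <- read.csv(paths[1], stringsAsFactors = FALSE)
  expect_equal(nrow(acc), 5)  # 4 speakers + Overall
  expect_equal(acc$Speaker[5], "Overall")
  expect_true(all(grepl("%$", acc$RF)))
  cmp <- readLines(paths[2])
  expect_match(cmp[1], "RF_vs_LDA")
})
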