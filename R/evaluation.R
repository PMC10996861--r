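#' Leave-one-speaker-out folds
#'
#' One fold per speaker: the validation set is exactly that speaker's
#' fixed-width subgroups, the training set is every other row. Subgroups of
#' the same speaker therefore never straddle the train/validation split.
#'
#' @param table a windowed table.
#' @return List of folds, each a list with `train`, `validation`
#'   (windowed-table row subsets) and `speaker`.
#' @export
loso_folds <- function(table) {
  nprime <- attr(table, "nprime")
  if (is.null(nprime)) stop_input("not a windowed table (missing nprime attribute)")
  sp <- windowed_speakers(table)
  speakers <- unique(sp)
  if (length(speakers) < 2L) {
    stop_input("leave-one-speaker-out needs at least 2 speakers (got %d)",
               length(speakers))
  }
  lapply(speakers, function(s) {
    val <- sp == s
    train <- table[!val, , drop = FALSE]
    if (length(unique(train$Target)) < 2L) {
      stop_input("training partition is single-class when holding out speaker %s", s)
    }
    list(train = structure(train, nprime = nprime),
         validation = structure(table[val, , drop = FALSE], nprime = nprime),
         speaker = s)
  })
}

#' Case-study configuration
#'
#' `use_smote = FALSE` is the unbalanced protocol (CE1); `use_smote = TRUE`
#' re-balances each training fold with SMOTE in every iteration (CE2). Each
#' held-out speaker is scored `n_iterations` times; with SMOTE off and
#' deterministic models the repeats are identical by construction.
#'
#' @param use_smote logical.
#' @param n_iterations repeats per fold (default 10).
#' @param seeds distinct integer seeds, one per iteration; defaults to
#'   `base_seed + 0:(n_iterations-1)`.
#' @param model_specs named list of [model_spec()] objects.
#' @param smote a [smote_config()] (its `seed` is overridden per iteration).
#' @param base_seed used to derive default `seeds`.
#' @return An object of class `case_study_config`.
#' @export
case_study_config <- function(use_smote = FALSE, n_iterations = 10,
                              seeds = NULL, model_specs = default_model_specs(),
                              smote = smote_config(), base_seed = 1L) {
  if (!is_count(n_iterations) || n_iterations < 1) {
    stop_input("n_iterations must be an integer >= 1")
  }
  seeds <- seeds %||% (as.integer(base_seed) + seq_len(n_iterations) - 1L)
  if (length(seeds) != n_iterations || anyDuplicated(seeds)) {
    stop_input("seeds must be %d distinct integers", n_iterations)
  }
  if (is.null(names(model_specs))) {
    names(model_specs) <- vapply(model_specs, `[[`, character(1), "method")
  }
  if (anyDuplicated(names(model_specs))) stop_input("duplicate method names in model_specs")
  structure(list(use_smote = isTRUE(use_smote),
                 n_iterations = as.integer(n_iterations),
                 seeds = as.integer(seeds),
                 model_specs = model_specs,
                 smote = smote),
            class = "case_study_config")
}

#' Run a leave-one-speaker-out case study
#'
#' For every fold and iteration: optionally SMOTE-balance the training rows
#' (iteration seed `cfg$seeds[i]`), fit each model on the CPP feature
#' columns, and score the held-out speaker's rows. Synthetic rows are
#' created only inside training folds and are never scored.
#'
#' @param table a windowed table.
#' @param cfg a [case_study_config()].
#' @return An `evaluation_report`: list with `accuracy` (named list of
#'   speaker x iteration matrices, one per method, entries in `[0, 1]`),
#'   `methods`, `speakers`, `n_iterations`, `use_smote`, `seeds`, `nprime`.
#' @export
run_case_study <- function(table, cfg = case_study_config()) {
  stopifnot(inherits(cfg, "case_study_config"))
  nprime <- attr(table, "nprime")
  feat_cols <- windowed_feature_cols(nprime)
  folds <- loso_folds(table)
  speakers <- vapply(folds, `[[`, character(1), "speaker")
  methods <- names(cfg$model_specs)
  acc <- lapply(methods, function(m) {
    matrix(NA_real_, length(speakers), cfg$n_iterations,
           dimnames = list(speakers, paste0("iter", seq_len(cfg$n_iterations))))
  })
  names(acc) <- methods
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (isTRUE(any(fold$validation$synthetic))) {
      stop_input("synthetic rows found in a validation fold (speaker %s)", fold$speaker)
    }
    xval <- as_feature_matrix(fold$validation[, feat_cols, drop = FALSE])
    yval <- factor(fold$validation$Target, levels = LABEL_LEVELS)
    for (i in seq_len(cfg$n_iterations)) {
      train <- fold$train
      if (cfg$use_smote) {
        scfg <- cfg$smote
        scfg$seed <- cfg$seeds[i]
        train <- balance_training_fold(train, scfg)
      }
      xtr <- as_feature_matrix(train[, feat_cols, drop = FALSE])
      ytr <- factor(train$Target, levels = LABEL_LEVELS)
      for (m in methods) {
        spec <- cfg$model_specs[[m]]
        spec$seed <- as.integer(spec$seed + cfg$seeds[i])
        model <- fit_model(spec, xtr, ytr)
        pred <- predict(model, xval)
        acc[[m]][fold$speaker, i] <- mean(pred == yval)
      }
    }
  }
  structure(list(accuracy = acc, methods = methods, speakers = speakers,
                 n_iterations = cfg$n_iterations, use_smote = cfg$use_smote,
                 seeds = cfg$seeds, nprime = nprime),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- summarize_report(x)
  cat(sprintf("<evaluation_report: %d speakers x %d iterations, SMOTE %s>\n",
              length(x$speakers), x$n_iterations, if (x$use_smote) "on" else "off"))
  cat("  overall accuracy:",
      paste(sprintf("%s %s", names(s$overall), format_pct(s$overall, 1)),
            collapse = "  "), "\n")
  invisible(x)
}

# --- Mann-Whitney rank-sum test --------------------------------------------

#' Two-sample Mann-Whitney rank-sum test
#'
#' Midranks for ties; `U = sum(ranks of x) - n1 (n1 + 1) / 2`. The two-sided
#' p-value is exact by complete enumeration of label assignments when
#' `n1 + n2 <= 20` and the pooled sample is tie-free, otherwise a normal
#' approximation with continuity and tie correction is used. When every
#' pooled value is identical there is no distance information at all and the
#' p-value is `NA` — the convention used for degenerate method comparisons
#' (e.g. two classifiers at a constant 100%).
#'
#' @param x,y non-empty numeric samples.
#' @return An object of class `rank_sum_result`: `u_statistic`, `p_value`
#'   (`NA` in the degenerate case), `n1`, `n2`, `sum_ranks_1`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop_input("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  sum_r1 <- sum(r[seq_len(n1)])
  u <- sum_r1 - n1 * (n1 + 1) / 2
  p <- if (all(pooled == pooled[1])) {
    NA_real_
  } else if (n1 + n2 <= 20 && !anyDuplicated(pooled)) {
    exact_ranksum_p(r, n1, u)
  } else {
    approx_ranksum_p(pooled, n1, n2, u)
  }
  structure(list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
                 sum_ranks_1 = sum_r1),
            class = "rank_sum_result")
}

# Exact two-sided p by enumerating all C(n1+n2, n1) assignments of the
# (tie-free) pooled ranks to the first sample.
exact_ranksum_p <- function(r, n1, u_obs) {
  n <- length(r)
  cmb <- utils::combn(n, n1)
  us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

approx_ranksum_p <- function(pooled, n1, n2, u_obs) {
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(NA_real_)
  z <- u_obs - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum: U = %g (n1 = %d, n2 = %d), p = %s\n",
              x$u_statistic, x$n1, x$n2,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4)))
  invisible(x)
}

# --- report summaries -------------------------------------------------------

#' Per-speaker pairwise method comparison
#'
#' For every speaker and every pair of methods, the rank-sum test is applied
#' to the two iteration accuracy vectors. Pairs follow the order of
#' `report$methods` (with the default four: `RF_vs_SVM`, `RF_vs_KNN`,
#' `RF_vs_LDA`, `SVM_vs_KNN`, `SVM_vs_LDA`, `KNN_vs_LDA`).
#'
#' @param report an `evaluation_report` with >= 2 methods.
#' @param alpha significance threshold (default 0.05).
#' @return Data frame of p-values, one row per speaker, with a `Speaker`
#'   column and a logical `significant` data frame (`p <= alpha`) attached
#'   as an attribute.
#' @export
comparison_table <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "evaluation_report"))
  if (length(report$methods) < 2L) stop_input("need at least 2 methods to compare")
  pairs <- utils::combn(report$methods, 2, simplify = FALSE)
  cols <- vapply(pairs, function(p) paste0(toupper(p[1]), "_vs_", toupper(p[2])),
                 character(1))
  out <- data.frame(Speaker = report$speakers, stringsAsFactors = FALSE)
  for (j in seq_along(pairs)) {
    a <- report$accuracy[[pairs[[j]][1]]]
    b <- report$accuracy[[pairs[[j]][2]]]
    out[[cols[j]]] <- vapply(report$speakers, function(s) {
      rank_sum_test(a[s, ], b[s, ])$p_value
    }, numeric(1))
  }
  sig <- out
  sig[cols] <- lapply(out[cols], function(p) !is.na(p) & p <= alpha)
  attr(out, "significant") <- sig
  out
}

#' Summarize an evaluation report
#'
#' @param report an `evaluation_report`.
#' @return List with `per_speaker` (data frame: `Speaker`, then one
#'   mean/sd pair per method, sd over iterations) and `overall` (named
#'   vector: mean over speakers of the per-speaker iteration means).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  per <- data.frame(Speaker = report$speakers, stringsAsFactors = FALSE)
  for (m in report$methods) {
    a <- report$accuracy[[m]]
    per[[paste0(m, "_mean")]] <- rowMeans(a)
    per[[paste0(m, "_sd")]] <- apply(a, 1, stats::sd)
  }
  overall <- vapply(report$methods,
                    function(m) mean(rowMeans(report$accuracy[[m]])),
                    numeric(1))
  list(per_speaker = per, overall = overall)
}

#' Write report CSVs
#'
#' Two files: `accuracy.csv` (per-speaker per-method mean accuracies as
#' two-decimal percentages, plus an `Overall` row with one decimal) and
#' `comparison.csv` (pairwise rank-sum p-values, `NA` literal for the
#' degenerate cases).
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summarize_report(report)
  acc <- data.frame(Speaker = s$per_speaker$Speaker, stringsAsFactors = FALSE)
  for (m in report$methods) {
    acc[[toupper(m)]] <- format_pct(s$per_speaker[[paste0(m, "_mean")]], 2)
  }
  overall <- c(Speaker = "Overall",
               stats::setNames(format_pct(s$overall, 1), toupper(report$methods)))
  acc <- rbind(acc, as.data.frame(as.list(overall), stringsAsFactors = FALSE))
  acc_path <- file.path(dir, "accuracy.csv")
  utils::write.csv(acc, acc_path, row.names = FALSE, quote = FALSE)
  cmp <- comparison_table(report)
  cmp_path <- file.path(dir, "comparison.csv")
  utils::write.csv(cmp, cmp_path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(c(acc_path, cmp_path))
}
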