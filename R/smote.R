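#' SMOTE configuration
#'
#' @param k_neighbors neighbours considered per seed row (capped at
#'   `n_minority - 1` at run time); the canonical default is 5.
#' @param target_ratio desired minority/majority row ratio after
#'   augmentation, in `(0, 1]`.
#' @param seed integer seed controlling the interpolation draws, or `NULL`
#'   to use the current RNG stream.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1.0, seed = NULL) {
  if (!is_count(k_neighbors) || k_neighbors < 1) {
    stop_input("k_neighbors must be an integer >= 1")
  }
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio > 1) {
    stop_input("target_ratio must be in (0, 1]")
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = seed),
            class = "smote_config")
}

#' Generate synthetic minority rows by nearest-neighbour interpolation
#'
#' Each synthetic row is `seed + lambda * (neighbor - seed)` with `lambda`
#' uniform on `[0, 1]`, the neighbour drawn uniformly from the seed row's
#' `k` nearest minority neighbours (Euclidean distance on the features), and
#' seed rows cycled so generation is spread uniformly over the minority
#' class. Reproducible under a fixed `cfg$seed`.
#'
#' @param minority_rows numeric matrix of minority-class feature rows
#'   (at least 2 rows).
#' @param n_new number of synthetic rows to generate.
#' @param cfg a [smote_config()].
#' @return Numeric matrix with `n_new` rows and attributes `seed_row`,
#'   `neighbor_row`, `lambda` recording the provenance of each row.
#' @export
smote_augment <- function(minority_rows, n_new, cfg = smote_config()) {
  x <- as.matrix(minority_rows)
  n <- nrow(x)
  if (n < 2L) {
    stop_input("SMOTE needs at least 2 minority rows to interpolate between (got %d)", n)
  }
  if (!is_count(n_new) || n_new < 0) stop_input("n_new must be a non-negative integer")
  k <- min(cfg$k_neighbors, n - 1L)
  if (n_new == 0L) {
    out <- x[0, , drop = FALSE]
    attr(out, "seed_row") <- integer(0)
    attr(out, "neighbor_row") <- integer(0)
    attr(out, "lambda") <- numeric(0)
    return(out)
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  with_seed(cfg$seed, {
    seed_idx <- rep(seq_len(n), length.out = n_new)
    nb_pick <- sample.int(k, n_new, replace = TRUE)
    lambda <- stats::runif(n_new)
    nb_idx <- nn[cbind(seed_idx, nb_pick)]
    synth <- x[seed_idx, , drop = FALSE] +
      lambda * (x[nb_idx, , drop = FALSE] - x[seed_idx, , drop = FALSE])
    rownames(synth) <- NULL
    attr(synth, "seed_row") <- seed_idx
    attr(synth, "neighbor_row") <- nb_idx
    attr(synth, "lambda") <- lambda
    synth
  })
}

#' Balance a training fold by SMOTE
#'
#' Identifies the minority class in the fold (computed, not assumed) and
#' appends interpolated rows until the minority count reaches
#' `round(target_ratio * majority)`. Only the CPP feature columns are
#' interpolated; `Sex`/`Group` metadata are copied from each synthetic row's
#' seed row. Synthetic rows carry `synthetic = TRUE` and names
#' `"synth.<class>.<i>"`; original rows are returned unmodified (with
#' `synthetic = FALSE`).
#'
#' @param fold_rows windowed-table rows forming a training fold; must
#'   contain both classes.
#' @param cfg a [smote_config()].
#' @return The augmented fold (data frame, same attributes plus a
#'   `synthetic` column).
#' @export
balance_training_fold <- function(fold_rows, cfg = smote_config()) {
  nprime <- attr(fold_rows, "nprime")
  if (is.null(nprime)) stop_input("fold is not a windowed table (missing nprime attribute)")
  present <- unique(fold_rows$Target)
  missing_class <- setdiff(LABEL_LEVELS, present)
  if (length(missing_class)) {
    stop_input("training fold contains no rows of class %s; cannot balance",
               paste(missing_class, collapse = ", "))
  }
  counts <- table(factor(fold_rows$Target, levels = LABEL_LEVELS))
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  n_new <- max(0L, round(cfg$target_ratio * n_maj) - n_min)
  fold_rows$synthetic <- fold_rows$synthetic %||% FALSE
  if (n_new == 0L) return(fold_rows)

  feat_cols <- windowed_feature_cols(nprime)
  min_rows <- fold_rows[fold_rows$Target == minority, , drop = FALSE]
  synth <- smote_augment(as.matrix(min_rows[, feat_cols, drop = FALSE]), n_new, cfg)
  seed_idx <- attr(synth, "seed_row")
  add <- data.frame(Name = sprintf("synth.%s.%d", minority, seq_len(n_new)),
                    as.data.frame(synth),
                    Target = minority,
                    Sex = min_rows$Sex[seed_idx],
                    Group = min_rows$Group[seed_idx],
                    synthetic = TRUE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(add)[seq_along(feat_cols) + 1L] <- feat_cols
  out <- rbind(fold_rows[, names(add), drop = FALSE], add)
  rownames(out) <- NULL
  structure(out, nprime = nprime)
}
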