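METHODS <- c("rf", "svm", "lda", "knn")

ALLOWED_HYPER <- list(
  rf  = c("ntree", "mtry"),
  svm = c("kernel", "cost", "degree", "gamma", "coef0"),
  lda = c("prior"),
  knn = c("k", "weighting")
)

SVM_KERNELS <- c(linear = "linear", poly = "polynomial",
                 rbf = "radial", sigmoid = "sigmoid")

#' Specify a supervised model
#'
#' Uniform description of the four supported methods. Hyperparameters are an
#' open key-value list validated per method; unlisted keys fall back to the
#' library defaults (rf: 100 trees; svm: rbf kernel, cost 1; knn: k = 5,
#' uniform neighbour weighting; lda: proportional priors).
#'
#' @param method one of `"rf"`, `"svm"`, `"lda"`, `"knn"`.
#' @param hyperparameters named list; allowed keys are `ntree`/`mtry` (rf),
#'   `kernel` in `linear|poly|rbf|sigmoid`, `cost`, `degree`, `gamma`,
#'   `coef0` (svm), `prior` (lda), `k` and `weighting` in
#'   `uniform|weighted` (knn).
#' @param seed integer seed used when fitting stochastic methods.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method, hyperparameters = list(), seed = 1L) {
  method <- match.arg(method, METHODS)
  bad <- setdiff(names(hyperparameters), ALLOWED_HYPER[[method]])
  if (length(bad)) {
    stop_input("unknown hyperparameter(s) for %s: %s (allowed: %s)",
               method, paste(bad, collapse = ", "),
               paste(ALLOWED_HYPER[[method]], collapse = ", "))
  }
  if (method == "svm" && !is.null(hyperparameters$kernel) &&
      !hyperparameters$kernel %in% names(SVM_KERNELS)) {
    stop_input("svm kernel must be one of: %s",
               paste(names(SVM_KERNELS), collapse = ", "))
  }
  if (method == "knn" && !is.null(hyperparameters$weighting) &&
      !hyperparameters$weighting %in% c("uniform", "weighted")) {
    stop_input("knn weighting must be 'uniform' or 'weighted'")
  }
  structure(list(method = method, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Default model specifications for the four methods
#'
#' @param methods subset of `c("rf", "svm", "knn", "lda")`; the default order
#'   matches the pairwise comparison column order of the report writer.
#' @param seed shared fitting seed.
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function(methods = c("rf", "svm", "knn", "lda"), seed = 1L) {
  methods <- match.arg(methods, METHODS, several.ok = TRUE)
  stats::setNames(lapply(methods, model_spec, seed = seed), methods)
}

as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("CPP", seq_len(ncol(x)))
  x
}

#' Fit a model to a feature matrix
#'
#' @param spec a [model_spec()].
#' @param features numeric matrix or data frame (rows = samples).
#' @param targets class labels, coercible to a factor with >= 2 levels.
#' @return A fitted handle of class `sms_model`, usable with `predict()`.
#' @export
fit_model <- function(spec, features, targets) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as_feature_matrix(features)
  y <- droplevels(factor(targets))
  if (nrow(x) != length(y)) stop_input("features and targets disagree in length")
  if (nlevels(y) < 2L) {
    stop_input("training targets contain a single class (%s); need both",
               paste(levels(y), collapse = ""))
  }
  h <- spec$hyperparameters
  fit <- switch(spec$method,
    rf = with_seed(spec$seed,
      randomForest::randomForest(x, y,
                                 ntree = h$ntree %||% 100,
                                 mtry = h$mtry %||% max(1, floor(sqrt(ncol(x)))))),
    svm = with_seed(spec$seed,
      e1071::svm(x, y,
                 kernel = SVM_KERNELS[[h$kernel %||% "rbf"]],
                 cost = h$cost %||% 1,
                 degree = h$degree %||% 3,
                 gamma = h$gamma %||% (1 / ncol(x)),
                 coef0 = h$coef0 %||% 0)),
    lda = if (is.null(h$prior)) MASS::lda(x, grouping = y)
          else MASS::lda(x, grouping = y, prior = h$prior),
    knn = list(x = x, y = y, k = h$k %||% 5L,
               weighting = h$weighting %||% "uniform")
  )
  structure(list(spec = spec, fit = fit, levels = levels(y), p = ncol(x),
                 feature_names = colnames(x)),
            class = "sms_model")
}

#' @export
print.sms_model <- function(x, ...) {
  cat(sprintf("<sms_model: %s, %d features, classes {%s}>\n",
              x$spec$method, x$p, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict class labels
#'
#' @param object an `sms_model` from [fit_model()].
#' @param newdata numeric matrix/data frame with the training feature width.
#' @param ... unused.
#' @return Factor of predicted labels (training level set), one per row;
#'   empty input yields an empty factor.
#' @export
predict.sms_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$p) {
    stop_input("feature width mismatch: model trained on %d features, got %d",
               object$p, ncol(x))
  }
  if (nrow(x) == 0L) return(factor(character(0), levels = object$levels))
  colnames(x) <- object$feature_names
  out <- switch(object$spec$method,
    rf  = stats::predict(object$fit, x),
    svm = stats::predict(object$fit, x),
    lda = stats::predict(object$fit, x)$class,
    knn = knn_predict(object$fit, x, object$spec$seed)
  )
  factor(as.character(out), levels = object$levels)
}

knn_predict <- function(fit, newdata, seed) {
  if (fit$weighting == "uniform") {
    with_seed(seed, class::knn(fit$x, newdata, fit$y, k = fit$k, use.all = TRUE))
  } else {
    # inverse-distance weighted vote over the k nearest training rows
    k <- min(fit$k, nrow(fit$x))
    apply_one <- function(q) {
      d <- sqrt(colSums((t(fit$x) - q)^2))
      nn <- order(d)[seq_len(k)]
      w <- 1 / (d[nn] + 1e-12)
      votes <- tapply(w, fit$y[nn], sum, default = 0)
      names(votes)[which.max(votes)]
    }
    apply(newdata, 1, apply_one)
  }
}

#' Exhaustive grid search over hyperparameter combinations
#'
#' Small helper mirroring an exhaustive hyperparameter sweep: every
#' combination in `grid` is scored by k-fold cross-validated accuracy and
#' the best-scoring [model_spec()] is returned.
#'
#' @param method classifier name.
#' @param grid named list of hyperparameter value vectors, e.g.
#'   `list(kernel = c("linear", "rbf"), cost = c(0.1, 1, 10))`.
#' @param features,targets training data.
#' @param folds number of CV folds.
#' @param seed seed for fold assignment and fitting.
#' @return List with `best_spec`, and `results` (one row per combination
#'   with its mean CV accuracy).
#' @export
grid_search <- function(method, grid, features, targets, folds = 5, seed = 1L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop_input("empty hyperparameter grid")
  x <- as_feature_matrix(features)
  y <- droplevels(factor(targets))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    spec <- model_spec(method, as.list(combos[i, , drop = FALSE]), seed = seed)
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      m <- fit_model(spec, x[tr, , drop = FALSE], y[tr])
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  list(best_spec = model_spec(method, as.list(combos[best, , drop = FALSE]), seed = seed),
       results = cbind(combos, cv_accuracy = acc))
}

#' Serialize a model spec as JSON
#' @param spec a [model_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  jsonlite::write_json(list(method = spec$method,
                            hyperparameters = spec$hyperparameters,
                            seed = spec$seed),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
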