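#' Train/test split specification
#'
#' @param train_fraction Fraction of rows used for training, in (0,1);
#'   default 0.70.
#' @param seed Integer seed; mandatory for a reproducible split.
#' @param stratified Stratify the split on the outcome (default `TRUE`).
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.70, seed, stratified = TRUE) {
  if (missing(seed)) stop("seed is mandatory for split_spec", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

.split_rows <- function(y, spec) {
  set.seed(spec$seed)
  n <- length(y)
  if (spec$stratified) {
    idx <- unlist(lapply(split(seq_len(n), y), function(rows) {
      sample(rows, round(spec$train_fraction * length(rows)))
    }), use.names = FALSE)
  } else {
    idx <- sample(n, round(spec$train_fraction * n))
  }
  sort(idx)
}

#' Held-out prediction accuracy of a reduced feature set
#'
#' Trains a classifier on the training partition of a single train/test
#' split and reports percent accuracy on the held-out rows. Logistic
#' regression classifies at predicted probability 0.5; the random forest
#' uses majority vote.
#'
#' @param data Data frame with predictors and the outcome column.
#' @param features Non-empty character vector of predictor names to use.
#' @param model_kind `"logistic_regression"` or `"random_forest"`.
#' @param split A [split_spec()].
#' @param outcome Name of the outcome column.
#' @param rf_params Extra [ranger::ranger()] arguments for the forest.
#' @return A `model_accuracy` list: `model_kind`, `feature_set`, `accuracy`
#'   (percent), `n_test`.
#' @export
evaluate_accuracy <- function(data, features,
                              model_kind = c("logistic_regression",
                                             "random_forest"),
                              split, outcome = "Heart Disease",
                              rf_params = list()) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(split, "split_spec"), length(features) >= 1)
  xy <- .split_xy(data, outcome)
  missing_feats <- setdiff(features, colnames(xy$x))
  if (length(missing_feats)) {
    stop("unknown feature(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  x <- data.matrix(xy$x[features])
  colnames(x) <- paste0("V", seq_along(features))
  y <- xy$y
  tr <- .split_rows(y, split)
  te <- setdiff(seq_along(y), tr)
  if (length(unique(y[tr])) < 2) {
    stop("training outcome has a single class; cannot fit", call. = FALSE)
  }

  if (model_kind == "logistic_regression") {
    fit <- stats::glm.fit(cbind(1, x[tr, , drop = FALSE]), y[tr],
                          family = stats::binomial())
    eta <- cbind(1, x[te, , drop = FALSE]) %*% fit$coefficients
    pred <- as.integer(stats::plogis(eta) > 0.5)
  } else {
    rf_args <- utils::modifyList(
      list(num.trees = 500, num.threads = 1,
           seed = split$seed),
      rf_params)
    fit <- do.call(ranger::ranger,
                   c(list(x = as.data.frame(x[tr, , drop = FALSE]),
                          y = factor(y[tr], levels = 0:1)),
                     rf_args))
    pred <- as.integer(as.character(
      stats::predict(fit, as.data.frame(x[te, , drop = FALSE]))$predictions))
  }
  structure(list(model_kind = model_kind, feature_set = features,
                 accuracy = 100 * mean(pred == y[te]),
                 n_test = length(te)),
            class = "model_accuracy")
}

#' @export
print.model_accuracy <- function(x, ...) {
  cat("<model_accuracy> ", x$model_kind, " on ", length(x$feature_set),
      " feature(s): ", sprintf("%.2f%%", x$accuracy),
      " (", x$n_test, " test rows)\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio comparison of nested logistic models
#'
#' Fits logistic regressions of the outcome on a reduced and a full feature
#' set and compares them by the likelihood-ratio chi-square test with
#' degrees of freedom equal to the difference in feature counts.
#'
#' @param data Data frame with predictors and the outcome column.
#' @param reduced,full Feature-name vectors with `reduced` a subset of
#'   `full`.
#' @param outcome Name of the outcome column.
#' @return The p-value, with attributes `statistic` (deviance difference)
#'   and `df`.
#' @export
compare_nested_models <- function(data, reduced, full,
                                  outcome = "Heart Disease") {
  if (!all(reduced %in% full)) {
    stop("'reduced' must be a subset of 'full'", call. = FALSE)
  }
  xy <- .split_xy(data, outcome)
  fit_one <- function(feats) {
    x <- data.matrix(xy$x[feats])
    stats::glm.fit(cbind(1, x), xy$y, family = stats::binomial())
  }
  f_red <- fit_one(reduced)
  f_full <- fit_one(full)
  stat <- max(f_red$deviance - f_full$deviance, 0)
  df <- length(full) - length(reduced)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(p, statistic = stat, df = df)
}
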