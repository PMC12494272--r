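#' Rank predictors by L1-penalised logistic regression
#'
#' Fits a lasso-penalised logistic regression of the outcome on all
#' predictors, standardised beforehand to zero mean and unit variance so
#' coefficient magnitudes are comparable, and scores each feature by its
#' absolute coefficient at the selected penalty. The penalty defaults to the
#' deviance-minimising value from 10-fold cross-validation with
#' seed-controlled folds.
#'
#' @param data Data frame with predictors and the outcome column.
#' @param outcome Name of the outcome column.
#' @param seed Integer seed controlling the cross-validation folds.
#' @param lambda Optional fixed penalty; `NULL` (default) selects by
#'   cross-validation.
#' @param nfolds Folds for [glmnet::cv.glmnet()] (default 10).
#' @param k Number of features for the `selected` slot.
#' @return An `importance_result` with `scores = |coefficient|` on the
#'   standardised scale and the chosen `lambda`.
#' @export
lasso_rank <- function(data, outcome = "Heart Disease", seed,
                       lambda = NULL, nfolds = 10, k = 5) {
  if (missing(seed)) seed <- 1L
  xy <- .split_xy(data, outcome)
  x <- data.matrix(xy$x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  xs <- scale(x)
  y <- xy$y

  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), length(y)))
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                            standardize = FALSE, foldid = foldid,
                            type.measure = "deviance")
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  co <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE,
                               x = xs, y = y))[-1]
  if (any(!is.finite(co))) {
    stop("lasso fit did not converge at penalty ", signif(lambda, 4),
         call. = FALSE)
  }
  scores <- abs(co)
  names(scores) <- colnames(xy$x)
  new_importance_result("lasso", scores, k = k,
                        extra = list(lambda = lambda))
}
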