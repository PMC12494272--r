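#' Shannon entropy of a label vector, in bits
#'
#' `H = -sum_v p_v log2 p_v` over the observed label values; for binary
#' labels `0 <= H <= 1`.
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits.
#' @export
entropy <- function(labels) {
  if (!length(labels)) stop("labels must be non-empty", call. = FALSE)
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency binning for continuous features; ties may merge bins
.discretize <- function(x, bins) {
  if (!is.numeric(x) || length(unique(x)) <= bins) return(x)
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Information gain of a feature about a label
#'
#' The reduction in label entropy from conditioning on the feature's groups:
#' `IG = H(Y) - sum_g (n_g/n) H(Y | g)`. Continuous features (more distinct
#' values than `bins`) are first discretised by equal-frequency binning.
#'
#' @param feature Feature vector, same length as `labels`.
#' @param labels Class label vector.
#' @param bins Number of equal-frequency bins for continuous features
#'   (default 5).
#' @return Non-negative information gain in bits; at most `H(labels)`.
#' @export
information_gain <- function(feature, labels, bins = 5) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length", call. = FALSE)
  }
  g <- .discretize(feature, bins)
  n <- length(labels)
  cond <- vapply(split(labels, g),
                 function(part) length(part) / n * entropy(part),
                 numeric(1))
  ig <- entropy(labels) - sum(cond)
  max(ig, 0) # guard tiny negative round-off
}

#' Rank predictors by information gain
#'
#' @param data Data frame holding the predictors and the outcome column
#'   (a `cohort_table` works as is).
#' @param outcome Name of the outcome column (default `"Heart Disease"`).
#' @param bins Bins for continuous features, passed to [information_gain()].
#' @param k Number of features to select.
#' @return An `importance_result` (see [rank_features()]).
#' @export
information_gain_rank <- function(data, outcome = "Heart Disease",
                                  bins = 5, k = 5) {
  xy <- .split_xy(data, outcome)
  scores <- vapply(xy$x, information_gain, numeric(1),
                   labels = xy$y, bins = bins)
  new_importance_result("information_gain", scores, k = k)
}

# ---- shared ImportanceResult plumbing ---------------------------------------

.split_xy <- function(data, outcome) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  x <- as.data.frame(data[setdiff(names(data), outcome)])
  list(x = x, y = .encode_outcome(data[[outcome]]))
}

# ranks: descending score, ties broken by original column order
new_importance_result <- function(method, scores, decisions = NULL, k = 5,
                                  extra = list()) {
  k <- min(k, length(scores))
  ord <- order(-scores, seq_along(scores))
  ranks <- match(seq_along(scores), ord)
  names(ranks) <- names(scores)
  res <- c(list(method = method, scores = scores, ranks = ranks,
                decisions = decisions,
                selected = names(scores)[ord[seq_len(k)]], k = k),
           extra)
  structure(res, class = "importance_result")
}

#' Take the top-k features of a ranking
#'
#' @param result An `importance_result`.
#' @param k How many features (must not exceed the number ranked).
#' @return Character vector of the `k` highest-scoring feature names, in
#'   descending score order; ties break by original column order.
#' @export
select_top_k <- function(result, k = 5) {
  stopifnot(inherits(result, "importance_result"))
  if (k > length(result$scores) || k < 1) {
    stop("k must be in 1..", length(result$scores), call. = FALSE)
  }
  names(result$scores)[order(-result$scores,
                             seq_along(result$scores))[seq_len(k)]]
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> method:", x$method, "\n")
  tab <- data.frame(feature = names(x$scores),
                    score = round(unname(x$scores), 4),
                    rank = unname(x$ranks))
  if (!is.null(x$decisions)) tab$decision <- unname(x$decisions)
  print(tab[order(tab$rank), ], row.names = FALSE)
  cat("selected (k=", x$k, "): ", paste(x$selected, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.importance_result <- function(x, ...) {
  data.frame(feature = names(x$scores), method = x$method,
             score = unname(x$scores), rank = unname(x$ranks),
             decision = if (is.null(x$decisions)) NA_character_
                        else unname(x$decisions),
             row.names = NULL)
}
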