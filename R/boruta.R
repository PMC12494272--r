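#' Shadow-feature random-forest selection
#'
#' All-relevant feature selection by comparison against permuted "shadow"
#' copies. Each iteration appends to the predictors an independently
#' row-permuted copy of every feature, fits a random forest, and credits a
#' feature with a "hit" when its permutation (out-of-bag accuracy)
#' importance exceeds the largest shadow importance. Cumulative hit counts are tested against
#' Binomial(iterations, 1/2) two-sidedly at level `alpha` with Bonferroni
#' correction across features: significantly many hits confirms a feature,
#' significantly few rejects it. Features still undecided after `max_iter`
#' iterations are resolved by the rough fix — confirmed when their median
#' importance over all iterations exceeds the median of the per-iteration
#' shadow maxima, rejected otherwise.
#'
#' @param data Data frame with predictors and the outcome column.
#' @param outcome Name of the outcome column.
#' @param max_iter Maximum number of forest iterations (default 100).
#' @param alpha Two-sided test level before Bonferroni correction
#'   (default 0.01).
#' @param rf_params Named list of [ranger::ranger()] arguments overriding
#'   the defaults (500 trees, `floor(sqrt(2p))` variables per split over
#'   the doubled feature matrix, permutation importance).
#' @param seed Integer seed; mandatory, the procedure is randomised.
#' @param k Number of features for the `selected` slot.
#' @param rough_fix Resolve leftover tentative features (default `TRUE`).
#' @return An `importance_result` with per-feature mean importances, hit
#'   counts, and decisions in `confirmed`/`rejected` (plus `tentative` when
#'   `rough_fix = FALSE`).
#' @export
boruta_select <- function(data, outcome = "Heart Disease", max_iter = 100,
                          alpha = 0.01, rf_params = list(), seed,
                          k = 5, rough_fix = TRUE) {
  if (missing(seed)) stop("seed is mandatory for boruta_select", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  xy <- .split_xy(data, outcome)
  x <- data.matrix(xy$x)
  p <- ncol(x)
  feat_names <- colnames(xy$x)
  colnames(x) <- paste0("V", seq_len(p)) # ranger-safe names
  y <- factor(xy$y)

  set.seed(seed)
  hits <- integer(p)
  decided <- rep(NA_character_, p) # NA = tentative
  imp_hist <- matrix(NA_real_, nrow = max_iter, ncol = p)
  shadow_max <- numeric(max_iter)
  iters <- 0L

  # permutation (OOB accuracy) importance: a permuted shadow is the exact
  # null of this measure, whereas impurity importance of a continuous
  # feature stays biased upward and inflates false confirmations
  rf_args <- utils::modifyList(
    list(num.trees = 500, importance = "permutation",
         mtry = floor(sqrt(2 * p)), num.threads = 1),
    rf_params)

  for (i in seq_len(max_iter)) {
    iters <- i
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("S", seq_len(p))
    df <- as.data.frame(cbind(x, shadow))
    fit <- do.call(ranger::ranger,
                   c(list(x = df, y = y, seed = sample.int(.Machine$integer.max, 1)),
                     rf_args))
    imp <- fit$variable.importance
    smax <- max(imp[colnames(shadow)])
    shadow_max[i] <- smax
    fi <- imp[colnames(x)]
    imp_hist[i, ] <- fi
    hits <- hits + as.integer(fi > smax)

    undec <- which(is.na(decided))
    thr <- alpha / (2 * p) # Bonferroni, two one-sided tests
    p_hi <- stats::pbinom(hits[undec] - 1L, i, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[undec], i, 0.5)
    decided[undec[p_hi < thr]] <- "confirmed"
    decided[undec[p_lo < thr]] <- "rejected"
    if (!anyNA(decided)) break
  }

  imp_hist <- imp_hist[seq_len(iters), , drop = FALSE]
  decisions_raw <- ifelse(is.na(decided), "tentative", decided)
  decisions <- decisions_raw
  if (rough_fix && anyNA(decided)) {
    med_shadow <- stats::median(shadow_max[seq_len(iters)])
    for (j in which(is.na(decided))) {
      decisions[j] <- if (stats::median(imp_hist[, j]) > med_shadow)
        "confirmed" else "rejected"
    }
  }
  scores <- colMeans(imp_hist)
  names(scores) <- feat_names
  names(decisions) <- names(decisions_raw) <- names(hits) <- feat_names
  if (!any(decisions == "confirmed")) {
    warning("no features confirmed; selected set may be meaningless")
  }
  new_importance_result("boruta", scores, decisions = decisions, k = k,
                        extra = list(hits = hits, iterations = iters,
                                     decisions_raw = decisions_raw,
                                     shadow_max = shadow_max[seq_len(iters)]))
}
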