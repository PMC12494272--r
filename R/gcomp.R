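#' Average treatment effect by g-computation
#'
#' Fits the main-effects Q-model, standardises the counterfactual risks
#' `pi1` (everyone treated) and `pi0` (no one treated) over the empirical
#' confounder distribution, and returns their difference (the ATE) together
#' with the marginal log odds ratio.
#'
#' @param frame A `treatment_frame`.
#' @param interactions Passed to [fit_q_model()]; diagnostic use only.
#' @return A `gcomp_point` list: `pi0`, `pi1`, `delta` (= `pi1 - pi0`),
#'   `log_or`, and the fitted `model`.
#' @export
ate <- function(frame, interactions = FALSE) {
  model <- fit_q_model(frame, interactions = interactions)
  pi0 <- standardized_risk(model, frame, 0)
  pi1 <- standardized_risk(model, frame, 1)
  structure(list(pi0 = pi0, pi1 = pi1, delta = pi1 - pi0,
                 log_or = marginal_log_or(pi1, pi0), model = model,
                 treatment_name = frame$treatment_name),
            class = "gcomp_point")
}

#' @export
print.gcomp_point <- function(x, ...) {
  cat("<gcomp_point> treatment '", x$treatment_name, "'\n",
      sprintf("  pi0 = %.4f, pi1 = %.4f, ATE = %.4f, logOR = %.4f\n",
              x$pi0, x$pi1, x$delta, x$log_or), sep = "")
  invisible(x)
}

#' Marginal log odds ratio of two standardised risks
#'
#' @param pi1,pi0 Standardised risks, strictly inside (0,1).
#' @return `log[(pi1/(1-pi1)) / (pi0/(1-pi0))]`.
#' @export
marginal_log_or <- function(pi1, pi0) {
  if (pi0 <= 0 || pi0 >= 1 || pi1 <= 0 || pi1 >= 1) {
    stop("risks on the boundary give an infinite odds ratio", call. = FALSE)
  }
  log(pi1 / (1 - pi1)) - log(pi0 / (1 - pi0))
}

# one g-computation pass on raw vectors; errors propagate to the caller
.gcomp_once <- function(tr, y, C) {
  fit <- .logit_fit(.q_design(tr, C), y)
  co <- fit$coefficients
  p1 <- mean(stats::plogis(drop(.q_design(rep(1L, length(tr)), C) %*% co)))
  p0 <- mean(stats::plogis(drop(.q_design(rep(0L, length(tr)), C) %*% co)))
  c(pi0 = p0, pi1 = p1)
}

#' Bootstrap inference for the g-computation estimator
#'
#' Resamples rows with replacement `B` times, refits the Q-model and
#' recomputes the standardised risks on every resample. Standard errors are
#' resample standard deviations; confidence intervals are percentile by
#' default or normal-approximation (`estimate +/- 1.96 * SE`); the p-value
#' is the two-sided normal-approximation test of `delta = 0` (equivalently
#' OR = 1) using the bootstrap SE. Degenerate resamples — an empty
#' treatment arm, a single-class outcome, or a separated fit — are redrawn
#' so that exactly `B` valid resamples contribute; the redraw count is
#' recorded, and inference is refused when redraws exceed `B` (more than
#' half of all draws degenerate).
#'
#' @param frame A `treatment_frame`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; mandatory.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `gcomp_result` with the point estimates (`pi0`, `pi1`,
#'   `delta`, `log_or`), bootstrap `se_delta`/`se_log_or`, `ci_delta`/
#'   `ci_log_or`, the bilateral `p_value`, `n_boot`, `n_redraws`, `seed`.
#' @export
bootstrap_inference <- function(frame, B = 1000, seed,
                                ci_method = c("percentile", "normal"),
                                conf_level = 0.95) {
  stopifnot(inherits(frame, "treatment_frame"))
  if (missing(seed)) stop("seed is mandatory for bootstrap_inference",
                          call. = FALSE)
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  ci_method <- match.arg(ci_method)

  point <- .gcomp_once(frame$T, frame$Y, frame$C)
  delta_hat <- unname(point["pi1"] - point["pi0"])
  logor_hat <- marginal_log_or(point["pi1"], point["pi0"])

  set.seed(seed)
  n <- length(frame$T)
  deltas <- numeric(B); logors <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      tr <- frame$T[idx]; y <- frame$Y[idx]
      est <- if (length(unique(tr)) < 2 || length(unique(y)) < 2) NULL else
        tryCatch(.gcomp_once(tr, y, frame$C[idx, , drop = FALSE]),
                 error = function(e) NULL)
      if (!is.null(est)) break
      redraws <- redraws + 1L
      if (redraws > B) {
        stop("more than half of bootstrap resamples were degenerate; ",
             "inference refused", call. = FALSE)
      }
    }
    deltas[b] <- est["pi1"] - est["pi0"]
    logors[b] <- marginal_log_or(est["pi1"], est["pi0"])
  }

  se_delta <- stats::sd(deltas)
  se_logor <- stats::sd(logors)
  aq <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  z <- stats::qnorm(aq[2])
  ci <- function(est, draws, se) {
    if (ci_method == "percentile") unname(stats::quantile(draws, aq))
    else est + c(-z, z) * se
  }
  p_value <- if (se_delta > 0) 2 * stats::pnorm(-abs(delta_hat) / se_delta)
             else as.numeric(delta_hat == 0)

  structure(list(pi0 = unname(point["pi0"]), pi1 = unname(point["pi1"]),
                 delta = delta_hat, log_or = unname(logor_hat),
                 se_delta = se_delta, se_log_or = se_logor,
                 ci_delta = ci(delta_hat, deltas, se_delta),
                 ci_log_or = ci(unname(logor_hat), logors, se_logor),
                 p_value = p_value, conf_level = conf_level,
                 ci_method = ci_method, n_boot = B, n_redraws = redraws,
                 seed = as.integer(seed),
                 treatment_name = frame$treatment_name),
            class = "gcomp_result")
}

#' @export
print.gcomp_result <- function(x, ...) {
  cat("<gcomp_result> treatment '", x$treatment_name, "' (B = ", x$n_boot,
      ", ", x$ci_method, " CI)\n", sep = "")
  cat(sprintf("  pi0 = %.4f, pi1 = %.4f\n", x$pi0, x$pi1))
  cat(sprintf("  ATE   = %.4f  [%.4f, %.4f]  se = %.4f\n",
              x$delta, x$ci_delta[1], x$ci_delta[2], x$se_delta))
  cat(sprintf("  logOR = %.4f  [%.4f, %.4f]  se = %.4f\n",
              x$log_or, x$ci_log_or[1], x$ci_log_or[2], x$se_log_or))
  cat(sprintf("  bilateral p-value (OR = 1): %.4g\n", x$p_value))
  if (x$n_redraws > 0) cat("  degenerate resamples redrawn:", x$n_redraws, "\n")
  invisible(x)
}

#' Raw, conditional, and marginal odds-ratio decomposition
#'
#' Three views of the treatment-outcome odds ratio: *raw*, from the
#' unadjusted 2x2 cross-product (equivalently logistic `Y ~ T`);
#' *conditional*, `exp(alpha)` from the covariate-adjusted Q-model; and
#' *marginal*, from the standardised risks. Odds ratios are
#' non-collapsible, so the three generally differ even without
#' confounding; with no confounders all three coincide exactly.
#'
#' @param frame A `treatment_frame`.
#' @return An `or_decomposition` list: `raw_or`, `conditional_or`,
#'   `marginal_or`, all strictly positive.
#' @export
or_decomposition <- function(frame) {
  stopifnot(inherits(frame, "treatment_frame"))
  tab <- table(factor(frame$T, 0:1), factor(frame$Y, 0:1))
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty 2x2 cell (T=", rownames(tab)[idx[1]], ", Y=",
         colnames(tab)[idx[2]], ") gives an infinite odds ratio",
         call. = FALSE)
  }
  raw <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  pt <- ate(frame)
  structure(list(raw_or = unname(raw),
                 conditional_or = exp(pt$model$alpha),
                 marginal_or = exp(pt$log_or),
                 treatment_name = frame$treatment_name),
            class = "or_decomposition")
}

#' @export
print.or_decomposition <- function(x, ...) {
  cat("<or_decomposition> treatment '", x$treatment_name, "'\n",
      sprintf("  raw = %.4f, conditional = %.4f, marginal = %.4f\n",
              x$raw_or, x$conditional_or, x$marginal_or), sep = "")
  invisible(x)
}

#' Full g-computation analysis of one treatment
#'
#' Convenience wrapper: point estimation ([ate()]), bootstrap inference
#' ([bootstrap_inference()]), and the odds-ratio decomposition
#' ([or_decomposition()]).
#'
#' @inheritParams bootstrap_inference
#' @return List with elements `result` (a `gcomp_result`) and
#'   `decomposition` (an `or_decomposition`).
#' @export
gcompute <- function(frame, B = 1000, seed,
                     ci_method = c("percentile", "normal")) {
  list(result = bootstrap_inference(frame, B = B, seed = seed,
                                    ci_method = ci_method),
       decomposition = or_decomposition(frame))
}
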