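.q_design <- function(tr, C, interactions = FALSE) {
  X <- cbind(`(Intercept)` = 1, T = tr, C)
  if (interactions && ncol(C)) {
    XI <- C * tr
    colnames(XI) <- paste0("T:", colnames(C))
    X <- cbind(X, XI)
  }
  X
}

# lean IRLS logistic fit on a design matrix; used everywhere a Q-model is fit
.logit_fit <- function(X, y) {
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  }
  # glm.fit's own warnings (non-convergence, boundary fitted values) are
  # superseded by the explicit errors below
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-14,
                                                maxit = 100)))
  co <- fit$coefficients
  # diverging coefficients on binary columns signal separation
  bin <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  if (any(abs(co[bin]) > 15, na.rm = TRUE)) {
    stop("perfect or quasi-perfect separation detected (coefficient ",
         "diverged for: ",
         paste(colnames(X)[bin][abs(co[bin]) > 15], collapse = ", "), ")",
         call. = FALSE)
  }
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  fit
}

#' Fit the logistic outcome (Q) model
#'
#' Maximum-likelihood logistic regression of the outcome on the treatment
#' and confounders, `logit P(Y=1 | T, C) = intercept + alpha*T + beta'C`.
#' This is the outcome model standardised over in g-computation. Treatment
#' by confounder interactions can be added for diagnostic use; the default
#' analysis model is main-effects only.
#'
#' @param frame A `treatment_frame`.
#' @param interactions Add `T:C` interaction terms (default `FALSE`).
#' @return A `q_model`: `intercept`, `alpha` (treatment log-odds ratio),
#'   `beta` (named confounder coefficients), `coefficients` (full vector),
#'   `log_likelihood`, `converged`, `interactions`.
#' @export
fit_q_model <- function(frame, interactions = FALSE) {
  stopifnot(inherits(frame, "treatment_frame"))
  X <- .q_design(frame$T, frame$C, interactions)
  fit <- .logit_fit(X, frame$Y)
  co <- fit$coefficients
  structure(list(intercept = unname(co[1]), alpha = unname(co[2]),
                 beta = co[-(1:2)], coefficients = co,
                 log_likelihood = -fit$deviance / 2,
                 converged = fit$converged,
                 interactions = interactions),
            class = "q_model")
}

#' @export
print.q_model <- function(x, ...) {
  cat("<q_model> logit P(Y=1|T,C) = ", sprintf("%.4f", x$intercept),
      " + ", sprintf("%.4f", x$alpha), "*T",
      if (length(x$beta)) paste0(" + beta'C [",
        paste(sprintf("%s=%.4f", names(x$beta), x$beta), collapse = ", "),
        "]") else "",
      "\n  logLik = ", sprintf("%.3f", x$log_likelihood), "\n", sep = "")
  invisible(x)
}

#' Standardised counterfactual risk
#'
#' The g-formula risk under the intervention `do(T = a)`: every subject's
#' outcome probability is predicted from the Q-model with the treatment
#' forced to `a` and their confounders unchanged, and the predictions are
#' averaged over all n subjects.
#'
#' @param model A `q_model` fitted on `frame`.
#' @param frame The `treatment_frame` the model was fitted on.
#' @param a Treatment level, 0 or 1.
#' @return The standardised risk, a probability.
#' @export
standardized_risk <- function(model, frame, a) {
  stopifnot(inherits(model, "q_model"), inherits(frame, "treatment_frame"))
  if (!(length(a) == 1 && a %in% c(0, 1))) {
    stop("treatment level 'a' must be 0 or 1", call. = FALSE)
  }
  Xa <- .q_design(rep(a, length(frame$T)), frame$C, model$interactions)
  mean(stats::plogis(drop(Xa %*% model$coefficients)))
}
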