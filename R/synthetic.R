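#' Specification of a confounded synthetic cohort
#'
#' Defines the generating process the causal analysis assumes: independent
#' binary confounders `C`, a confounder-dependent treatment
#' `T ~ Bernoulli(plogis(gamma0 + gamma'C))`, and a logistic structural
#' outcome `Y ~ Bernoulli(plogis(intercept + alpha*T + beta'C))`. Because
#' the coefficients are known, the true standardised risks and ATE are
#' exactly computable by [true_effects()].
#'
#' The defaults mimic the scale of a small observational cardiac cohort:
#' n = 270, three binary confounders with prevalences 0.3/0.5/0.4, genuine
#' confounding (`gamma != 0`), and a treatment log-odds ratio of 1 — chosen
#' to put the marginal odds ratio in the single digits, the order seen in
#' such cohorts. They are package defaults, not estimates from any dataset.
#'
#' @param n Cohort size (default 270).
#' @param conf_prev Confounder prevalences, each in (0,1).
#' @param gamma Treatment-model coefficients `(gamma0, gamma_1..gamma_p)`;
#'   length `length(conf_prev) + 1`.
#' @param intercept Outcome-model intercept.
#' @param alpha True treatment coefficient (conditional log odds ratio).
#' @param beta True confounder coefficients; length `length(conf_prev)`.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n = 270,
                           conf_prev = c(0.3, 0.5, 0.4),
                           gamma = c(-0.5, 0.6, 0.4, -0.3),
                           intercept = -1.2,
                           alpha = 1.0,
                           beta = c(0.5, -0.4, 0.8)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(conf_prev <= 0) || any(conf_prev >= 1)) {
    stop("confounder prevalences must be in (0,1)", call. = FALSE)
  }
  if (length(gamma) != length(conf_prev) + 1) {
    stop("gamma must have length ", length(conf_prev) + 1,
         " (intercept + one per confounder)", call. = FALSE)
  }
  if (length(beta) != length(conf_prev)) {
    stop("beta must have one coefficient per confounder", call. = FALSE)
  }
  structure(list(n = as.integer(n), conf_prev = conf_prev, gamma = gamma,
                 intercept = intercept, alpha = alpha, beta = beta),
            class = "generator_spec")
}

#' Exact causal truth implied by a generator specification
#'
#' Standardises the structural outcome model over the exact confounder
#' distribution by exhaustive summation over the `2^p` binary strata:
#' `true_pi_a = sum_c P(c) plogis(intercept + alpha*a + beta'c)`.
#'
#' @param spec A [generator_spec()].
#' @return A `synthetic_truth` list: `true_pi0`, `true_pi1`, `true_ate`,
#'   `true_marginal_or`.
#' @export
true_effects <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  p <- length(spec$conf_prev)
  grid <- as.matrix(expand.grid(rep(list(0:1), p)))
  w <- apply(grid, 1, function(c_row) {
    prod(ifelse(c_row == 1, spec$conf_prev, 1 - spec$conf_prev))
  })
  risk <- function(a) {
    sum(w * stats::plogis(spec$intercept + spec$alpha * a +
                            drop(grid %*% spec$beta)))
  }
  pi0 <- risk(0); pi1 <- risk(1)
  structure(list(true_pi0 = pi0, true_pi1 = pi1, true_ate = pi1 - pi0,
                 true_marginal_or = exp(marginal_log_or(pi1, pi0))),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> pi0 = %.4f, pi1 = %.4f, ATE = %.4f, marginal OR = %.4f\n",
    x$true_pi0, x$true_pi1, x$true_ate, x$true_marginal_or))
  invisible(x)
}

# draw order contract: confounders (column-wise), then T, then Y
.draw_tf <- function(spec) {
  n <- spec$n
  C <- vapply(spec$conf_prev, function(p) stats::rbinom(n, 1, p), numeric(n))
  colnames(C) <- paste0("C", seq_along(spec$conf_prev))
  tr <- stats::rbinom(n, 1, stats::plogis(spec$gamma[1] +
                                            drop(C %*% spec$gamma[-1])))
  y <- stats::rbinom(n, 1, stats::plogis(spec$intercept + spec$alpha * tr +
                                           drop(C %*% spec$beta)))
  list(C = C, tr = tr, y = y)
}

#' Generate a synthetic confounded cohort
#'
#' Draws a cohort from a [generator_spec()] under a fixed seed and returns
#' it together with its exact causal truth. Two output shapes:
#' \describe{
#'   \item{`table1_mode = FALSE`}{a `treatment_frame` (T, Y, C) ready for
#'     the causal stage;}
#'   \item{`table1_mode = TRUE`}{a full 14-column `cohort_table` with the
#'     standard clinical schema. Requires the default three confounders,
#'     which become the vessel count (3 vs 0-2), sex, and cholesterol
#'     (above vs below 240 mg/dl); the treatment becomes the thallium code
#'     (7 vs 3/6). The nine remaining predictors are drawn independently of
#'     the outcome from plausible marginal ranges, after Y in the draw
#'     order.}
#' }
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed; mandatory, one seed yields one cohort.
#' @param table1_mode Emit the full clinical schema (default `FALSE`).
#' @return List with elements `data` (a `treatment_frame` or
#'   `cohort_table`) and `truth` (a `synthetic_truth`).
#' @export
generate_cohort <- function(spec = generator_spec(), seed,
                            table1_mode = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  if (missing(seed)) stop("seed is mandatory for generate_cohort",
                          call. = FALSE)
  truth <- true_effects(spec)
  set.seed(seed)
  d <- .draw_tf(spec)

  if (!table1_mode) {
    data <- new_treatment_frame(d$tr, d$y, d$C, treatment_name = "T")
    return(list(data = data, truth = truth))
  }

  if (length(spec$conf_prev) != 3) {
    stop("table1_mode requires exactly three confounders ",
         "(vessels, sex, cholesterol)", call. = FALSE)
  }
  n <- spec$n
  vessels <- ifelse(d$C[, 1] == 1, 3L, sample(0:2, n, replace = TRUE))
  sex <- d$C[, 2]
  chol <- ifelse(d$C[, 3] == 1,
                 sample(240:564, n, replace = TRUE),
                 sample(126:239, n, replace = TRUE))
  thal <- ifelse(d$tr == 1, 7L, sample(c(3L, 6L), n, replace = TRUE))
  df <- data.frame(
    check.names = FALSE,
    Age = sample(29:77, n, replace = TRUE),
    Sex = sex,
    `Chest pain type` = sample(1:4, n, replace = TRUE),
    BP = sample(94:200, n, replace = TRUE),
    Cholesterol = chol,
    `FBS over 120` = stats::rbinom(n, 1, 0.15),
    `EKG results` = sample(0:2, n, replace = TRUE),
    `Max HR` = sample(71:202, n, replace = TRUE),
    `Exercise angina` = stats::rbinom(n, 1, 0.33),
    `ST depression` = round(stats::runif(n, 0, 6.2), 1),
    `Slope of ST` = sample(1:3, n, replace = TRUE),
    `Number of vessels fluro` = vessels,
    Thallium = thal,
    `Heart Disease` = d$y
  )
  list(data = as_cohort(df), truth = truth)
}
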