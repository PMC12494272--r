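#' Configuration for an end-to-end pipeline run
#'
#' All seeds are materialised here: a resolved config fully determines the
#' run, and the manifest written by [run_pipeline()] reproduces it
#' byte-for-byte.
#'
#' @param data_path Path to a cohort CSV, or `NULL` to simulate.
#' @param sim_spec A [generator_spec()] used when `data_path` is `NULL`.
#' @param sim_seed Seed for the simulated cohort.
#' @param methods Ranking methods to run, subset of
#'   `c("information_gain", "boruta", "lasso")`.
#' @param k Features to select per method (default 5).
#' @param bins Discretisation bins for information gain.
#' @param selection_seed Seed for Boruta, lasso folds, and the train/test
#'   split.
#' @param treatments Treatments to analyse, subset of
#'   `names(treatment_set())` (default all four).
#' @param B Bootstrap resamples per treatment.
#' @param causal_seed Seed for the bootstrap.
#' @param ci_method `"percentile"` or `"normal"`.
#' @param boruta_max_iter,boruta_rf_params Forwarded to [boruta_select()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(data_path = NULL, sim_spec = generator_spec(),
                       sim_seed = 1L,
                       methods = c("information_gain", "boruta", "lasso"),
                       k = 5, bins = 5, selection_seed = 1L,
                       treatments = names(treatment_set()),
                       B = 1000, causal_seed = 1L,
                       ci_method = "percentile",
                       boruta_max_iter = 100, boruta_rf_params = list(),
                       out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  treatments <- match.arg(treatments, names(treatment_set()),
                          several.ok = TRUE)
  if (!is.null(data_path) && !file.exists(data_path)) {
    stop("data file not found: ", data_path, call. = FALSE)
  }
  structure(list(data_path = data_path, sim_spec = sim_spec,
                 sim_seed = as.integer(sim_seed), methods = methods, k = k,
                 bins = bins, selection_seed = as.integer(selection_seed),
                 treatments = treatments, B = B,
                 causal_seed = as.integer(causal_seed),
                 ci_method = ci_method,
                 boruta_max_iter = boruta_max_iter,
                 boruta_rf_params = boruta_rf_params,
                 out_dir = out_dir),
            class = "run_config")
}

.rank_one <- function(method, cohort, config) {
  switch(method,
    information_gain = information_gain_rank(cohort, bins = config$bins,
                                             k = config$k),
    boruta = boruta_select(cohort, max_iter = config$boruta_max_iter,
                           rf_params = config$boruta_rf_params,
                           seed = config$selection_seed, k = config$k),
    lasso = lasso_rank(cohort, seed = config$selection_seed, k = config$k))
}

#' Run the full two-stage analysis
#'
#' Orchestrates the pipeline on a cohort read from disk or simulated with
#' known truth: (1) feature rankings by the configured methods plus
#' held-out accuracy of each top-k set against the full 13-feature set,
#' for logistic regression and random forest; (2) per-treatment
#' g-computation with bootstrap inference and the odds-ratio
#' decomposition; (3) a manifest holding every seed and setting. When
#' `out_dir` is set, the tables are written as CSV and the manifest (and
#' simulation truth, if any) as JSON.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: `rankings` (per-method
#'   `importance_result`s), `accuracy` (data frame), `causal` (per-treatment
#'   [gcompute()] output), `causal_table`, `or_table`, `truth` (when
#'   simulated), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  truth <- NULL
  if (is.null(config$data_path)) {
    sim <- generate_cohort(config$sim_spec, seed = config$sim_seed,
                           table1_mode = TRUE)
    cohort <- sim$data
    truth <- sim$truth
  } else {
    cohort <- read_cohort(config$data_path)
  }

  # stage 1: rankings + accuracy
  rankings <- lapply(config$methods, .rank_one, cohort = cohort,
                     config = config)
  names(rankings) <- config$methods
  split <- split_spec(seed = config$selection_seed)
  feature_sets <- c(list(full = predictor_columns()),
                    lapply(rankings, `[[`, "selected"))
  accuracy <- do.call(rbind, lapply(names(feature_sets), function(nm) {
    do.call(rbind, lapply(c("logistic_regression", "random_forest"),
      function(mk) {
        acc <- evaluate_accuracy(cohort, feature_sets[[nm]], mk,
                                 split = split)
        data.frame(feature_set = nm, model = mk, accuracy = acc$accuracy,
                   n_features = length(feature_sets[[nm]]))
      }))
  }))

  # stage 2: g-computation per treatment
  causal <- lapply(config$treatments, function(trt) {
    frame <- make_treatment_frame(cohort, trt)
    gcompute(frame, B = config$B, seed = config$causal_seed,
             ci_method = config$ci_method)
  })
  names(causal) <- config$treatments
  causal_table <- do.call(rbind, lapply(config$treatments, function(trt) {
    r <- causal[[trt]]$result
    data.frame(treatment = treatment_set()[[trt]],
               pi0 = r$pi0, pi1 = r$pi1, ATE = r$delta, logOR = r$log_or,
               se_ATE = r$se_delta, ci_lower = r$ci_delta[1],
               ci_upper = r$ci_delta[2], p_value = r$p_value,
               n_redraws = r$n_redraws)
  }))
  or_table <- do.call(rbind, lapply(config$treatments, function(trt) {
    d <- causal[[trt]]$decomposition
    data.frame(treatment = treatment_set()[[trt]], raw = d$raw_or,
               conditional = d$conditional_or, marginal = d$marginal_or)
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("heartgc")),
    data = if (is.null(config$data_path)) "simulated" else config$data_path,
    n = nrow(cohort),
    seeds = list(sim = config$sim_seed, selection = config$selection_seed,
                 causal = config$causal_seed),
    settings = list(methods = config$methods, k = config$k,
                    bins = config$bins, B = config$B,
                    ci_method = config$ci_method,
                    treatments = config$treatments,
                    boruta_max_iter = config$boruta_max_iter),
    redraws = vapply(causal, function(x) x$result$n_redraws, integer(1))
  )

  report <- structure(list(rankings = rankings, accuracy = accuracy,
                           causal = causal, causal_table = causal_table,
                           or_table = or_table, truth = truth,
                           manifest = manifest),
                      class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                           row.names = FALSE)
    wr(do.call(rbind, lapply(rankings, as.data.frame)), "rankings.csv")
    wr(accuracy, "accuracy.csv")
    wr(causal_table, "gcomputation.csv")
    wr(or_table, "or_decomposition.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(truth)) {
      jsonlite::write_json(unclass(truth),
                           file.path(config$out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n\n-- held-out accuracy (%) --\n")
  print(x$accuracy, row.names = FALSE)
  cat("\n-- g-computation --\n")
  print(x$causal_table, row.names = FALSE, digits = 4)
  cat("\n-- odds-ratio decomposition --\n")
  print(x$or_table, row.names = FALSE, digits = 5)
  if (!is.null(x$truth)) { cat("\n"); print(x$truth) }
  invisible(x)
}

#' Recompute the causal tables for a cohort CSV
#'
#' For users holding a real cohort file with the standard 14-column schema:
#' runs g-computation for all four candidate treatments and returns the ATE
#' and odds-ratio decomposition tables. Point estimates (pi0, pi1, ATE,
#' log-OR, the three ORs) are deterministic; only the bootstrap intervals
#' and p-values depend on `seed`.
#'
#' @param path Path to the cohort CSV.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed (default 1).
#' @param binarize_confounders Confounder scale toggle, see
#'   [make_treatment_frame()].
#' @return A `pipeline_report`-like list with `causal_table` and
#'   `or_table`.
#' @export
reproduce_study <- function(path, B = 1000, seed = 1,
                            binarize_confounders = TRUE) {
  cohort <- read_cohort(path)
  res <- lapply(names(treatment_set()), function(trt) {
    frame <- make_treatment_frame(cohort, trt,
                                  binarize_confounders = binarize_confounders)
    gcompute(frame, B = B, seed = seed)
  })
  names(res) <- names(treatment_set())
  list(
    causal_table = do.call(rbind, lapply(names(res), function(trt) {
      r <- res[[trt]]$result
      data.frame(treatment = treatment_set()[[trt]], pi0 = r$pi0,
                 pi1 = r$pi1, ATE = r$delta, logOR = r$log_or,
                 p_value = r$p_value)
    })),
    or_table = do.call(rbind, lapply(names(res), function(trt) {
      d <- res[[trt]]$decomposition
      data.frame(treatment = treatment_set()[[trt]], raw = d$raw_or,
                 conditional = d$conditional_or, marginal = d$marginal_or)
    })),
    causal = res
  )
}
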