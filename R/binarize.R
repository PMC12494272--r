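#' Binarisation rules for the four candidate treatment variables
#'
#' The causal stage works with binary treatments. The four candidate
#' treatments ("Number of vessels fluro", "Thallium", "Sex", "Cholesterol")
#' are dichotomised by clinically motivated rules:
#' \itemize{
#'   \item vessel count: 1 if all three major vessels appear narrowed in
#'     fluoroscopy (code 3), else 0;
#'   \item thallium stress test: 1 for code 7 (reversible defect, indicative
#'     of ischemia), 0 for codes 3 (normal) and 6 (fixed defect);
#'   \item cholesterol: 1 at or above a guideline threshold, 240 mg/dl by
#'     default;
#'   \item sex: already 0/1 (1 = male) and passed through unchanged.
#' }
#' All rules are idempotent: a vector containing only 0/1 values is taken
#' to be rule output already and is returned unchanged. (For the vessel
#' rule this means a raw cohort in which no patient exceeds one narrowed
#' vessel cannot be distinguished from rule output; such a cohort has no
#' treated arm under the rule either way.)
#'
#' @param values Integer vector on the source scale.
#' @param threshold High-cholesterol cut-off (mg/dl); default 240.
#' @return Integer 0/1 vector of the same length.
#' @name binarize
NULL

#' @rdname binarize
#' @export
binarize_vessels <- function(values) {
  if (all(values %in% 0:1)) return(as.integer(values))
  .check_domain(values, 0:3, "Number of vessels fluro")
  as.integer(values == 3)
}

#' @rdname binarize
#' @export
binarize_thallium <- function(values) {
  if (all(values %in% 0:1)) return(as.integer(values))
  .check_domain(values, c(3, 6, 7), "Thallium")
  as.integer(values == 7)
}

#' @rdname binarize
#' @export
binarize_cholesterol <- function(values, threshold = 240) {
  if (all(values %in% 0:1)) return(as.integer(values))
  if (any(values <= 0)) stop("cholesterol values must be positive", call. = FALSE)
  as.integer(values >= threshold)
}

# The candidate treatment set S, keyed by shorthand.
.treatment_set <- c(
  vessels     = "Number of vessels fluro",
  thallium    = "Thallium",
  sex         = "Sex",
  cholesterol = "Cholesterol"
)

#' Candidate treatment variables
#'
#' @return Named character vector mapping shorthands (`vessels`, `thallium`,
#'   `sex`, `cholesterol`) to cohort column names.
#' @export
treatment_set <- function() .treatment_set

.resolve_treatment <- function(treatment) {
  if (treatment %in% names(.treatment_set)) return(treatment)
  hit <- names(.treatment_set)[.norm_name(.treatment_set) == .norm_name(treatment)]
  if (!length(hit)) {
    stop("treatment must be one of: ",
         paste(.treatment_set, collapse = ", "), " (got '", treatment, "')",
         call. = FALSE)
  }
  hit
}

.binarize_by_key <- function(key, values, chol_threshold) {
  switch(key,
         vessels     = binarize_vessels(values),
         thallium    = binarize_thallium(values),
         sex         = as.integer(values),
         cholesterol = binarize_cholesterol(values, chol_threshold))
}

#' Build an analysis-ready treatment frame (T, Y, C)
#'
#' Extracts from a cohort the binary treatment `T`, the binary outcome `Y`,
#' and the confounder matrix `C` holding the remaining members of the
#' candidate treatment set. By default confounders enter in binarised form
#' (the same dichotomies used when each serves as the treatment); set
#' `binarize_confounders = FALSE` to keep them on their raw scales.
#'
#' @param cohort A `cohort_table`.
#' @param treatment Treatment name: a cohort column name in
#'   [treatment_set()] or its shorthand.
#' @param binarize_confounders Logical; dichotomise confounders (default
#'   `TRUE`).
#' @param chol_threshold Cholesterol cut-off passed to
#'   [binarize_cholesterol()].
#' @return A `treatment_frame`: list with elements `T`, `Y` (integer 0/1
#'   vectors), `C` (numeric matrix), `treatment_name`, `confounder_names`.
#' @export
make_treatment_frame <- function(cohort, treatment,
                                 binarize_confounders = TRUE,
                                 chol_threshold = 240) {
  stopifnot(inherits(cohort, "cohort_table"))
  key <- .resolve_treatment(treatment)

  tr <- .binarize_by_key(key, cohort[[.treatment_set[[key]]]], chol_threshold)
  if (length(unique(tr)) < 2) {
    stop("treatment '", .treatment_set[[key]],
         "' has an empty arm after binarisation; estimation refused",
         call. = FALSE)
  }
  conf_keys <- setdiff(names(.treatment_set), key)
  C <- vapply(conf_keys, function(k) {
    v <- cohort[[.treatment_set[[k]]]]
    if (binarize_confounders) as.numeric(.binarize_by_key(k, v, chol_threshold))
    else as.numeric(v)
  }, numeric(nrow(cohort)))
  cn <- ifelse(conf_keys == "sex", "sex",
               paste0(conf_keys, if (binarize_confounders) "_bin" else ""))
  colnames(C) <- cn

  new_treatment_frame(tr, cohort[["Heart Disease"]], C,
                      treatment_name = .treatment_set[[key]])
}

#' Construct a treatment frame from raw vectors
#'
#' Low-level constructor used by [make_treatment_frame()] and the synthetic
#' generator; validates the (T, Y, C) contract.
#'
#' @param treat,outcome Integer 0/1 vectors of equal length.
#' @param C Numeric confounder matrix with `length(treat)` rows, or `NULL`
#'   for an unadjusted frame.
#' @param treatment_name Label for reporting.
#' @return A `treatment_frame`.
#' @export
new_treatment_frame <- function(treat, outcome, C = NULL,
                                treatment_name = "T") {
  treat <- as.integer(treat); outcome <- as.integer(outcome)
  stopifnot(all(treat %in% 0:1), all(outcome %in% 0:1),
            length(treat) == length(outcome))
  if (is.null(C)) {
    C <- matrix(numeric(0), nrow = length(treat), ncol = 0)
  }
  C <- as.matrix(C)
  stopifnot(nrow(C) == length(treat))
  if (ncol(C) && is.null(colnames(C))) {
    colnames(C) <- paste0("C", seq_len(ncol(C)))
  }
  if (length(unique(treat)) < 2) {
    stop("both treatment arms must be non-empty; estimation refused",
         call. = FALSE)
  }
  structure(
    list(T = treat, Y = outcome, C = C,
         treatment_name = treatment_name,
         confounder_names = colnames(C)),
    class = "treatment_frame"
  )
}

#' @export
print.treatment_frame <- function(x, ...) {
  cat("<treatment_frame> treatment '", x$treatment_name, "': n = ",
      length(x$T), ", treated = ", sum(x$T), ", events = ", sum(x$Y),
      "\n  confounders: ",
      if (length(x$confounder_names)) paste(x$confounder_names, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}
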