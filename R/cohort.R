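#' Canonical column names of the 14-column cardiac cohort table
#'
#' Thirteen clinical predictors plus the binary heart-disease outcome, in the
#' order used throughout the package (tie-breaks in feature rankings follow
#' this order).
#'
#' @return Character vector of length 14; the outcome column is last.
#' @export
cohort_columns <- function() {
  c("Age", "Sex", "Chest pain type", "BP", "Cholesterol", "FBS over 120",
    "EKG results", "Max HR", "Exercise angina", "ST depression",
    "Slope of ST", "Number of vessels fluro", "Thallium", "Heart Disease")
}

#' @rdname cohort_columns
#' @export
predictor_columns <- function() {
  setdiff(cohort_columns(), "Heart Disease")
}

# trim + casefold + collapse internal whitespace, for header matching
.norm_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

.encode_outcome <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) {
      stop("numeric outcome must be coded 0/1; found: ",
           paste(utils::head(setdiff(unique(y), c(0, 1))), collapse = ", "),
           call. = FALSE)
    }
    return(as.integer(y))
  }
  lv <- .norm_name(as.character(y))
  if (!all(lv %in% c("presence", "absence"))) {
    stop("outcome must be 'Presence'/'Absence' or 0/1; found: ",
         paste(utils::head(setdiff(unique(lv), c("presence", "absence"))),
               collapse = ", "),
         call. = FALSE)
  }
  as.integer(lv == "presence")
}

#' Validate a data frame as a cardiac cohort table
#'
#' Checks the schema (all 14 columns of [cohort_columns()] present), the
#' absence of missing values, the outcome coding, and the value domains of
#' the coded predictors: vessel count in \{0,1,2,3\}, thallium result in
#' \{3,6,7\}, sex in \{0,1\}, cholesterol a positive integer.
#'
#' @param x A data frame. The outcome may be coded `"Presence"`/`"Absence"`
#'   or 0/1; it is returned as integer 0/1 (1 = disease present).
#' @return The validated table with canonical column names and class
#'   `cohort_table`.
#' @export
as_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  have <- .norm_name(names(x))
  want <- .norm_name(cohort_columns())
  miss <- cohort_columns()[!(want %in% have)]
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- x[match(want, have)]
  names(x) <- cohort_columns()

  for (j in seq_along(x)) {
    bad <- which(is.na(x[[j]]))
    if (length(bad)) {
      stop("missing value in column '", names(x)[j], "' at row ", bad[1],
           call. = FALSE)
    }
  }
  x[["Heart Disease"]] <- .encode_outcome(x[["Heart Disease"]])

  .check_domain(x[["Number of vessels fluro"]], 0:3, "Number of vessels fluro")
  .check_domain(x[["Thallium"]], c(3, 6, 7), "Thallium")
  .check_domain(x[["Sex"]], 0:1, "Sex")
  chol <- x[["Cholesterol"]]
  if (!is.numeric(chol) || any(chol <= 0) || any(chol != round(chol))) {
    stop("'Cholesterol' must be a positive integer", call. = FALSE)
  }
  structure(x, class = c("cohort_table", "data.frame"))
}

.check_domain <- function(v, domain, name) {
  bad <- setdiff(unique(v), domain)
  if (length(bad)) {
    stop("column '", name, "' contains value(s) outside {",
         paste(domain, collapse = ","), "}: ",
         paste(utils::head(bad), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cardiac cohort CSV
#'
#' Reads an RFC-4180 comma-separated file with a header row holding the 14
#' columns of [cohort_columns()] (matched case-insensitively after trimming
#' whitespace) and validates it with [as_cohort()].
#'
#' @param path Path to the CSV file.
#' @return A validated `cohort_table`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  as_cohort(raw)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` returns `x`
#' unchanged for any valid cohort.
#'
#' @param x A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort_table"))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " patients, ",
      length(predictor_columns()), " predictors; disease prevalence ",
      sprintf("%.3f", mean(x[["Heart Disease"]])), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
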