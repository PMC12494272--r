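# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-written valid cohort (3 patients, string outcome).
toy_cohort_df <- function() {
  data.frame(
    check.names = FALSE,
    Age = c(54, 61, 47), Sex = c(1, 0, 1),
    `Chest pain type` = c(4, 2, 3), BP = c(130, 120, 140),
    Cholesterol = c(250, 204, 320), `FBS over 120` = c(0, 0, 1),
    `EKG results` = c(2, 0, 2), `Max HR` = c(150, 172, 120),
    `Exercise angina` = c(0, 0, 1), `ST depression` = c(2.3, 0, 1.4),
    `Slope of ST` = c(2, 1, 2),
    `Number of vessels fluro` = c(0, 3, 2), Thallium = c(3, 7, 6),
    `Heart Disease` = c("Presence", "Absence", "Presence")
  )
}

# Independent IG oracle: mutual information from the joint contingency
# table, I(X;Y) = sum p(x,y) log2[ p(x,y) / (p(x) p(y)) ].
mutual_information_oracle <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0) {
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
    }
  }
  unname(s)
}

# Nonparametric standardisation oracle over a single binary confounder:
# pi_a = sum_c phat(c) * mean(Y | T = a, C = c). All four (t,c) cells must
# be populated.
np_standardize <- function(tr, y, c1, a) {
  pc <- table(factor(c1, 0:1)) / length(c1)
  s <- 0
  for (cv in 0:1) {
    sel <- tr == a & c1 == cv
    s <- s + pc[as.character(cv)] * mean(y[sel])
  }
  unname(s)
}

# Random single-confounder frame with every (t, c) stratum populated and
# every stratum event rate strictly inside (0, 1), so the saturated
# logistic fit is finite.
random_stratified_frame <- function() {
  repeat {
    counts <- sample(4:12, 4, replace = TRUE)      # cells (t,c)
    events <- vapply(counts, function(m) sample(seq_len(m - 1), 1), 1L)
    tr <- c(); y <- c(); c1 <- c()
    k <- 1
    for (t in 0:1) for (cv in 0:1) {
      m <- counts[k]
      tr <- c(tr, rep(t, m)); c1 <- c(c1, rep(cv, m))
      y <- c(y, rep(1, events[k]), rep(0, m - events[k]))
      k <- k + 1
    }
    # keep stratum rates away from 0/1 extremes the coefficient guard flags
    ok <- tryCatch({
      fr <- new_treatment_frame(tr, y, matrix(c1, ncol = 1,
                                              dimnames = list(NULL, "C1")))
      fit_q_model(fr, interactions = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      return(new_treatment_frame(tr, y, matrix(c1, ncol = 1,
                                               dimnames = list(NULL, "C1"))))
    }
  }
}

# Predictor matrix of iid noise plus outcome, for selector null tests.
noise_data <- function(n, p, seed) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("noise", seq_len(p))
  x[["Heart Disease"]] <- rbinom(n, 1, 0.5)
  x
}
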