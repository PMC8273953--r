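#' Fit the normative regression for one test
#'
#' Ordinary least squares of the observed raw result (for LTT, the
#' error-adjusted composite) on age and education over healthy volunteers.
#' The residual SD is the unbiased regression estimate with denominator
#' n - 3 (intercept plus two slopes). Subjects missing this test's result are
#' dropped from this fit only (per-test complete case).
#'
#' @param data Subject/battery data frame (see [read_subjects()]); if a
#'   `group` column is present only `"volunteer"` rows are used.
#' @param test One of `"NCT_A"`, `"NCT_B"`, `"SDT"`, `"LTT"`, `"DST"`.
#' @param min_n Minimum usable sample size (default 10).
#' @return A [test_norm()] object with the fitted coefficients.
#' @export
fit_test_model <- function(data, test, min_n = 10) {
  test <- match.arg(test, phes_tests)
  if ("group" %in% names(data)) {
    data <- data[data$group == "volunteer", , drop = FALSE]
  }
  y <- observed_result(data, test)
  keep <- !is.na(y) & !is.na(data$age) & !is.na(data$education)
  y <- y[keep]
  age <- data$age[keep]
  education <- data$education[keep]
  n <- length(y)
  if (n < min_n) {
    stop("need at least ", min_n, " volunteers with a ", test,
         " result to fit a norm; got ", n, call. = FALSE)
  }
  for (pred in c("age", "education")) {
    if (sd(get(pred)) == 0) {
      stop("cannot fit ", test, " norm: predictor '", pred,
           "' is constant (rank-deficient design)", call. = FALSE)
    }
  }
  fit <- lm(y ~ age + education)
  if (fit$rank < 3) {
    stop("cannot fit ", test,
         " norm: age and education are collinear (rank-deficient design)",
         call. = FALSE)
  }
  cf <- coef(fit)
  resid_sd <- sqrt(sum(residuals(fit)^2) / (n - 3))
  if (resid_sd == 0) {
    # Exact linear data: keep a valid (tiny) SD so the norm object remains
    # usable; scoring against such a norm is degenerate by construction.
    resid_sd <- .Machine$double.eps
  }
  test_norm(test, cf[["(Intercept)"]], cf[["age"]], cf[["education"]],
            resid_sd)
}

#' Fit a complete normative model on a volunteer sample
#'
#' Fits all five test norms with [fit_test_model()], then scores the fitting
#' sample against the fresh norms to obtain the reference PHES mean and SD,
#' from which the cut-off is derived at mean - 2 SD ([derive_cutoff()]) —
#' the standardisation procedure applied to the reference cohort.
#'
#' @inheritParams fit_test_model
#' @param name Identifier recorded on the model.
#' @param provenance Free-text provenance note.
#' @return A [phes_norms()] object.
#' @export
fit_norms <- function(data, name = "fitted", provenance = "", min_n = 10) {
  norms <- lapply(phes_tests, function(test) fit_test_model(data, test, min_n))
  names(norms) <- phes_tests
  model <- structure(
    list(name = name, provenance = provenance,
         phes_mean = 0, phes_sd = 1, cutoff = 0L, norms = norms),
    class = "phes_norms"
  )
  vols <- if ("group" %in% names(data)) {
    data[data$group == "volunteer", , drop = FALSE]
  } else data
  scored <- score_phes(vols, model)
  model$phes_mean <- mean(scored$phes)
  model$phes_sd <- sd(scored$phes)
  model$cutoff <- derive_cutoff(model$phes_mean, model$phes_sd)
  validate_norms(model)
}

#' Correlations of test results and PHES with age and education
#'
#' For each raw test result (LTT as composite) and for the PHES total,
#' computes the correlation with age and with education, both as
#' product-moment (Pearson) and rank (Spearman) coefficients. Signs follow
#' the raw results, not the deficit Z, so e.g. timed tests correlate
#' positively with age and negatively with education in a normative sample
#' while DST shows the reverse.
#'
#' @param scored Output of [score_phes()] (must retain `age` and
#'   `education`).
#' @return A data frame with one row per measure (`NCT_A` ... `DST`, `PHES`)
#'   and columns `age_pearson`, `age_spearman`, `edu_pearson`,
#'   `edu_spearman`. Cells where either variable is constant are `NA`
#'   (undefined correlation), flagged with a warning rather than an error.
#' @export
phes_correlations <- function(scored) {
  needed <- c("age", "education", paste0(tolower(phes_tests), "_observed"),
              "phes")
  absent <- setdiff(needed, names(scored))
  if (length(absent)) {
    stop("scored input is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(scored) < 3) {
    stop("need at least 3 complete records to correlate; got ",
         nrow(scored), call. = FALSE)
  }
  measures <- c(setNames(paste0(tolower(phes_tests), "_observed"), phes_tests),
                PHES = "phes")
  safe_cor <- function(x, y, method) {
    if (sd(x) == 0 || sd(y) == 0) {
      warning("undefined correlation: zero-variance column", call. = FALSE)
      return(NA_real_)
    }
    cor(x, y, method = method)
  }
  rows <- lapply(names(measures), function(measure) {
    v <- scored[[measures[[measure]]]]
    data.frame(
      measure = measure,
      age_pearson = safe_cor(v, scored$age, "pearson"),
      age_spearman = safe_cor(v, scored$age, "spearman"),
      edu_pearson = safe_cor(v, scored$education, "pearson"),
      edu_spearman = safe_cor(v, scored$education, "spearman")
    )
  })
  do.call(rbind, rows)
}
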