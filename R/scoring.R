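#' Error-adjusted line tracing composite
#'
#' The line tracing test is recorded as a completion time (`LTTt`, seconds)
#' and an error score (`LTTe`). The scored quantity is the composite
#' `(1 + LTTe/100) * LTTt`, which penalises each error point by 1% of the
#' time. Strictly increasing in both arguments.
#'
#' @param ltt_time Completion time in seconds, > 0.
#' @param ltt_errors Error score, >= 0.
#' @return Composite score in seconds. Vectorised; `NA` inputs give `NA`.
#' @examples
#' ltt_composite(100, 0)   # 100
#' ltt_composite(100, 10)  # 110
#' @export
ltt_composite <- function(ltt_time, ltt_errors) {
  if (any(ltt_time <= 0, na.rm = TRUE)) {
    stop("ltt_time must be positive", call. = FALSE)
  }
  if (any(ltt_errors < 0, na.rm = TRUE)) {
    stop("ltt_errors must be non-negative", call. = FALSE)
  }
  (1 + ltt_errors / 100) * ltt_time
}

#' Norm-predicted expected result for a subject
#'
#' Evaluates the normative linear predictor
#' `intercept + age_coef * age + edu_coef * education`.
#'
#' @param norm A [test_norm()] entry.
#' @param age Age in years, > 0 (age 0 is admitted only as the degenerate
#'   intercept evaluation).
#' @param education Years of schooling, >= 0.
#' @return Expected raw result in the test's units. Vectorised.
#' @export
expected_value <- function(norm, age, education) {
  if (any(age < 0, na.rm = TRUE) || any(education < 0, na.rm = TRUE)) {
    stop("age and education must be non-negative", call. = FALSE)
  }
  norm$intercept + norm$age_coef * age + norm$edu_coef * education
}

#' Direction-adjusted deficit Z-score
#'
#' Standardised distance of the observed result from the norm-predicted
#' expectation, oriented so that a positive value always means
#' worse-than-expected performance: for timed (higher-is-worse) tests
#' `(observed - expected) / residual_sd`, for DST (higher-is-better)
#' `(expected - observed) / residual_sd`.
#'
#' @param observed,expected Raw results in the test's units.
#' @param residual_sd Residual SD of the normative fit, > 0.
#' @param direction `"higher_is_worse"` or `"higher_is_better"`.
#' @return Dimensionless deficit Z. Vectorised.
#' @export
deficit_z <- function(observed, expected, residual_sd,
                      direction = c("higher_is_worse", "higher_is_better")) {
  direction <- match.arg(direction)
  if (any(residual_sd <= 0, na.rm = TRUE) || anyNA(residual_sd)) {
    stop("residual_sd must be positive", call. = FALSE)
  }
  z <- (observed - expected) / residual_sd
  if (direction == "higher_is_better") -z else z
}

#' Band a deficit Z-score into PHES component points
#'
#' Deviations within one SD of the expectation score 0; each further SD of
#' deficit loses one point down to -3 beyond three SDs; performance better
#' than one SD above expectation earns +1. Band boundaries belong to the less
#' pathological band, and the +1 bonus requires a strictly
#' better-than-one-SD result:
#' `z < -1` gives +1; `-1 <= z <= 1` gives 0; `1 < z <= 2` gives -1;
#' `2 < z <= 3` gives -2; `z > 3` gives -3.
#'
#' @param z Deficit Z-score(s); must be finite.
#' @return Integer points in `{-3, -2, -1, 0, +1}`. Vectorised.
#' @examples
#' band_points(c(-1.5, 0, 1, 2.5, 4))  # 1 0 0 -2 -3
#' @export
band_points <- function(z) {
  if (any(!is.finite(z))) stop("deficit z must be finite", call. = FALSE)
  pts <- integer(length(z))
  pts[z < -1] <- 1L
  pts[z > 1 & z <= 2] <- -1L
  pts[z > 2 & z <= 3] <- -2L
  pts[z > 3] <- -3L
  pts
}

#' Derive the PHES cut-off from the reference distribution
#'
#' The limit between normal and pathological PHES is placed at the reference
#' mean minus two SDs, floored to the nearest integer since PHES is
#' integer-valued (the conservative convention: -0.08 - 2 x 1.28 = -2.64
#' becomes -3).
#'
#' @param phes_mean Mean PHES of the reference sample.
#' @param phes_sd SD of the reference PHES, > 0.
#' @return Integer cut-off.
#' @export
derive_cutoff <- function(phes_mean, phes_sd) {
  if (is.na(phes_sd) || phes_sd <= 0) {
    stop("phes_sd must be positive", call. = FALSE)
  }
  as.integer(floor(phes_mean - 2 * phes_sd))
}

#' Classify minimal hepatic encephalopathy from a PHES total
#'
#' The default rule flags MHE when PHES is strictly below the cut-off
#' ("less than -3 points"); an inclusive rule (`phes <= cutoff`) is exposed
#' for sensitivity analyses since cut-off phrasing varies across reports.
#'
#' @param phes Integer PHES total(s).
#' @param cutoff Integer cut-off.
#' @param rule `"strict_less"` (default) or `"less_equal"`.
#' @return Logical MHE flag. Vectorised over `phes`.
#' @export
classify_mhe <- function(phes, cutoff, rule = c("strict_less", "less_equal")) {
  rule <- match.arg(rule)
  if (rule == "strict_less") phes < cutoff else phes <= cutoff
}

#' Score subjects' raw batteries against a normative model
#'
#' For each subject the five raw results (LTT as its error-adjusted
#' composite) are compared with their norm-predicted expectations, converted
#' to deficit Z-scores, banded into component points and summed into the
#' integer PHES; MHE is classified against the model's cut-off.
#'
#' @param data Data frame with columns `age`, `education` and the raw battery
#'   (`nct_a_s`, `nct_b_s`, `sdt_s`, `ltt_time_s`, `ltt_errors`,
#'   `dst_points`); an `id` column and any further columns (`group`, sex,
#'   clinical covariates) are carried through.
#' @param model A [phes_norms()] object.
#' @param rule MHE classification rule, see [classify_mhe()].
#' @return A data frame with, per test, `<test>_observed`, `<test>_expected`,
#'   `<test>_z` and `<test>_points` columns (lower-case test prefixes), plus
#'   `phes`, `mhe` and `cutoff_used`.
#' @examples
#' norms <- cameroon_norms()
#' vols <- gen_volunteers(5, norms, seed = 1)
#' score_phes(vols, norms)[, c("id", "phes", "mhe")]
#' @export
score_phes <- function(data, model, rule = c("strict_less", "less_equal")) {
  rule <- match.arg(rule)
  model <- validate_norms(model)
  battery_cols <- c("nct_a_s", "nct_b_s", "sdt_s", "ltt_time_s",
                    "ltt_errors", "dst_points")
  needed <- c("age", "education", battery_cols)
  absent <- setdiff(needed, names(data))
  if (length(absent)) {
    stop("scoring input is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (col in battery_cols) {
    if (anyNA(data[[col]])) {
      rows <- which(is.na(data[[col]]))
      ids <- if ("id" %in% names(data)) data$id[rows] else rows
      stop("cannot score: missing ", col, " for subject(s) ",
           paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
    }
  }
  carried <- intersect(c("id", "group", "sex", "age", "education",
                         clinical_covariates), names(data))
  out <- data[, carried, drop = FALSE]
  total <- integer(nrow(data))
  for (test in phes_tests) {
    nm <- model$norms[[test]]
    obs <- observed_result(data, test)
    exp <- expected_value(nm, data$age, data$education)
    z <- deficit_z(obs, exp, nm$residual_sd, nm$direction)
    pts <- band_points(z)
    prefix <- tolower(test)
    out[[paste0(prefix, "_observed")]] <- obs
    out[[paste0(prefix, "_expected")]] <- exp
    out[[paste0(prefix, "_z")]] <- z
    out[[paste0(prefix, "_points")]] <- pts
    total <- total + pts
  }
  out$phes <- total
  out$mhe <- classify_mhe(total, model$cutoff, rule)
  out$cutoff_used <- model$cutoff
  out
}

#' Score a single subject's battery
#'
#' Convenience wrapper around [score_phes()] for one subject given as plain
#' arguments.
#'
#' @param age,education Demographics in years.
#' @param nct_a_s,nct_b_s,sdt_s,ltt_time_s,ltt_errors,dst_points Raw battery.
#' @param model A [phes_norms()] object.
#' @param rule See [classify_mhe()].
#' @param id Optional subject identifier.
#' @return One-row data frame as from [score_phes()].
#' @export
score_battery <- function(age, education, nct_a_s, nct_b_s, sdt_s,
                          ltt_time_s, ltt_errors, dst_points,
                          model = cameroon_norms(),
                          rule = c("strict_less", "less_equal"),
                          id = "subject") {
  score_phes(data.frame(
    id = id, age = age, education = education,
    nct_a_s = nct_a_s, nct_b_s = nct_b_s, sdt_s = sdt_s,
    ltt_time_s = ltt_time_s, ltt_errors = ltt_errors,
    dst_points = dst_points
  ), model, rule)
}
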