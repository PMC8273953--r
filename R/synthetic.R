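# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

#' Demography of the reference volunteer population
#'
#' Age-band weights and per-band education distributions describing the
#' healthy-volunteer sample: 102 volunteers spread 29/31/19/17/6 over the
#' bands 20-30, 30-40, 40-50, 50-60 and 60-72 years, with band education
#' means (SD, range) of 12 (4, 7-21), 13 (5, 4-22), 11 (3, 5-16),
#' 10 (4, 4-15) and 6 (2, 4-6) years, and 54/102 males. Ages are drawn
#' uniformly within their band; education is a Gaussian truncated to the
#' band's observed range.
#'
#' @param age_bands Data frame with columns `low`, `high`, `weight`,
#'   `edu_mean`, `edu_sd`, `edu_min`, `edu_max`. Weights are normalised to
#'   sum to 1; bands must not overlap; `edu_min` must be >= 0.
#' @param sex_ratio Proportion of males.
#' @return A list of class `demography_config`.
#' @export
demography_config <- function(age_bands = NULL, sex_ratio = 54 / 102) {
  if (is.null(age_bands)) {
    age_bands <- data.frame(
      low = c(20, 30, 40, 50, 60),
      high = c(30, 40, 50, 60, 72),
      weight = c(29, 31, 19, 17, 6) / 102,
      edu_mean = c(12, 13, 11, 10, 6),
      edu_sd = c(4, 5, 3, 4, 2),
      edu_min = c(7, 4, 5, 4, 4),
      edu_max = c(21, 22, 16, 15, 6)
    )
  }
  needed <- c("low", "high", "weight", "edu_mean", "edu_sd", "edu_min",
              "edu_max")
  if (!all(needed %in% names(age_bands))) {
    stop("age_bands must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  o <- order(age_bands$low)
  age_bands <- age_bands[o, , drop = FALSE]
  if (any(age_bands$high <= age_bands$low)) {
    stop("each age band needs high > low", call. = FALSE)
  }
  if (nrow(age_bands) > 1 &&
      any(age_bands$low[-1] < age_bands$high[-nrow(age_bands)])) {
    stop("age bands must not overlap", call. = FALSE)
  }
  if (any(age_bands$edu_min < 0)) stop("edu_min must be >= 0", call. = FALSE)
  if (any(age_bands$weight < 0) || sum(age_bands$weight) <= 0) {
    stop("band weights must be non-negative with positive sum", call. = FALSE)
  }
  age_bands$weight <- age_bands$weight / sum(age_bands$weight)
  if (is.na(sex_ratio) || sex_ratio < 0 || sex_ratio > 1) {
    stop("sex_ratio must be in [0, 1]", call. = FALSE)
  }
  structure(list(age_bands = age_bands, sex_ratio = sex_ratio),
            class = "demography_config")
}

#' Configuration of the simulated cirrhotic arm
#'
#' Cirrhotic subjects share the volunteer demography shifted by the
#' age/education offsets observed between the groups (defaults +11.2 years
#' and -2.0 years of schooling), and each test result is degraded by a
#' subject-level performance deficit expressed in residual-SD units. The
#' deficit is heterogeneous across patients: subject i's shift is drawn from
#' a Gaussian with mean `deficit_shift` and SD `shift_sd`, truncated at 0,
#' and applied to all five tests in the pathological direction. Clinical
#' covariates are drawn independently at the configured prevalences with
#' configurable missingness.
#'
#' @param deficit_shift Mean deficit in residual-SD units, >= 0 (default 2).
#' @param shift_sd Between-subject SD of the deficit (default 1; 0 gives the
#'   homogeneous-shift model).
#' @param age_offset,education_offset Years added to the volunteer-demography
#'   draws (education clamped at 0).
#' @param covariate_prevalences Named list of probabilities:
#'   `child_pugh_bc`, `ascites`, `jaundice`, `gi_bleed` (defaults are the
#'   cirrhotic-cohort marginals 17/43, 0.34, 0.18, 0.16).
#' @param missingness Named list of per-covariate missingness probabilities
#'   (default: Child-Pugh missing in 7/50, others complete).
#' @return A list of class `cirrhosis_config`.
#' @export
cirrhosis_config <- function(deficit_shift = 2, shift_sd = 1,
                             age_offset = 11.2, education_offset = -2,
                             covariate_prevalences = list(
                               child_pugh_bc = 17 / 43, ascites = 0.34,
                               jaundice = 0.18, gi_bleed = 0.16),
                             missingness = list(child_pugh = 7 / 50,
                                                ascites = 0, jaundice = 0,
                                                gi_bleed = 0)) {
  if (is.na(deficit_shift) || deficit_shift < 0) {
    stop("deficit_shift must be >= 0", call. = FALSE)
  }
  if (is.na(shift_sd) || shift_sd < 0) stop("shift_sd must be >= 0",
                                            call. = FALSE)
  probs <- unlist(covariate_prevalences)
  if (any(probs < 0 | probs > 1)) {
    stop("covariate prevalences must be probabilities", call. = FALSE)
  }
  miss <- unlist(missingness)
  if (any(miss < 0 | miss > 1)) {
    stop("missingness values must be probabilities", call. = FALSE)
  }
  structure(list(deficit_shift = deficit_shift, shift_sd = shift_sd,
                 age_offset = age_offset, education_offset = education_offset,
                 covariate_prevalences = covariate_prevalences,
                 missingness = missingness),
            class = "cirrhosis_config")
}

# Truncated-Gaussian draw by rejection with a clamping fallback.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmin(pmax(x, lower), upper)
}

draw_demography <- function(n, demo) {
  bands <- demo$age_bands
  idx <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$weight)
  age <- runif(n, bands$low[idx], bands$high[idx])
  education <- rnorm_trunc(n, bands$edu_mean[idx], bands$edu_sd[idx],
                           bands$edu_min[idx], bands$edu_max[idx])
  sex <- ifelse(runif(n) < demo$sex_ratio, "male", "female")
  data.frame(age = age, education = education, sex = sex)
}

# Draw the raw battery for subjects at a given per-subject deficit (in
# residual-SD units, 0 for volunteers). Deficits act in the pathological
# direction of each test. Times are floored at 10 s and DST is rounded to a
# non-negative integer; the LTT composite is drawn from its linear model and
# split into (time, errors) with Poisson errors.
draw_battery <- function(demog, model, deficit, time_floor = 10,
                         ltt_error_lambda = 5) {
  n <- nrow(demog)
  res <- list()
  for (test in phes_tests) {
    nm <- model$norms[[test]]
    sign <- if (nm$direction == "higher_is_worse") 1 else -1
    value <- expected_value(nm, demog$age, demog$education) +
      rnorm(n, 0, nm$residual_sd) + sign * deficit * nm$residual_sd
    res[[test]] <- value
  }
  out <- demog
  out$nct_a_s <- pmax(res$NCT_A, time_floor)
  out$nct_b_s <- pmax(res$NCT_B, time_floor)
  out$sdt_s <- pmax(res$SDT, time_floor)
  composite <- pmax(res$LTT, time_floor)
  errors <- rpois(n, ltt_error_lambda)
  out$ltt_time_s <- composite / (1 + errors / 100)
  out$ltt_errors <- errors
  out$dst_points <- pmax(round(res$DST), 0)
  out
}

#' Generate a synthetic healthy-volunteer cohort
#'
#' Draws demographics from [demography_config()] (band-weighted uniform ages,
#' truncated-Gaussian education) and raw test results from the normative
#' measurement model: each result is its norm-predicted expectation plus
#' Gaussian noise at the test's residual SD, with times floored at
#' `time_floor` seconds, DST rounded to a non-negative integer, and the LTT
#' composite split into a Poisson error count and a back-solved time. The
#' same `(n, config, seed)` triple always yields an identical cohort.
#'
#' @param n Number of volunteers, >= 1.
#' @param model A [phes_norms()] measurement model (default the built-in
#'   Cameroonian constants).
#' @param demo A [demography_config()].
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param time_floor Lower truncation for timed results, seconds.
#' @param ltt_error_lambda Poisson mean of the LTT error count.
#' @return Data frame in the subject/battery CSV schema (clinical covariates
#'   `NA`).
#' @export
gen_volunteers <- function(n, model = cameroon_norms(),
                           demo = demography_config(), seed = NULL,
                           time_floor = 10, ltt_error_lambda = 5) {
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  model <- validate_norms(model)
  stopifnot(inherits(demo, "demography_config"))
  with_seed(seed, {
    demog <- draw_demography(n, demo)
    out <- draw_battery(demog, model, deficit = 0, time_floor = time_floor,
                        ltt_error_lambda = ltt_error_lambda)
    out$id <- sprintf("V%04d", seq_len(n))
    out$group <- "volunteer"
    for (cov in clinical_covariates) out[[cov]] <- NA_character_
    out[, subject_columns]
  })
}

#' Generate a synthetic cirrhotic cohort
#'
#' As [gen_volunteers()], but demographics are shifted by the configured
#' age/education offsets, every test result is degraded by a subject-level
#' deficit drawn from `N(deficit_shift, shift_sd)` truncated at 0 (in
#' residual-SD units, applied in each test's pathological direction), and
#' clinical covariates (Child-Pugh class, ascites, jaundice, prior GI
#' haemorrhage) are drawn at the configured prevalences with configurable
#' missingness.
#'
#' @inheritParams gen_volunteers
#' @param cfg A [cirrhosis_config()].
#' @return Data frame in the subject/battery CSV schema.
#' @export
gen_cirrhotics <- function(n, model = cameroon_norms(),
                           cfg = cirrhosis_config(),
                           demo = demography_config(), seed = NULL,
                           time_floor = 10, ltt_error_lambda = 5) {
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  model <- validate_norms(model)
  stopifnot(inherits(cfg, "cirrhosis_config"),
            inherits(demo, "demography_config"))
  with_seed(seed, {
    demog <- draw_demography(n, demo)
    demog$age <- demog$age + cfg$age_offset
    demog$education <- pmax(demog$education + cfg$education_offset, 0)
    deficit <- pmax(rnorm(n, cfg$deficit_shift, cfg$shift_sd), 0)
    out <- draw_battery(demog, model, deficit = deficit,
                        time_floor = time_floor,
                        ltt_error_lambda = ltt_error_lambda)
    out$id <- sprintf("C%04d", seq_len(n))
    out$group <- "cirrhotic"
    prev <- cfg$covariate_prevalences
    miss <- cfg$missingness
    draw_cov <- function(p, miss_p, levels) {
      v <- ifelse(runif(n) < p, levels[1], levels[2])
      v[runif(n) < miss_p] <- NA_character_
      v
    }
    bc <- draw_cov(prev$child_pugh_bc, miss$child_pugh %||% 0, c("BC", "A"))
    # split B/C at the observed 12:5 ratio among B/C patients
    out$child_pugh <- ifelse(is.na(bc), NA_character_,
                             ifelse(bc == "A", "A",
                                    ifelse(runif(n) < 12 / 17, "B", "C")))
    out$ascites <- draw_cov(prev$ascites, miss$ascites %||% 0, c("yes", "no"))
    out$jaundice <- draw_cov(prev$jaundice, miss$jaundice %||% 0,
                             c("yes", "no"))
    out$gi_bleed <- draw_cov(prev$gi_bleed, miss$gi_bleed %||% 0,
                             c("yes", "no"))
    out[, subject_columns]
  })
}
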