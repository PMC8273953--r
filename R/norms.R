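#' Construct a single-test normative entry
#'
#' A test norm is the linear prediction of the expected raw result from age
#' and education (all in raw-score units; age and education in years),
#' together with the residual standard deviation used to standardise observed
#' deviations, and the scoring direction of the test.
#'
#' @param test One of `"NCT_A"`, `"NCT_B"`, `"SDT"`, `"LTT"`, `"DST"`.
#' @param intercept,age_coef,edu_coef Regression coefficients in raw-score
#'   units (per year for the slopes).
#' @param residual_sd Residual standard deviation of the fit; must be > 0.
#' @param direction `"higher_is_worse"` (timed tests) or `"higher_is_better"`
#'   (DST). Defaults to the direction implied by the test identity.
#' @return An object of class `test_norm`.
#' @export
test_norm <- function(test, intercept, age_coef, edu_coef, residual_sd,
                      direction = test_direction(test)) {
  test <- match.arg(test, phes_tests)
  direction <- match.arg(direction, c("higher_is_worse", "higher_is_better"))
  if (!is.numeric(residual_sd) || length(residual_sd) != 1 ||
      is.na(residual_sd) || residual_sd <= 0) {
    stop("residual_sd for ", test, " must be a single positive number",
         call. = FALSE)
  }
  if (direction != test_direction(test)) {
    stop("direction for ", test, " must be '", test_direction(test), "'",
         call. = FALSE)
  }
  structure(
    list(test = test, intercept = as.numeric(intercept),
         age_coef = as.numeric(age_coef), edu_coef = as.numeric(edu_coef),
         residual_sd = as.numeric(residual_sd), direction = direction),
    class = "test_norm"
  )
}

#' Assemble a complete normative model
#'
#' @param name Short identifier for the reference population.
#' @param norms A list of five [test_norm()] objects, one per battery test.
#' @param phes_mean,phes_sd Mean and SD of the PHES distribution in the
#'   reference sample (used by [derive_cutoff()]).
#' @param cutoff Integer PHES cut-off (<= 0); PHES below it flags MHE under
#'   the default strict rule.
#' @param provenance Free-text note on where the constants come from.
#' @return An object of class `phes_norms`.
#' @seealso [cameroon_norms()], [fit_norms()], [read_norms()]
#' @export
phes_norms <- function(name, norms, phes_mean, phes_sd, cutoff,
                       provenance = "") {
  model <- structure(
    list(name = as.character(name), provenance = as.character(provenance),
         phes_mean = as.numeric(phes_mean), phes_sd = as.numeric(phes_sd),
         cutoff = as.integer(cutoff), norms = norms),
    class = "phes_norms"
  )
  validate_norms(model)
}

validate_norms <- function(model) {
  if (!is.list(model$norms)) stop("norms must be a list", call. = FALSE)
  missing <- setdiff(phes_tests, names(model$norms))
  if (length(missing)) {
    stop("normative model is missing test(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(model$norms), phes_tests)
  if (length(unknown)) {
    stop("unknown test name(s) in normative model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (test in phes_tests) {
    nm <- model$norms[[test]]
    if (!inherits(nm, "test_norm")) {
      model$norms[[test]] <- do.call(test_norm, c(list(test = test),
        nm[c("intercept", "age_coef", "edu_coef", "residual_sd", "direction")]))
    } else if (!identical(nm$test, test)) {
      stop("norm stored under ", test, " describes ", nm$test, call. = FALSE)
    }
  }
  model$norms <- model$norms[phes_tests]
  if (is.na(model$phes_sd) || model$phes_sd <= 0) {
    stop("phes_sd must be positive", call. = FALSE)
  }
  if (is.na(model$cutoff) || model$cutoff > 0) {
    stop("cutoff must be an integer <= 0", call. = FALSE)
  }
  model
}

#' @export
print.phes_norms <- function(x, ...) {
  cat("PHES normative model:", x$name, "\n")
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  cat(sprintf("  reference PHES %.2f +/- %.2f, cut-off %d\n",
              x$phes_mean, x$phes_sd, x$cutoff))
  for (nm in x$norms) {
    cat(sprintf("  %-5s  %8.2f %+.3f x age %+.3f x education   (SD %.2f, %s)\n",
                nm$test, nm$intercept, nm$age_coef, nm$edu_coef,
                nm$residual_sd, nm$direction))
  }
  invisible(x)
}

#' Published Cameroonian normative constants
#'
#' Returns the normative model standardised on 102 healthy Cameroonian
#' volunteers: per-test linear predictors on age and education with their
#' residual SDs, the reference PHES distribution (-0.08 +/- 1.28) and the
#' derived cut-off of -3 points.
#'
#' @return A [phes_norms()] object named `"cameroon-2021"`.
#' @examples
#' norms <- cameroon_norms()
#' expected_value(norms$norms$NCT_A, age = 40, education = 12)
#' @export
cameroon_norms <- function() {
  phes_norms(
    name = "cameroon-2021",
    provenance = "Normative constants standardised on 102 healthy Cameroonian volunteers",
    norms = list(
      NCT_A = test_norm("NCT_A", 125.62, 0.30, -4.47, 11.69),
      NCT_B = test_norm("NCT_B", 159.82, 1.39, -7.96, 24.65),
      SDT   = test_norm("SDT",    78.89, 0.35, -1.60,  9.39),
      LTT   = test_norm("LTT",   150.02, 0.11, -3.82, 15.10),
      DST   = test_norm("DST",    23.40, -0.20, 1.63,  3.24)
    ),
    phes_mean = -0.08, phes_sd = 1.28, cutoff = -3L
  )
}

#' Save or load a normative model as JSON
#'
#' The on-disk format is a JSON object with fields `name`, `provenance`,
#' `phes_mean`, `phes_sd`, `cutoff` and `norms`, the latter keyed by the test
#' names `NCT_A`, `NCT_B`, `SDT`, `LTT`, `DST`, each holding `intercept`,
#' `age_coef`, `edu_coef`, `residual_sd` and `direction`. `read_norms()`
#' validates the file and fails naming the offending field; the round trip
#' `read_norms(write_norms(m, f))` reproduces `m` field for field.
#'
#' @param model A [phes_norms()] object.
#' @param path File path of the JSON model file.
#' @return `write_norms()` returns `path` invisibly; `read_norms()` returns a
#'   validated [phes_norms()] object.
#' @export
write_norms <- function(model, path) {
  model <- validate_norms(model)
  payload <- list(
    name = model$name, provenance = model$provenance,
    phes_mean = model$phes_mean, phes_sd = model$phes_sd,
    cutoff = model$cutoff,
    norms = lapply(model$norms, function(nm) {
      nm[c("intercept", "age_coef", "edu_coef", "residual_sd", "direction")]
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("name", "phes_mean", "phes_sd", "cutoff", "norms")) {
    if (is.null(payload[[field]])) {
      stop("norms file is missing field '", field, "'", call. = FALSE)
    }
  }
  norms <- lapply(names(payload$norms), function(test) {
    entry <- payload$norms[[test]]
    if (!(test %in% phes_tests)) {
      stop("unknown test name in norms file: ", test, call. = FALSE)
    }
    for (field in c("intercept", "age_coef", "edu_coef", "residual_sd")) {
      if (is.null(entry[[field]]) || !is.numeric(entry[[field]])) {
        stop("norms file: ", test, " is missing numeric '", field, "'",
             call. = FALSE)
      }
    }
    test_norm(test, entry$intercept, entry$age_coef, entry$edu_coef,
              entry$residual_sd,
              direction = entry$direction %||% test_direction(test))
  })
  names(norms) <- names(payload$norms)
  phes_norms(payload$name, norms, payload$phes_mean, payload$phes_sd,
             payload$cutoff, provenance = payload$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
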