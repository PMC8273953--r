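#' MHE prevalence with raw counts
#'
#' @param flags Logical vector of MHE flags (no `NA`).
#' @return A list of class `phes_prevalence` with `numerator`, `denominator`,
#'   `proportion` and `percent`.
#' @examples
#' prevalence(rep(c(TRUE, FALSE), c(37, 13)))  # 74% (37/50)
#' @export
prevalence <- function(flags) {
  if (length(flags) == 0) stop("empty flag list", call. = FALSE)
  if (anyNA(flags)) stop("flags must not contain NA", call. = FALSE)
  k <- sum(flags)
  n <- length(flags)
  structure(list(numerator = k, denominator = n, proportion = k / n,
                 percent = 100 * k / n),
            class = "phes_prevalence")
}

#' @export
print.phes_prevalence <- function(x, ...) {
  cat(sprintf("prevalence %s%% (%d/%d)\n", render_pct(x$proportion),
              x$numerator, x$denominator))
  invisible(x)
}

#' Construct a 2x2 exposure-by-outcome table
#'
#' Counts are laid out as cases/non-cases among exposed and unexposed
#' subjects, the layout used for odds-ratio analysis of MHE against a binary
#' clinical exposure.
#'
#' @param exposed_case,exposed_noncase,unexposed_case,unexposed_noncase
#'   Non-negative counts; total must be positive.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(exposed_case, exposed_noncase,
                       unexposed_case, unexposed_noncase) {
  counts <- c(a = exposed_case, b = exposed_noncase,
              c = unexposed_case, d = unexposed_noncase)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  structure(as.list(counts), class = "two_by_two")
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a * d) / (b * c)` at full precision. With a zero
#' cell the OR is undefined and `NA` is returned with a warning, unless the
#' Haldane-Anscombe 0.5 continuity correction is explicitly switched on.
#' Use [render_or()] for the two-decimal truncated reporting convention.
#'
#' @param t A [two_by_two()] table.
#' @param haldane Add 0.5 to every cell when any cell is zero (off by
#'   default).
#' @return Numeric odds ratio.
#' @examples
#' odds_ratio(two_by_two(15, 16, 2, 10))  # 4.6875
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- unlist(t[c("a", "b", "c", "d")])
  if (any(cells == 0)) {
    if (!haldane) {
      warning("odds ratio undefined: zero cell in 2x2 table", call. = FALSE)
      return(NA_real_)
    }
    cells <- cells + 0.5
  }
  (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-normal interval `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Always contains the point OR and widens as any cell count decreases.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`; `NA`s for a zero cell
#'   unless `haldane = TRUE`.
#' @export
woolf_ci <- function(t, level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- unlist(t[c("a", "b", "c", "d")])
  if (any(cells == 0)) {
    if (!haldane) {
      warning("Woolf interval undefined: zero cell in 2x2 table",
              call. = FALSE)
      return(c(lower = NA_real_, upper = NA_real_))
    }
    cells <- cells + 0.5
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Reporting helpers: truncated odds ratios, half-up percentages
#'
#' Odds ratios are reported truncated (not rounded) to two decimals;
#' percentages are reported to one decimal with half-up rounding. Internal
#' values always keep full precision — these helpers only format.
#'
#' @param or Odds ratio(s).
#' @param digits Decimals kept.
#' @return Character vector.
#' @examples
#' render_or(4.6875)  # "4.68"
#' render_pct(15 / 31)  # "48.4"
#' @export
render_or <- function(or, digits = 2) {
  scale <- 10^digits
  formatC(trunc(or * scale) / scale, format = "f", digits = digits)
}

#' @rdname render_or
#' @param p Proportion(s) in `[0, 1]`.
#' @export
render_pct <- function(p, digits = 1) {
  scale <- 10^digits
  # half-up: floor(x + 0.5) rather than banker's rounding
  formatC(floor(p * 100 * scale + 0.5) / scale, format = "f", digits = digits)
}

# Variables recognised by the cohort comparison layer.
cohort_variables <- function() {
  c("age", "education", "sex", "phes", clinical_covariates)
}

#' Per-group complete-case counts for a variable
#'
#' Counts subjects with the variable recorded, separately in the MHE and
#' no-MHE groups. These denominators feed the reported percentages and the
#' group comparisons when clinical covariates are partially missing.
#'
#' @param cohort Scored cohort data frame with a logical `mhe` column.
#' @param variable One of the registered cohort variables (demographics,
#'   `phes`, or a clinical covariate).
#' @return Named integer vector `c(n_mhe, n_nomhe)`.
#' @export
complete_case_counts <- function(cohort, variable) {
  if (!(variable %in% cohort_variables())) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (!all(c(variable, "mhe") %in% names(cohort))) {
    stop("cohort is missing column(s): ",
         paste(setdiff(c(variable, "mhe"), names(cohort)), collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(cohort[[variable]])
  c(n_mhe = sum(ok & cohort$mhe), n_nomhe = sum(ok & !cohort$mhe))
}

#' Compare a variable between the MHE and no-MHE groups
#'
#' Quantitative variables: Shapiro-Wilk normality in each group and Levene's
#' variance-homogeneity test gate the choice between the two-sample t-test
#' (means) and the Mann-Whitney U-test (medians). Categorical variables:
#' chi-squared test, falling back to Fisher's exact test when any expected
#' cell is below 5. All p values two-sided; complete-case per variable.
#'
#' @inheritParams complete_case_counts
#' @param alpha Gate level for the normality/variance checks (default 0.05).
#' @return A list of class `phes_comparison`: `variable`, `n_mhe`,
#'   `n_nomhe`, `statistic_kind` (`mean_t`, `median_mannwhitney`,
#'   `proportion_fisher_chi2`, or `not_computable`), `estimate` (per-group
#'   means/medians or the contingency table) and `p_value`.
#' @export
compare_groups <- function(cohort, variable, alpha = 0.05) {
  n <- complete_case_counts(cohort, variable)
  keep <- !is.na(cohort[[variable]])
  x <- cohort[[variable]][keep]
  g <- factor(ifelse(cohort$mhe[keep], "MHE", "noMHE"),
              levels = c("MHE", "noMHE"))
  out <- list(variable = variable, n_mhe = unname(n["n_mhe"]),
              n_nomhe = unname(n["n_nomhe"]), statistic_kind = "not_computable",
              estimate = NULL, p_value = NA_real_)
  class(out) <- "phes_comparison"
  if (is.numeric(x)) {
    if (min(n) < 2 || any(tapply(x, g, sd) == 0, na.rm = TRUE)) {
      warning("comparison of '", variable, "' not computable: degenerate group",
              call. = FALSE)
      return(out)
    }
    # Shapiro-Wilk needs at least 3 observations per group; below that the
    # normality gate cannot run and the rank test is used directly.
    normal <- min(n) >= 3 &&
      all(tapply(x, g, function(v) shapiro.test(v)$p.value) >= alpha)
    homosked <- car::leveneTest(x ~ g)[1, "Pr(>F)"] >= alpha
    if (normal && homosked) {
      ht <- t.test(x ~ g, var.equal = TRUE)
      out$statistic_kind <- "mean_t"
      out$estimate <- tapply(x, g, mean)
    } else {
      ht <- suppressWarnings(wilcox.test(x ~ g))
      out$statistic_kind <- "median_mannwhitney"
      out$estimate <- tapply(x, g, median)
    }
    out$p_value <- ht$p.value
  } else {
    tab <- table(g, factor(x))
    if (min(n) < 1 || ncol(tab) < 2) {
      warning("comparison of '", variable, "' not computable: degenerate group",
              call. = FALSE)
      return(out)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ht <- if (any(expected < 5)) {
      fisher.test(tab)
    } else {
      chisq.test(tab, correct = FALSE)
    }
    out$statistic_kind <- "proportion_fisher_chi2"
    out$estimate <- tab
    out$p_value <- ht$p.value
  }
  out
}

#' @export
print.phes_comparison <- function(x, ...) {
  cat(sprintf("%s (n = %d MHE / %d no-MHE): %s, p = %s\n", x$variable,
              x$n_mhe, x$n_nomhe, x$statistic_kind,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Cohort epidemiology report
#'
#' Summarises a scored cirrhotic cohort: overall MHE prevalence, per-variable
#' complete-case group summaries, odds ratios with Woolf 95% intervals for
#' the binary clinical exposures (Child-Pugh B/C vs A, jaundice, ascites,
#' prior GI haemorrhage, male sex), and group-comparison p values.
#'
#' @param cohort Output of [score_phes()] on cirrhotic subjects, retaining
#'   `sex` and the clinical covariates.
#' @param variables Variables to report (default: all registered ones
#'   present in `cohort`).
#' @return A list of class `phes_cohort_report` with elements `prevalence`
#'   (a [prevalence()] object) and `table` (one row per variable: group
#'   summaries, `or`, `or_lower`, `or_upper`, `p_value`).
#' @export
cohort_report <- function(cohort, variables = NULL) {
  stopifnot("mhe" %in% names(cohort))
  if (is.null(variables)) {
    variables <- intersect(cohort_variables(), names(cohort))
  }
  prev <- prevalence(cohort$mhe)
  rows <- lapply(variables, function(v) {
    cmp <- suppressWarnings(compare_groups(cohort, v))
    exposure <- binary_exposure(cohort, v)
    or <- lower <- upper <- NA_real_
    summ_mhe <- summ_nomhe <- NA_character_
    if (!is.null(exposure)) {
      tab <- exposure_table(exposure, cohort$mhe)
      or <- suppressWarnings(odds_ratio(tab))
      ci <- suppressWarnings(woolf_ci(tab))
      lower <- unname(ci["lower"])
      upper <- unname(ci["upper"])
      summ_mhe <- sprintf("%d (%s%%)", tab$a, render_pct(tab$a / (tab$a + tab$c)))
      summ_nomhe <- sprintf("%d (%s%%)", tab$b, render_pct(tab$b / (tab$b + tab$d)))
    } else if (is.numeric(cohort[[v]]) && !is.null(cmp$estimate)) {
      fmt <- function(m, s) sprintf("%.1f +/- %.1f", m, s)
      keep <- !is.na(cohort[[v]])
      x <- cohort[[v]][keep]
      g <- cohort$mhe[keep]
      summ_mhe <- fmt(mean(x[g]), sd(x[g]))
      summ_nomhe <- fmt(mean(x[!g]), sd(x[!g]))
    }
    data.frame(variable = v, n_mhe = cmp$n_mhe, n_nomhe = cmp$n_nomhe,
               mhe_summary = summ_mhe, nomhe_summary = summ_nomhe,
               or = or, or_lower = lower, or_upper = upper,
               statistic = cmp$statistic_kind, p_value = cmp$p_value)
  })
  structure(list(prevalence = prev, table = do.call(rbind, rows)),
            class = "phes_cohort_report")
}

# Binary exposure vector (TRUE = exposed) for OR analysis, or NULL when the
# variable is not a binary exposure. Child-Pugh is dichotomised B/C vs A.
binary_exposure <- function(cohort, variable) {
  v <- cohort[[variable]]
  switch(variable,
    child_pugh = ifelse(is.na(v), NA, v %in% c("B", "C")),
    ascites = , jaundice = , gi_bleed = ifelse(is.na(v), NA, v == "yes"),
    sex = ifelse(is.na(v) | v == "unknown", NA, v == "male"),
    NULL
  )
}

exposure_table <- function(exposed, mhe) {
  ok <- !is.na(exposed)
  two_by_two(
    exposed_case = sum(exposed & mhe & ok, na.rm = TRUE),
    exposed_noncase = sum(exposed & !mhe & ok, na.rm = TRUE),
    unexposed_case = sum(!exposed & mhe & ok, na.rm = TRUE),
    unexposed_noncase = sum(!exposed & !mhe & ok, na.rm = TRUE)
  )
}

#' @export
print.phes_cohort_report <- function(x, ...) {
  print(x$prevalence)
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    or_txt <- if (is.na(r$or)) "-" else {
      sprintf("OR %s [%.1f-%.1f]", render_or(r$or), r$or_lower, r$or_upper)
    }
    cat(sprintf("  %-12s MHE %s | no-MHE %s | %s | p = %s\n", r$variable,
                r$mhe_summary, r$nomhe_summary, or_txt,
                format.pval(r$p_value, digits = 2)))
  }
  invisible(x)
}
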