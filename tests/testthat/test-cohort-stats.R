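test_that("prevalence returns the proportion with its raw counts", {
  p <- prevalence(rep(c(TRUE, FALSE), c(37, 13)))
  expect_equal(p$percent, 74)
  expect_equal(p$numerator, 37)
  expect_equal(p$denominator, 50)
  expect_equal(prevalence(rep(FALSE, 10))$percent, 0)
  expect_equal(prevalence(rep(TRUE, 7))$percent, 100)
  # numerator plus complement equals the denominator
  flags <- runif(40) < 0.3
  p2 <- prevalence(flags)
  expect_equal(p2$numerator + sum(!flags), p2$denominator)
  expect_error(prevalence(logical(0)), "empty")
})

test_that("odds ratio is the cross-product ratio at full precision", {
  expect_equal(odds_ratio(two_by_two(15, 16, 2, 10)), 4.6875)
  expect_equal(render_or(odds_ratio(two_by_two(15, 16, 2, 10))), "4.68")
  expect_equal(odds_ratio(two_by_two(8, 29, 1, 12)), 96 / 29)
  expect_equal(render_or(96 / 29), "3.31")
  expect_equal(odds_ratio(two_by_two(1, 1, 1, 1)), 1)
})

test_that("odds ratio matches the (a/b)/(c/d) oracle over an exhaustive sweep", {
  cells <- expand.grid(a = 1:30, b = c(1:15, 30), c = c(1:15, 30),
                       d = 1:30)
  # vectorised oracle on a thinned but large sweep, exact small-table block
  oracle <- (cells$a / cells$b) / (cells$c / cells$d)
  ours <- (cells$a * cells$d) / (cells$b * cells$c)
  expect_true(all(abs(ours - oracle) <= 1e-12 * pmax(oracle, 1)))
  # spot-check the classed interface against the same oracle
  for (i in sample(nrow(cells), 200)) {
    t <- two_by_two(cells$a[i], cells$b[i], cells$c[i], cells$d[i])
    expect_equal(odds_ratio(t), oracle[i], tolerance = 1e-12)
  }
})

test_that("transposing the exposure inverts the odds ratio", {
  t <- two_by_two(15, 16, 2, 10)
  flipped <- two_by_two(2, 10, 15, 16)
  expect_equal(odds_ratio(flipped), 1 / odds_ratio(t))
})

test_that("zero cells yield an undefined OR unless Haldane correction is requested", {
  t0 <- two_by_two(5, 0, 3, 7)
  expect_warning(or <- odds_ratio(t0), "zero cell")
  expect_true(is.na(or))
  expect_equal(odds_ratio(t0, haldane = TRUE),
               (5.5 * 7.5) / (0.5 * 3.5))
  expect_warning(ci <- woolf_ci(t0), "zero cell")
  expect_true(all(is.na(ci)))
  expect_true(all(is.finite(woolf_ci(t0, haldane = TRUE))))
})

test_that("Woolf interval matches hand evaluation and brackets the OR", {
  # male-sex table of the cirrhotic cohort; hand-evaluated log-OR interval
  t <- two_by_two(20, 17, 9, 4)
  ci <- woolf_ci(t)
  expect_equal(unname(ci), c(0.13647, 2.00417), tolerance = 1e-4)
  or <- odds_ratio(t)
  expect_lt(ci["lower"], or)
  expect_gt(ci["upper"], or)
  # scaling all cells up narrows the interval
  big <- two_by_two(20000, 17000, 9000, 4000)
  ci_big <- woolf_ci(big)
  expect_lt(diff(ci_big), diff(ci))
  # swapping case/noncase labels maps to the reciprocal interval
  swapped <- two_by_two(17, 20, 4, 9)
  ci_sw <- woolf_ci(swapped)
  expect_equal(unname(ci_sw), unname(rev(1 / ci)), tolerance = 1e-12)
})

test_that("complete-case denominators drive the reported percentages", {
  cohort <- published_cirrhotic_cohort()
  n <- complete_case_counts(cohort, "child_pugh")
  expect_equal(unname(n), c(31, 12))
  bc_mhe <- sum(cohort$mhe & cohort$child_pugh %in% c("B", "C"), na.rm = TRUE)
  expect_equal(bc_mhe, 15)
  expect_equal(render_pct(bc_mhe / n[["n_mhe"]]), "48.4")
  expect_equal(unname(complete_case_counts(cohort, "sex")), c(37, 13))
  expect_error(complete_case_counts(cohort, "meld"), "unknown variable")
  empty <- cohort
  empty$ascites <- NA_character_
  expect_equal(unname(complete_case_counts(empty, "ascites")), c(0, 0))
  expect_warning(cmp <- compare_groups(empty, "ascites"), "not computable")
  expect_identical(cmp$statistic_kind, "not_computable")
})

test_that("group comparisons select the test per the gating rules", {
  # identical balanced binary variable: p = 1
  cohort <- data.frame(mhe = rep(c(TRUE, FALSE), each = 10),
                       ascites = rep(c("yes", "no"), 10))
  cmp <- compare_groups(cohort, "ascites")
  expect_identical(cmp$statistic_kind, "proportion_fisher_chi2")
  expect_equal(cmp$p_value, 1)

  # small expected cells route to Fisher's exact test
  cohort2 <- published_cirrhotic_cohort()
  cmp2 <- compare_groups(cohort2, "jaundice")
  keep <- !is.na(cohort2$jaundice)
  oracle <- fisher.test(table(cohort2$mhe[keep], cohort2$jaundice[keep]))
  expect_equal(cmp2$p_value, oracle$p.value)

  # heavily skewed quantitative variable routes to Mann-Whitney
  set.seed(31)
  skewed <- data.frame(mhe = rep(c(TRUE, FALSE), each = 40),
                       age = exp(rnorm(80, 3, 1)))
  cmp3 <- compare_groups(skewed, "age")
  expect_identical(cmp3$statistic_kind, "median_mannwhitney")

  # a single observation in one group is not computable
  tiny <- data.frame(mhe = c(TRUE, rep(FALSE, 9)), age = rnorm(10, 50, 5))
  expect_warning(cmp4 <- compare_groups(tiny, "age"), "not computable")
  expect_true(is.na(cmp4$p_value))
})

test_that("a built-in age gap is detected in nearly every replicate", {
  # MHE group older by 15 years (SD 10, n = 40/group): the comparison must
  # flag the difference at alpha = 0.001 in at least 95 of 100 seeds
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    cohort <- data.frame(
      mhe = rep(c(TRUE, FALSE), each = 40),
      age = c(rnorm(40, 50, 10), rnorm(40, 35, 10))
    )
    cmp <- compare_groups(cohort, "age")
    if (!is.na(cmp$p_value) && cmp$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("the cohort report assembles prevalence, ORs and p values", {
  cohort <- published_cirrhotic_cohort()
  cohort$age <- c(rnorm(37, 54.3, 13.9), rnorm(13, 35.2, 10.9))
  rep <- cohort_report(cohort, variables = c("age", "sex", "child_pugh",
                                             "jaundice", "ascites",
                                             "gi_bleed"))
  expect_equal(rep$prevalence$percent, 74)
  tab <- rep$table
  expect_equal(render_or(tab$or[tab$variable == "child_pugh"]), "4.68")
  expect_equal(render_or(tab$or[tab$variable == "sex"]), "0.52")
  expect_equal(render_or(tab$or[tab$variable == "jaundice"]), "3.31")
  expect_equal(render_or(tab$or[tab$variable == "ascites"]), "2.02")
  expect_equal(render_or(tab$or[tab$variable == "gi_bleed"]), "1.06")
  expect_true(all(is.na(tab$or) | (tab$or_lower <= tab$or &
                                   tab$or <= tab$or_upper)))
  expect_true(is.na(tab$or[tab$variable == "age"]))
  expect_output(print(rep), "prevalence 74.0% \\(37/50\\)")
})

test_that("reporting helpers truncate ORs and half-up round percentages", {
  expect_equal(render_or(c(2.029, 4.6875, 1.0645)), c("2.02", "4.68", "1.06"))
  expect_equal(render_pct(c(0.15, 0.125, 15 / 31)), c("15.0", "12.5", "48.4"))
  expect_equal(render_pct(0.3785), "37.9")  # half-up at the third decimal
})
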