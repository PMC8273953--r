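test_that("identical (n, config, seed) triples give identical cohorts", {
  m <- cameroon_norms()
  a <- gen_volunteers(5, m, seed = 42)
  b <- gen_volunteers(5, m, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, gen_volunteers(5, m, seed = 43)))
  ca <- gen_cirrhotics(5, m, seed = 42)
  cb <- gen_cirrhotics(5, m, seed = 42)
  expect_identical(ca, cb)
  # the caller's RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_volunteers(3, m, seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generator rejects invalid sizes and configs", {
  expect_error(gen_volunteers(0), ">= 1")
  expect_error(gen_cirrhotics(0), ">= 1")
  expect_error(cirrhosis_config(deficit_shift = -1), ">= 0")
  expect_error(cirrhosis_config(covariate_prevalences = list(
    child_pugh_bc = 1.4, ascites = 0.3, jaundice = 0.1, gi_bleed = 0.1)),
    "probabilities")
  bands <- demography_config()$age_bands
  bands$high[1] <- 45   # overlaps the second band
  expect_error(demography_config(bands), "overlap")
  bands2 <- demography_config()$age_bands
  bands2$edu_min[2] <- -1
  expect_error(demography_config(bands2), "edu_min")
  expect_error(demography_config(sex_ratio = 1.2), "sex_ratio")
})

test_that("generated results are centred on the normative expectations", {
  m <- cameroon_norms()
  vols <- gen_volunteers(10000, m, seed = 8)
  for (test in c("NCT_A", "NCT_B", "SDT", "LTT", "DST")) {
    nm <- m$norms[[test]]
    obs <- switch(test,
                  NCT_A = vols$nct_a_s, NCT_B = vols$nct_b_s,
                  SDT = vols$sdt_s, DST = vols$dst_points,
                  LTT = ltt_composite(vols$ltt_time_s, vols$ltt_errors))
    expected <- expected_value(nm, vols$age, vols$education)
    expect_lt(abs(mean(obs - expected)), 0.05 * nm$residual_sd)
  }
})

test_that("demography respects band supports and the schema", {
  vols <- gen_volunteers(2000, seed = 15)
  expect_true(all(vols$age >= 20 & vols$age <= 72))
  expect_true(all(vols$education >= 4 & vols$education <= 22))
  # education range within each band
  bands <- demography_config()$age_bands
  for (i in seq_len(nrow(bands))) {
    in_band <- vols$age >= bands$low[i] & vols$age < bands$high[i]
    expect_true(all(vols$education[in_band] >= bands$edu_min[i]))
    expect_true(all(vols$education[in_band] <= bands$edu_max[i]))
  }
  expect_true(all(vols$group == "volunteer"))
  expect_true(all(vols$dst_points >= 0 & vols$dst_points == round(vols$dst_points)))
  expect_true(all(vols$ltt_errors >= 0))
  expect_named(vols, c("id", "group", "sex", "age", "education", "nct_a_s",
                       "nct_b_s", "sdt_s", "ltt_time_s", "ltt_errors",
                       "dst_points", "child_pugh", "ascites", "jaundice",
                       "gi_bleed"))
})

test_that("a zero deficit shift reproduces the volunteer distribution", {
  m <- cameroon_norms()
  cfg <- cirrhosis_config(deficit_shift = 0, shift_sd = 0, age_offset = 0,
                          education_offset = 0)
  vols <- gen_volunteers(5000, m, seed = 101)
  cirr <- gen_cirrhotics(5000, m, cfg = cfg, seed = 202)
  for (col in c("nct_a_s", "nct_b_s", "sdt_s")) {
    ks <- suppressWarnings(ks.test(vols[[col]], cirr[[col]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("MHE prevalence is non-decreasing in the deficit shift and saturates", {
  m <- cameroon_norms()
  prev <- vapply(0:4, function(shift) {
    cirr <- gen_cirrhotics(500, m, cfg = cirrhosis_config(deficit_shift = shift),
                           seed = 77)
    mean(score_phes(cirr, m)$mhe)
  }, numeric(1))
  expect_true(all(diff(prev) >= 0))
  expect_gt(prev[5], 0.95)  # a uniform 4-SD deficit scores -3 per test
  expect_lt(prev[1], 0.2)
})

test_that("cirrhotic covariates follow the configured prevalences and missingness", {
  cirr <- gen_cirrhotics(4000, seed = 55)
  expect_true(all(is.na(cirr$child_pugh) |
                  cirr$child_pugh %in% c("A", "B", "C")))
  expect_equal(mean(is.na(cirr$child_pugh)), 7 / 50, tolerance = 0.25)
  expect_equal(mean(cirr$ascites == "yes"), 0.34, tolerance = 0.1)
  expect_equal(mean(cirr$jaundice == "yes"), 0.18, tolerance = 0.15)
  recorded <- cirr$child_pugh[!is.na(cirr$child_pugh)]
  expect_equal(mean(recorded %in% c("B", "C")), 17 / 43, tolerance = 0.15)
  # offsets shift the demography
  vols <- gen_volunteers(4000, seed = 55)
  expect_gt(mean(cirr$age) - mean(vols$age), 8)
  expect_lt(mean(cirr$education) - mean(vols$education), -1)
})

test_that("norms fitted on a generated cohort recover the generating model", {
  m <- cameroon_norms()
  vols <- gen_volunteers(5000, m, seed = 303)
  fitted <- fit_norms(vols, name = "recovered")
  for (test in c("NCT_A", "NCT_B", "SDT", "LTT", "DST")) {
    expect_equal(fitted$norms[[test]]$intercept, m$norms[[test]]$intercept,
                 tolerance = 0.05)
    expect_equal(fitted$norms[[test]]$residual_sd, m$norms[[test]]$residual_sd,
                 tolerance = 0.05)
  }
  # self-normalised reference distribution near (0, 1ish) and cutoff near -3
  expect_lt(abs(fitted$phes_mean), 0.3)
  expect_true(fitted$cutoff %in% c(-4L, -3L, -2L))
})
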