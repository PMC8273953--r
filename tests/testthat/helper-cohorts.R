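# Shared fixtures, built in code.

# Battery whose five results sit exactly `z_worse` residual-SDs in the
# pathological direction from the norm-predicted expectation.
battery_at_z <- function(age, education, model = cameroon_norms(),
                         z_worse = 0, id = "S1") {
  nm <- model$norms
  exp_for <- function(t) expected_value(nm[[t]], age, education)
  data.frame(
    id = id, group = "cirrhotic", sex = "male",
    age = age, education = education,
    nct_a_s = exp_for("NCT_A") + z_worse * nm$NCT_A$residual_sd,
    nct_b_s = exp_for("NCT_B") + z_worse * nm$NCT_B$residual_sd,
    sdt_s = exp_for("SDT") + z_worse * nm$SDT$residual_sd,
    # zero errors: composite equals the recorded time
    ltt_time_s = exp_for("LTT") + z_worse * nm$LTT$residual_sd,
    ltt_errors = 0,
    dst_points = exp_for("DST") - z_worse * nm$DST$residual_sd,
    child_pugh = NA_character_, ascites = NA_character_,
    jaundice = NA_character_, gi_bleed = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Exact (noise-free) volunteer sample from a single linear model.
exact_linear_sample <- function(n, intercept, age_coef, edu_coef, seed = 1) {
  set.seed(seed)
  age <- runif(n, 20, 70)
  education <- runif(n, 2, 20)
  y <- intercept + age_coef * age + edu_coef * education
  data.frame(group = "volunteer", age = age, education = education, y = y)
}

# Wrap a single test's results into the full battery schema so that
# fit_test_model() can be exercised for that test alone; other tests get
# plausible constants (never fitted in these checks).
as_battery <- function(df, test) {
  out <- data.frame(
    id = sprintf("V%03d", seq_len(nrow(df))), group = df$group,
    sex = "female", age = df$age, education = df$education,
    nct_a_s = 80, nct_b_s = 120, sdt_s = 70, ltt_time_s = 100,
    ltt_errors = 0, dst_points = 30,
    child_pugh = NA_character_, ascites = NA_character_,
    jaundice = NA_character_, gi_bleed = NA_character_,
    stringsAsFactors = FALSE
  )
  col <- switch(test, NCT_A = "nct_a_s", NCT_B = "nct_b_s", SDT = "sdt_s",
                LTT = "ltt_time_s", DST = "dst_points")
  out[[col]] <- df$y
  out
}

# MHE/no-MHE cohort matching the published cirrhotic-cohort margins:
# 37 MHE / 13 no-MHE; Child-Pugh recorded in 31 / 12 (15 and 2 of them B/C);
# jaundice 8 / 1; ascites 14 / 3; prior GI bleed 6 / 2; male 20 / 9.
published_cirrhotic_cohort <- function() {
  fill <- function(n, k_yes, n_recorded = n) {
    c(rep("yes", k_yes), rep("no", n_recorded - k_yes),
      rep(NA_character_, n - n_recorded))
  }
  data.frame(
    id = sprintf("C%02d", 1:50),
    mhe = rep(c(TRUE, FALSE), c(37, 13)),
    sex = c(rep(c("male", "female"), c(20, 17)),
            rep(c("male", "female"), c(9, 4))),
    child_pugh = c(rep(c("B", "A", NA), c(15, 16, 6)),
                   rep(c("B", "A", NA), c(2, 10, 1))),
    jaundice = c(fill(37, 8), fill(13, 1)),
    ascites = c(fill(37, 14), fill(13, 3)),
    gi_bleed = c(fill(37, 6), fill(13, 2)),
    stringsAsFactors = FALSE
  )
}

# Brute-force banding oracle: explicit interval membership, independent of
# the production step function.
band_points_oracle <- function(z) {
  vapply(z, function(v) {
    if (v < -1) 1L
    else if (v >= -1 && v <= 1) 0L
    else if (v > 1 && v <= 2) -1L
    else if (v > 2 && v <= 3) -2L
    else -3L
  }, integer(1))
}
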