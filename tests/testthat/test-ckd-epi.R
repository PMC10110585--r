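test_that("2009 equation reproduces the closed form for a mid-range male", {
  # 141 * (0.9/0.9)^a * 1 * 0.993^50, constants straight from the 2009 form
  expect_equal(ckd_epi_egfr(0.9, 50, "male", FALSE, variant = "2009"),
               141 * 0.993^50, tolerance = 1e-12)
  # female below the knot picks up the 1.018 multiplier and alpha = -0.329
  expect_equal(ckd_epi_egfr(0.5, 40, "female", FALSE, variant = "2009"),
               141 * (0.5 / 0.7)^-0.329 * 0.993^40 * 1.018,
               tolerance = 1e-12)
  # Black race multiplies by 1.159 in 2009 and is ignored in 2021
  expect_equal(ckd_epi_egfr(1.1, 60, "male", TRUE, variant = "2009") /
                 ckd_epi_egfr(1.1, 60, "male", FALSE, variant = "2009"),
               1.159)
  expect_equal(ckd_epi_egfr(1.1, 60, "male", TRUE, variant = "2021"),
               ckd_epi_egfr(1.1, 60, "male", FALSE, variant = "2021"))
})

test_that("at the sex-specific knot the creatinine terms drop out", {
  # scr = kappa and the youngest admissible age: both ratio terms are 1
  expect_equal(ckd_epi_egfr(0.9, 18, "male", FALSE, variant = "2009"),
               141 * 0.993^18, tolerance = 1e-12)
  expect_equal(ckd_epi_egfr(0.7, 18, "female", FALSE, variant = "2009"),
               141 * 0.993^18 * 1.018, tolerance = 1e-12)
})

test_that("eGFR is strictly decreasing in creatinine and age, both variants", {
  scr_grid <- c(0.3, 0.5, 0.69, 0.7, 0.71, 0.89, 0.9, 0.91, 1.2, 2, 4, 8)
  for (variant in c("2009", "2021")) {
    for (sex in c("male", "female")) {
      for (age in c(18, 40, 65, 90)) {
        e <- ckd_epi_egfr(scr_grid, age, sex, FALSE, variant = variant)
        expect_true(all(diff(e) < 0),
                    info = paste(variant, sex, age, "creatinine monotone"))
        expect_true(all(e > 0) && all(is.finite(e)))
      }
      ages <- c(18, 30, 50, 70, 90)
      e_age <- ckd_epi_egfr(1.0, ages, sex, FALSE, variant = variant)
      expect_true(all(diff(e_age) < 0),
                  info = paste(variant, sex, "age monotone"))
    }
  }
})

test_that("eGFR is continuous in creatinine across the knot", {
  eps <- 1e-9
  for (variant in c("2009", "2021")) {
    for (sex in c("male", "female")) {
      kappa <- if (sex == "female") 0.7 else 0.9
      left <- ckd_epi_egfr(kappa - eps, 50, sex, FALSE, variant = variant)
      right <- ckd_epi_egfr(kappa + eps, 50, sex, FALSE, variant = variant)
      expect_equal(left, right, tolerance = 1e-6)
    }
  }
})

test_that("invalid inputs and missing race are hard errors", {
  expect_error(ckd_epi_egfr(0, 50, "male"), "creatinine")
  expect_error(ckd_epi_egfr(-1, 50, "male"), "creatinine")
  expect_error(ckd_epi_egfr(1, 10, "male"), "18")
  expect_error(ckd_epi_egfr(1, 50, "other"), "sex")
  expect_error(ckd_epi_egfr(1, 50, "male", NA, variant = "2009"),
               "race_black")
  # 2021 variant must tolerate missing race
  expect_silent(ckd_epi_egfr(1, 50, "male", NA, variant = "2021"))
})
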