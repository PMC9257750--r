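test_that("ionization classification follows the threshold rules", {
  cases <- list(
    list(f = c(0.05, 0.9, 0.05, 0), want = "basic"),
    list(f = c(0, 0, 1, 0), want = "neutral"),
    # zwitterion precedence at the 0.5 boundary
    list(f = c(0.3, 0.1, 0.1, 0.5), want = "zwitterion"),
    list(f = c(0.6, 0.1, 0.3, 0), want = "acidic"),
    # nothing exceeds 0.5 -> neutral catch-all
    list(f = c(0.4, 0.4, 0.2, 0), want = "neutral"))
  for (cs in cases) {
    p <- ionization_profile(cs$f[1], cs$f[2], cs$f[3], cs$f[4])
    expect_identical(classify_ionization(p), cs$want)
  }
})

test_that("ionization profile validates fractions", {
  expect_error(ionization_profile(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(ionization_profile(-0.1, 0.6, 0.3, 0.2), "\\[0, 1\\]")
  expect_error(classify_ionization(ionization_profile()), "missing")
})

test_that("ionization_from_pka gives consistent HH fractions", {
  p <- ionization_from_pka(pka_base = 9)
  expect_equal(p$f_cation, 1 / (1 + 10^(7.4 - 9)))
  expect_equal(p$f_anion + p$f_cation + p$f_union + p$f_zwitter, 1)
  expect_identical(classify_ionization(p), "basic")
  z <- ionization_from_pka(pka_acid = 4, pka_base = 9.5)
  expect_identical(classify_ionization(z), "zwitterion")
  # weak base at pH 7.4 stays neutral
  expect_identical(classify_ionization(ionization_from_pka(pka_base = 7)),
                   "neutral")
})

test_that("ECCS decision table and boundary conventions", {
  # boundary inclusive on high-permeability and low-MW sides
  expect_identical(classify_eccs(5e-6, "acidic", 400), "1a")
  expect_identical(classify_eccs(1e-5, "acidic", 450), "1b")
  expect_identical(classify_eccs(1e-7, "acidic", 350), "3a")
  expect_identical(classify_eccs(1e-7, "zwitterion", 500), "3b")
  expect_identical(classify_eccs(1e-5, "basic", 450), "2")
  expect_identical(classify_eccs(1e-5, "neutral", 350), "2")
  expect_identical(classify_eccs(1e-7, "neutral", 350), "4")
  expect_identical(classify_eccs(1e-7, "basic", 500), "4")
})

test_that("high-permeability acids/zwitterions never map to renal classes", {
  set.seed(1)
  for (i in 1:50) {
    cl <- classify_eccs(runif(1, 5e-6, 1e-3),
                        sample(c("acidic", "zwitterion"), 1),
                        runif(1, 150, 900))
    expect_false(cl %in% c("3a", "3b", "4"))
  }
})

test_that("clearance bins follow the printed thresholds, clipping above 60", {
  expect_identical(classify_clearance(5), "very_low")
  expect_identical(classify_clearance(0), "very_low")
  expect_identical(classify_clearance(6), "low")
  expect_identical(classify_clearance(30), "moderate")
  expect_identical(classify_clearance(42), "high")
  expect_identical(classify_clearance(75), "high")
  expect_error(classify_clearance(-1), "nonnegative")
})

test_that("protein-binding category threshold is 2% with inclusive boundary", {
  expect_identical(classify_binding(0.01), "high")
  expect_identical(classify_binding(0.02), "moderate")
  expect_identical(classify_binding(0.5), "moderate")
  expect_error(classify_binding(0), "\\(0, 1\\]")
})

test_that("Papp -> human Peff correlation", {
  expect_equal(papp_to_peff_human(1e-5), 10^(0.607 * -5 + 2.014))
  # unit-intercept case: exponent exactly zero
  expect_equal(papp_to_peff_human(10^(-2.014 / 0.607)), 1)
  expect_error(papp_to_peff_human(0), "> 0")
  expect_error(papp_to_peff_human(-1e-6), "> 0")
  # strictly monotone power law, also through the rat scaling
  pp <- sort(10^runif(20, -7, -3))
  expect_true(all(diff(peff_human_to_rat(papp_to_peff_human(pp))) > 0))
})

test_that("human-to-rat Peff scaling is exactly 1.14x", {
  expect_equal(peff_human_to_rat(2), 2.28)
  expect_equal(peff_human_to_rat(0), 0)
  expect_equal(peff_human_to_rat(2.18), 2.4852)
})

test_that("study_arm validates route, dose range and formulation", {
  a <- study_arm("c1", "IV", 1, "solution", observed_cl = 20)
  expect_s3_class(a, "study_arm")
  expect_warning(study_arm("c1", "IV", 20, "solution"), "outside")
  expect_warning(study_arm("c1", "PO", 50, "solution"), "outside")
  expect_error(study_arm("c1", "IV", 1, "suspension"), "PO only")
  expect_error(study_arm("c1", "PO", 1, "solution", fe = 1.2), "fe")
})
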