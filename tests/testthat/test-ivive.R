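phys <- rat_physiology()

test_that("fu_inc under the four incubation-binding assumptions", {
  expect_equal(compute_fu_inc(scaling_method("direct"), fup = 0.1), 0.1)
  expect_equal(compute_fu_inc(scaling_method("dilution"), fup = 1), 1)
  expect_equal(compute_fu_inc(scaling_method("dilution"), fup = 0.1),
               1 / (1 + 0.1 * 9))
  # df = 1 reduces the dilution method to direct scaling
  expect_equal(compute_fu_inc(scaling_method("dilution", df = 1),
                              fup = 0.37), 0.37)
  expect_equal(compute_fu_inc(scaling_method("unbound"), fup = 0.01), 1)
  # Austin: logD for neutrals, reconstructed logP for bases
  expect_equal(compute_fu_inc(scaling_method("austin"), fup = 0.2,
                              logd74 = 2.5,
                              ionization_category = "neutral"),
               1 / (1 + 10^(0.4 * 2.5 - 1.38)))
  logp <- 1.5 + log10(1 + 10^(9 - 7.4))
  expect_equal(compute_fu_inc(scaling_method("austin"), fup = 0.2,
                              logd74 = 1.5, ionization_category = "basic",
                              pka_base = 9),
               1 / (1 + 10^(0.4 * logp - 1.38)))
  expect_warning(
    compute_fu_inc(scaling_method("austin"), fup = 0.2, logd74 = 1.5,
                   ionization_category = "basic"),
    "no basic pKa")
  expect_error(compute_fu_inc(scaling_method("direct"), fup = 0), "fup")
})

test_that("unbound clint and whole-body scaling arithmetic", {
  expect_equal(unbound_clint(5, 1), 5)
  expect_equal(unbound_clint(5, 0.5), 10)
  expect_equal(unbound_clint(0, 0.2), 0)
  expect_error(unbound_clint(5, 0), "fu_inc")
  expect_equal(scale_to_whole_body(1, phys), 4.8)
  expect_equal(scale_to_whole_body(0, phys), 0)
  # round trip with the inverse factor
  x <- c(0.3, 7, 120)
  expect_equal(scale_to_whole_body(x, phys) / 4.8, x)
})

test_that("well-stirred clearance: worked value, limits, monotonicity", {
  expect_equal(well_stirred_cl(600, fup = 0.1, bp = 1, phys), 30)
  expect_equal(well_stirred_cl(0, fup = 0.5, bp = 2, phys), 0)
  # flow-limited asymptote: blood clearance -> Qh
  expect_equal(well_stirred_cl(1e12, fup = 0.5, bp = 1.3, phys) / 1.3,
               phys$qh, tolerance = 1e-6)
  cls <- vapply(c(1, 10, 100, 1e3, 1e4), well_stirred_cl,
                numeric(1), fup = 0.3, bp = 0.8, phys = phys)
  expect_true(all(diff(cls) > 0))
  expect_true(all(cls <= phys$qh * 0.8))
})

test_that("back-calculation inverts the well-stirred model", {
  expect_equal(back_calculate_clint(30, fup = 0.1, bp = 1, phys = phys),
               125)
  expect_equal(back_calculate_clint(0, fup = 0.3, bp = 1.2, phys = phys),
               0)
  # property: forward(inverse(x)) == x over random valid draws
  set.seed(42)
  for (i in 1:300) {
    fup <- runif(1, 0.005, 1)
    bp <- runif(1, 0.6, 3)
    cl <- runif(1, 0, 0.98 * phys$qh * bp)
    if (cl / bp >= 0.99 * phys$qh) next
    clint <- back_calculate_clint(cl, fup = fup, bp = bp, phys = phys)
    expect_equal(well_stirred_cl(scale_to_whole_body(clint, phys),
                                 fup, bp, phys),
                 cl, tolerance = 1e-9)
  }
})

test_that("back-calculation signals blood-flow-exceeded exclusions", {
  expect_error(back_calculate_clint(65, fup = 0.2, bp = 1, phys = phys),
               class = "htpbpk_flow_exceeded")
  # margin applies just below Qh too
  expect_error(back_calculate_clint(59.8, fup = 0.2, bp = 1, phys = phys),
               class = "htpbpk_flow_exceeded")
  # fe reduces the hepatic share and can rescue an arm
  expect_silent(back_calculate_clint(59.8, fup = 0.2, bp = 1, fe = 0.5,
                                     phys = phys))
})

test_that("dilution fu_inc >= fup implies ordered clearance predictions", {
  set.seed(7)
  for (i in 1:50) {
    fup <- runif(1, 0.001, 1)
    bp <- runif(1, 0.6, 2.5)
    clint <- 10^runif(1, -1, 3)
    fu_dir <- compute_fu_inc(scaling_method("direct"), fup)
    fu_dil <- compute_fu_inc(scaling_method("dilution"), fup)
    expect_gte(fu_dil, fu_dir)
    cl_dir <- well_stirred_cl(
      scale_to_whole_body(unbound_clint(clint, fu_dir), phys), fup, bp,
      phys)
    cl_dil <- well_stirred_cl(
      scale_to_whole_body(unbound_clint(clint, fu_dil), phys), fup, bp,
      phys)
    expect_lte(cl_dil, cl_dir + 1e-12)
  }
})
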