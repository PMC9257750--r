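phys <- rat_physiology()

test_that("solubilization ratio from biorelevant media", {
  expect_equal(estimate_solubilization_ratio(1, s_fassif = 1), 0)
  expect_equal(estimate_solubilization_ratio(1, s_fassif = 4), 1)
  expect_equal(estimate_solubilization_ratio(1, s_fessif = 16), 1)
  # max over available media
  expect_equal(estimate_solubilization_ratio(1, s_fassif = 7,
                                             s_fessif = 16), 2)
  # de-solubilization is clipped at zero
  expect_equal(estimate_solubilization_ratio(2, s_fassif = 1), 0)
  expect_warning(sr <- estimate_solubilization_ratio(1), "no biorelevant")
  expect_equal(sr, 0)
})

test_that("local solubility: HH scaling and bile-salt enhancement", {
  gut <- rat_gut()
  duod <- gut[gut$compartment == "duodenum", ]      # pH 6.2, 10 mM
  # neutral compound: pH-independent, only bile-salt enhancement
  m <- solubility_model(5, sr = 0.2)
  expect_equal(local_solubility(m, duod), 5 * (1 + 0.2 * 10))
  # monoprotic acid, hand-computed HH values at three pHs
  m2 <- solubility_model(1, ref_ph = 6.5, pka_acid = 5)
  for (ph in c(3, 6.5, 7.4)) {
    comp <- data.frame(ph = ph, bile_salt = 0)
    expect_equal(local_solubility(m2, comp),
                 (1 + 10^(ph - 5)) / (1 + 10^(6.5 - 5)))
  }
  # amplification is capped
  m3 <- solubility_model(1, ref_ph = 6.5, pka_acid = 0.5,
                         max_amplification = 50)
  expect_equal(local_solubility(m3, data.frame(ph = 8.5, bile_salt = 0)),
               50)
})

test_that("dissolution rate: saturation clamp and radius scaling", {
  d <- diffusion_coefficient(400)
  expect_equal(dissolution_rate(10, 25e-4, cs = 0.01, c_diss = 0.01,
                                d_diff = d), 0)
  expect_equal(dissolution_rate(10, 25e-4, cs = 0.01, c_diss = 0.02,
                                d_diff = d), 0)
  r1 <- dissolution_rate(10, 25e-4, cs = 0.01, c_diss = 0, d_diff = d)
  expect_gt(r1, 0)
  # with h_eff = r (below the 30 um cap), rate scales as 1/r^2
  r2 <- dissolution_rate(10, 12.5e-4, cs = 0.01, c_diss = 0, d_diff = d)
  expect_equal(r2 / r1, 4, tolerance = 1e-10)
  # above the cap the thickness saturates and scaling becomes 1/r
  r3 <- dissolution_rate(10, 60e-4, cs = 0.01, c_diss = 0, d_diff = d)
  r4 <- dissolution_rate(10, 120e-4, cs = 0.01, c_diss = 0, d_diff = d)
  expect_equal(r3 / r4, 2, tolerance = 1e-10)
})

test_that("time to 90% dissolved scales with initial radius squared", {
  # single-beaker sink-condition integration using the package rate law as
  # the only model content; the oracle is the analytic r^2 scaling
  d <- diffusion_coefficient(400)
  t90 <- function(r0) {
    m <- 1; m0 <- 1; r <- r0; t <- 0; dt <- 0.01
    while (m > 0.1 * m0) {
      m <- m - dissolution_rate(m, r, cs = 0.05, c_diss = 0,
                                d_diff = d) * dt
      r <- r0 * (m / m0)^(1 / 3)
      t <- t + dt
    }
    t
  }
  expect_equal(t90(12.5e-4) / t90(25e-4), 0.25, tolerance = 0.02)
})

test_that("PO solution: gut mass balance and Foral consistency", {
  cmpd <- make_compound(s_aq = 200, papp = 2e-3, pka_base = 8.5)
  clint <- 200
  sim <- simulate_po(cmpd, 2, clint, formulation = "solution",
                     phys = phys)
  states <- setdiff(colnames(sim$amounts), "aabs")
  expect_lt(max(abs(rowSums(sim$amounts[, states]) - 2)), 2 * 1e-9)
  expect_equal(sim$fg, 1)
  clh_b <- well_stirred_cl(clint, cmpd$in_vitro$fup, cmpd$in_vitro$bp,
                           phys) / cmpd$in_vitro$bp
  expect_equal(sim$fh, 1 - clh_b / phys$qh)
  # Foral ~ Fabs * Fh for a solution with no gut loss
  expect_equal(sim$foral, sim$fabs * sim$fh, tolerance = 0.05)
  expect_lte(sim$foral, sim$fabs + 1e-9)
})

test_that("PO suspension: dissolution-limited but mass-conserving", {
  cmpd <- make_compound(s_aq = 0.5, papp = 2e-3, s_fassif = 1.5)
  sim <- simulate_po(cmpd, 5, 100, formulation = "suspension", phys = phys)
  states <- setdiff(colnames(sim$amounts), "aabs")
  expect_lt(max(abs(rowSums(sim$amounts[, states]) - 5)), 5 * 1e-9)
  expect_lt(sim$fabs, 1)
  # same compound as a solution absorbs more
  sol <- simulate_po(cmpd, 5, 100, formulation = "solution", phys = phys)
  expect_gt(sol$fabs, sim$fabs)
})

test_that("zero permeability means nothing is absorbed", {
  cmpd <- make_compound()
  sim <- simulate_po(cmpd, 1, 100, formulation = "solution", phys = phys,
                     peff_rat = 0)
  expect_equal(sim$fabs, 0, tolerance = 1e-12)
  expect_equal(max(sim$plasma), 0)
})

test_that("complete absorption with no first pass gives Foral near 1", {
  cmpd <- make_compound(s_aq = 500, papp = 5e-3)
  sim <- suppressWarnings(
    simulate_po(cmpd, 1, 0, formulation = "solution", phys = phys))
  expect_equal(sim$fabs, 1, tolerance = 0.02)
  expect_equal(sim$foral, 1, tolerance = 0.02)
  expect_true("foral_from_auclast" %in% sim$flags)
})

test_that("Fabs is nondecreasing in permeability and solubility", {
  fabs_p <- vapply(c(0.05, 0.2, 1, 5), function(pf)
    simulate_po(make_compound(s_aq = 2), 2, 100,
                formulation = "suspension", phys = phys,
                peff_rat = pf)$fabs, numeric(1))
  expect_true(all(diff(fabs_p) > -1e-9))
  fabs_s <- vapply(c(0.2, 2, 20, 200), function(s)
    simulate_po(make_compound(s_aq = s), 2, 100,
                formulation = "suspension", phys = phys)$fabs, numeric(1))
  expect_true(all(diff(fabs_s) > -1e-9))
})

test_that("reduced PO model tracks the full model's AUC", {
  cmpd <- make_compound(s_aq = 100, pka_base = 8.5)
  kps <- compute_kp_set(cmpd, phys)
  vss <- compute_vss(kps, cmpd$in_vitro$bp, phys)
  clint <- 200
  pk_f <- suppressWarnings(nca(simulate_po(cmpd, 2, clint, "solution",
                                           kps = kps, phys = phys)))
  pk_r <- suppressWarnings(nca(simulate_reduced(cmpd, 2, "PO", clint,
                                                vss = vss, phys = phys)))
  expect_equal(pk_f$aucinf, pk_r$aucinf, tolerance = 0.1)
})
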