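phys <- rat_physiology()

test_that("degenerate one-compartment config matches the closed form", {
  # one lumped eliminating tissue, Kp = 1, vanishing blood pools: the exact
  # solution (venous sampling, post-hepatic) is C = (D/V) exp(-fup*CLint*t/V)
  phys1 <- one_compartment_phys()
  cmpd <- make_compound(fup = 1, bp = 1, logd = 0)
  clint <- 120
  times <- default_time_grid(4, 150)
  sim <- simulate_iv(cmpd, 1, clint, kps = unit_kp(), phys = phys1,
                     times = times)
  V <- 1000 + 0.01
  cref <- 1 / V * exp(-clint / V * sim$time * 60) * 1e6
  keep <- sim$time > 0.005
  expect_lt(max(abs(sim$plasma[keep] - cref[keep]) / cref[keep]), 1e-4)
})

test_that("IV simulation conserves mass at machine precision", {
  cmpd <- make_compound(pka_base = 8.5)
  sim <- simulate_iv(cmpd, 2, 240, phys = phys)
  total <- rowSums(sim$amounts)
  expect_lt(max(abs(total - 2)), 2 * 1e-9)
  expect_true(all(sim$plasma >= 0))
  expect_true(all(sim$conc >= 0))
})

test_that("linear-system identity: AUCinf * CL = Dose", {
  for (seed in 1:3) {
    set.seed(seed)
    cmpd <- make_compound(id = paste0("L", seed),
                          logd = runif(1, 0, 3),
                          fup = runif(1, 0.05, 0.9),
                          bp = runif(1, 0.8, 1.5),
                          pka_base = if (seed == 2) 8.5 else numeric(0))
    clint <- 10^runif(1, 1, 3)
    sim <- simulate_iv(cmpd, 1, clint, phys = phys)
    pk <- nca(sim)
    cl_ws <- well_stirred_cl(clint, cmpd$in_vitro$fup, cmpd$in_vitro$bp,
                             phys)
    expect_equal(pk$aucinf * cl_ws * 60 / 1e6, 1, tolerance = 5e-3)
  }
})

test_that("zero intrinsic clearance gives a flagged, non-eliminating profile", {
  cmpd <- make_compound()
  sim <- simulate_iv(cmpd, 1, 0, phys = phys)
  expect_true("auc_divergent" %in% sim$flags)
  n <- length(sim$plasma)
  # plasma plateaus after distribution, no elimination
  expect_equal(sim$plasma[n], sim$plasma[n - 10], tolerance = 1e-6)
  expect_equal(max(sim$cumulative$metabolized), 0)
  expect_warning(pk <- nca(sim), "terminal")
  expect_true(is.na(pk$aucinf))
})

test_that("reduced IV model equals the one-compartment closed form", {
  cmpd <- make_compound()
  vss <- 2.5
  clint <- 300
  sim <- simulate_reduced(cmpd, 1.5, "IV", clint, vss = vss, phys = phys)
  cl <- well_stirred_cl(clint, cmpd$in_vitro$fup, cmpd$in_vitro$bp, phys)
  cref <- 1.5 / (vss * 1000) * exp(-cl / (vss * 1000) * sim$time * 60) * 1e6
  expect_equal(sim$plasma, cref, tolerance = 1e-12)
  # Cmax at t = 0 is Dose/Vss
  expect_equal(sim$plasma[1], 1.5 / (vss * 1000) * 1e6)
})

test_that("full and reduced IV models agree on AUCinf (same clearance)", {
  cmpd <- make_compound(pka_base = 8.5)
  kps <- compute_kp_set(cmpd, phys)
  vss <- compute_vss(kps, cmpd$in_vitro$bp, phys)
  clint <- 240
  pk_f <- nca(simulate_iv(cmpd, 1, clint, kps = kps, phys = phys))
  pk_r <- nca(simulate_reduced(cmpd, 1, "IV", clint, vss = vss,
                               phys = phys))
  expect_equal(pk_f$aucinf, pk_r$aucinf, tolerance = 0.01)
})

test_that("tidy export contains plasma and per-compartment series", {
  cmpd <- make_compound()
  sim <- simulate_iv(cmpd, 1, 100, phys = phys)
  df <- as.data.frame(sim)
  expect_true(all(c("time", "compartment", "concentration") %in% names(df)))
  expect_true(all(c("plasma", "liver", "adipose") %in% df$compartment))
  expect_true(all(df$concentration >= 0))
})
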