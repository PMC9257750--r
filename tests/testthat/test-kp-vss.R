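phys <- rat_physiology()

test_that("water-only limit: no lipid, no binding, neutral -> Kp is tissue water", {
  tis <- data.frame(tissue = "toy", v = 100, q = 10, f_ew = 0.2,
                    f_iw = 0.55, f_nl = 0, f_np = 0, ap = 1, ratp = 0)
  kp <- compute_kp(tis, fup = 1, bp = 1, logd74 = -12,
                   ionization_from_pka())
  expect_equal(kp, 0.2 + 0.55, tolerance = 1e-10)
})

test_that("Kp is strictly increasing in logD for a neutral compound", {
  tis <- phys$tissues[phys$tissues$tissue == "muscle", ]
  kps <- vapply(seq(-1, 4, by = 0.5), function(ld)
    compute_kp(tis, fup = 0.3, bp = 1, logd74 = ld,
               ionization_from_pka()), numeric(1))
  expect_true(all(diff(kps) > 0))
})

test_that("base-class Kp matches an independent step-by-step transcription", {
  # reference basic compound: pKa 9.0, logD 2.0, fup 0.25, BP 1.5, muscle
  tis <- phys$tissues[phys$tissues$tissue == "muscle", ]
  fup <- 0.25; bp <- 1.5; logd <- 2; pka <- 9; hct <- 0.46
  # --- independent transcription of the documented equations ---
  P <- 10^logd
  X <- 10^(pka - 7.4)            # ionized:neutral, plasma
  Yt <- 10^(pka - 7.0)           # ionized:neutral, tissue cell water
  Yb <- 10^(pka - 7.22)          # ionized:neutral, erythrocyte
  kpu_bc <- (hct - 1 + bp) / (hct * fup)
  lip_bc <- P * 0.0017 + (0.3 * P + 0.7) * 0.0029
  ka <- (kpu_bc - 0.603 * (1 + Yb) / (1 + X) - lip_bc) *
    (1 + X) / (0.5 * Yb)
  lip_t <- P * tis$f_nl + (0.3 * P + 0.7) * tis$f_np
  kpu <- tis$f_ew + tis$f_iw * (1 + Yt) / (1 + X) + lip_t +
    ka * tis$ap * Yt / (1 + X)
  expect_equal(
    compute_kp(tis, fup, bp, logd, ionization_from_pka(pka_base = pka),
               hct = hct),
    kpu * fup, tolerance = 1e-12)
})

test_that("acid-class Kp includes the extracellular protein term", {
  tis <- phys$tissues[phys$tissues$tissue == "kidney", ]
  fup <- 0.05; logd <- 1.2; pka <- 4.5
  P <- 10^logd
  X <- 10^(7.4 - pka); Y <- 10^(7.0 - pka)
  lip_t <- P * tis$f_nl + (0.3 * P + 0.7) * tis$f_np
  lip_p <- P * 0.0023 + (0.3 * P + 0.7) * 0.0013
  kpu <- tis$f_ew + tis$f_iw * (1 + Y) / (1 + X) + lip_t +
    (1 / fup - 1 - lip_p) * tis$ratp
  expect_equal(
    compute_kp(tis, fup, 0.6, logd, ionization_from_pka(pka_acid = pka)),
    kpu * fup, tolerance = 1e-12)
})

test_that("inconsistent BP raises diagnostic errors for bases", {
  tis <- phys$tissues[phys$tissues$tissue == "muscle", ]
  ion <- ionization_from_pka(pka_base = 9)
  expect_error(compute_kp(tis, fup = 0.3, bp = 0.5, logd74 = 2, ion),
               "negative blood-cell partition")
  # BP below what water+lipid alone explain -> negative association const
  expect_error(compute_kp(tis, fup = 0.9, bp = 0.58, logd74 = 3, ion),
               "association constant")
})

test_that("Vss formula: unit Kp, linearity and missing-tissue error", {
  kps <- stats::setNames(rep(1, nrow(phys$tissues)), phys$tissues$tissue)
  vss <- compute_vss(kps, bp = 1, phys)
  # all Kp = 1 and BP = 1: total tissue volume plus total blood volume
  expect_equal(vss, (sum(phys$tissues$v) + phys$v_ven + phys$v_art) / 1000)
  # doubling every Kp doubles exactly the tissue term
  v2 <- compute_vss(2 * kps, bp = 1, phys)
  blood <- (phys$v_ven + phys$v_art) / 1000
  expect_equal(v2 - blood, 2 * (vss - blood), tolerance = 1e-12)
  expect_error(compute_vss(kps[-3], bp = 1, phys), "missing")
  expect_error(compute_vss(kps, bp = 0.2, phys), "erythrocyte")
})

test_that("compute_kp_set covers all tissues and feeds compute_vss", {
  cmpd <- make_compound(pka_base = 8.5)
  kps <- compute_kp_set(cmpd, phys)
  expect_named(kps, phys$tissues$tissue)
  expect_true(all(kps > 0))
  vss <- compute_vss(kps, cmpd$in_vitro$bp, phys)
  expect_gt(vss, 0.1)
})
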