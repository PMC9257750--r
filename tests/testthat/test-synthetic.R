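test_that("library generation is deterministic and size-correct", {
  spec <- library_spec(n_compounds = 12, seed = 99)
  a <- generate_library(spec)
  b <- generate_library(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_length(a, 12)
  expect_length(generate_library(library_spec(n_compounds = 0)), 0)
  # different seed differs
  c <- generate_library(library_spec(n_compounds = 12, seed = 100))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("marginals hit the dataset-level targets", {
  lib <- generate_library(library_spec(n_compounds = 1000, seed = 5))
  df <- as.data.frame(lib)
  expect_lt(abs(mean(df$mw) - 413), 10)
  expect_lt(abs(mean(df$logd74) - 2.48), 0.15)
  # ~11.6% highly bound
  expect_gt(mean(df$fup < 0.02), 0.07)
  expect_lt(mean(df$fup < 0.02), 0.17)
  expect_true(all(df$fup > 0 & df$fup <= 1))
  expect_true(all(df$bp > 0.54))
  # mean human Peff near 2.18 (1e-4 cm/s)
  peff <- papp_to_peff_human(df$papp_llcpk1)
  expect_lt(abs(mean(peff) - 2.18), 0.5)
  ion <- vapply(lib, function(x) classify_ionization(x$ionization), "")
  tab <- table(factor(ion, c("acidic", "basic", "neutral", "zwitterion")))
  expect_lt(abs(tab[["basic"]] / 1000 - 0.33), 0.06)
  expect_lt(abs(tab[["neutral"]] / 1000 - 0.637), 0.06)
  # ECCS class 2 is the majority after classification
  eccs <- vapply(lib, function(x)
    classify_eccs(x$in_vitro$papp_llcpk1, classify_ionization(x$ionization),
                  x$in_vitro$mw), "")
  expect_gt(mean(eccs == "2"), 0.5)
  # every generated compound yields a valid partition set
  ok <- vapply(lib[1:200], function(x)
    tryCatch({ compute_kp_set(x); TRUE }, error = function(e) FALSE),
    logical(1))
  expect_true(all(ok))
})

test_that("observations are deterministic under a fixed seed", {
  lib <- random_library(4, seed = 3)
  spec <- library_spec(n_compounds = 4, seed = 3)
  a <- generate_observations(lib, spec, seed = 21, routes = "IV")
  b <- generate_observations(lib, spec, seed = 21, routes = "IV")
  expect_identical(a, b)
  expect_true(all(c("compound_id", "route", "dose", "formulation",
                    "observed_cl", "observed_aucinf") %in% names(a)))
  expect_true(all(a$dose >= 0.03 & a$dose <= 10))
})

test_that("noise-free world is self-consistent under the generating method", {
  lib <- random_library(10, seed = 8)
  spec <- library_spec(n_compounds = 10, seed = 8)
  arms <- generate_observations(lib, spec, noise_model(1, 1), seed = 13,
                                routes = "IV")
  phys <- rat_physiology()
  # direct scaling (the generating assumption) reproduces observed CL
  for (cmpd in lib) {
    a <- arms[arms$compound_id == cmpd$compound_id, ][1, ]
    if (!is.finite(a$observed_cl)) next
    clint <- scale_to_whole_body(
      unbound_clint(cmpd$in_vitro$clint_heps,
                    compute_fu_inc(scaling_method("direct"),
                                   cmpd$in_vitro$fup)), phys)
    pk <- suppressWarnings(nca(simulate_iv(cmpd, 1, clint, phys = phys)))
    expect_equal(pk$cl, a$observed_cl, tolerance = 1e-6)
  }
})

test_that("stronger clint perturbation degrades direct-scaling precision", {
  lib <- random_library(40, seed = 17)
  spec <- library_spec(n_compounds = 40, seed = 17)
  phys <- rat_physiology()
  aafe_at <- function(gsd) {
    arms <- generate_observations(lib, spec, noise_model(1, gsd),
                                  seed = 31, routes = "IV")
    arms <- arms[!duplicated(arms$compound_id), ]
    pred <- vapply(seq_len(nrow(arms)), function(i) {
      cmpd <- lib[[match(arms$compound_id[i],
                         vapply(lib, `[[`, "", "compound_id"))]]
      clint <- scale_to_whole_body(
        unbound_clint(cmpd$in_vitro$clint_heps,
                      cmpd$in_vitro$fup), phys)
      well_stirred_cl(clint, cmpd$in_vitro$fup, cmpd$in_vitro$bp, phys)
    }, numeric(1))
    suppressMessages(
      fold_error_panel(pred, arms$observed_cl)$aafe)
  }
  expect_gt(aafe_at(2.5), aafe_at(1.0))
})
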