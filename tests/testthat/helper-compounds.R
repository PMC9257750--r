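# shared fixture builders (all fixtures are generated in code)

make_compound <- function(id = "T-1", logd = 2, s_aq = 10, papp = 2e-5,
                          clint = 10, fup = 0.2, bp = 1.2, mw = 400,
                          pka_acid = numeric(0), pka_base = numeric(0),
                          s_fassif = NA_real_, s_fessif = NA_real_,
                          clint_external = NA_real_) {
  compound_record(
    id,
    in_vitro_inputs(logd74 = logd, s_aq = s_aq, papp_llcpk1 = papp,
                    clint_heps = clint, fup = fup, bp = bp, mw = mw,
                    s_fassif = s_fassif, s_fessif = s_fessif),
    ionization_from_pka(pka_acid = pka_acid, pka_base = pka_base),
    clint_external = clint_external)
}

random_library <- function(n, seed = 1L, ...) {
  generate_library(library_spec(n_compounds = n, seed = seed, ...))
}

# degenerate single-compartment physiology: one lumped eliminating tissue,
# near-zero blood pools, no lung (used by the closed-form ODE oracle)
one_compartment_phys <- function(v_tissue = 1000, q = 60) {
  tis <- data.frame(tissue = "liver", v = v_tissue, q = q, f_ew = 0.2,
                    f_iw = 0.5, f_nl = 0.01, f_np = 0.01, ap = 1,
                    ratp = 0.1)
  rat_physiology(tissues = tis, v_ven = 0.005, v_art = 0.005)
}

# independent transcription of Lin's concordance formula (population
# moments), used as the oracle for the panel's CCC fields
lin_ccc_ref <- function(x, y) {
  n <- length(x)
  sxy <- mean(x * y) - mean(x) * mean(y)
  2 * sxy / (mean(x^2) - mean(x)^2 + mean(y^2) - mean(y)^2 +
               (mean(x) - mean(y))^2)
}

unit_kp <- function(tissues = "liver") {
  structure(stats::setNames(rep(1, length(tissues)), tissues),
            class = "kp_set")
}
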