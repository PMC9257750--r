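#' Specification of a synthetic compound library
#'
#' Describes the marginal property distributions and study-arm structure of
#' an early-discovery rat PK dataset. Defaults emulate the published
#' dataset-level summaries this package is designed around: mean molecular
#' weight 413 Da, mean LogD7.4 2.48, geometric-scale aqueous solubility
#' location 0.20 ug/mL, human Peff mean 2.18e-4 cm/s (via the permeability
#' correlation), ionization mix of roughly 33% basic / 64% neutral with a
#' small acid/zwitterion remainder, ~11.6% of compounds with fup < 2%,
#' biorelevant solubilities available for about half the library, IV doses
#' 0.03-10 mg/kg and PO doses 0.2-34 mg/kg.
#'
#' Positive-valued, orders-of-magnitude-spread properties (solubility,
#' permeability, intrinsic clearance, fup) use log10-normal marginals;
#' MW and LogD use truncated normals.
#'
#' @param n_compounds library size (default 267).
#' @param seed integer seed fixing all randomness of [generate_library()].
#' @param mw_mean,mw_sd,mw_range MW marginal (Da).
#' @param logd_mean,logd_sd,logd_range LogD7.4 marginal.
#' @param saq_log10_mean,saq_log10_sd log10 aqueous solubility (ug/mL).
#' @param papp_log10_mean,papp_log10_sd log10 LLC-PK1 Papp (cm/s).
#' @param clint_log10_mean,clint_log10_sd log10 CLint,heps
#'   (uL/min/10^6 cells).
#' @param fup_log10_mean,fup_log10_sd log10 fup (truncated at 1).
#' @param ion_props named proportions for acidic/basic/neutral/zwitterion
#'   (must sum to 1).
#' @param p_biorelevant probability that FaSSIF/FeSSIF solubilities are
#'   available.
#' @param iv_dose_range,po_dose_range log-uniform dose ranges, mg/kg.
#' @param iv_arm_lambda,po_arm_lambda Poisson rates for extra arms per
#'   compound (arm count is `1 + rpois(lambda)`).
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_compounds = 267, seed = 1L,
                         mw_mean = 413, mw_sd = 80, mw_range = c(250, 700),
                         logd_mean = 2.48, logd_sd = 1.2,
                         logd_range = c(-1.5, 5),
                         saq_log10_mean = log10(0.20), saq_log10_sd = 1.2,
                         papp_log10_mean = -2.97, papp_log10_sd = 0.55,
                         clint_log10_mean = 1, clint_log10_sd = 0.55,
                         fup_log10_mean = -0.75, fup_log10_sd = 0.65,
                         ion_props = c(acidic = 0.025, basic = 0.33,
                                       neutral = 0.637, zwitterion = 0.008),
                         p_biorelevant = 0.494,
                         iv_dose_range = c(0.03, 10),
                         po_dose_range = c(0.2, 34),
                         iv_arm_lambda = 0.6, po_arm_lambda = 0.8) {
  stopifnot(n_compounds >= 0, length(ion_props) == 4)
  if (abs(sum(ion_props) - 1) > 1e-8)
    stop("ionization proportions must sum to 1")
  structure(as.list(environment()), class = "library_spec")
}

#' Observation noise model for pseudo-observed PK
#'
#' Multiplicative lognormal error structure: a geometric standard deviation
#' (GSD) applied to each observed PK parameter, plus a GSD perturbing the
#' "true" in vivo intrinsic clearance away from the in vitro value (the
#' realistic IVIVE disconnect). GSD 1 means no noise.
#'
#' @param gsd_obs observation GSD for CL, Vss, AUCinf, Cmax, Foral
#'   (default 1.15).
#' @param gsd_clint in vitro-to-in vivo intrinsic clearance perturbation GSD
#'   (default 2.0, matching the roughly 2-fold geometric precision seen for
#'   hepatocyte-based clearance scaling).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gsd_obs = 1.15, gsd_clint = 2.0) {
  stopifnot(gsd_obs >= 1, gsd_clint >= 1)
  structure(list(gsd_obs = gsd_obs, gsd_clint = gsd_clint),
            class = "noise_model")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2]))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic compound library
#'
#' Draws `n_compounds` compound records with the marginal structure of a
#' [library_spec()]. Ionization fractions are derived from drawn pKa values
#' (Henderson-Hasselbalch), so classification and partitioning see a
#' consistent compound. The blood-to-plasma ratio is constructed from a
#' drawn erythrocyte partition through the same composition equations used
#' by [compute_kp()], which guarantees a physically consistent BP for every
#' compound (in particular, a nonnegative acidic-phospholipid association
#' constant for bases). An `external_predicted` intrinsic clearance column
#' (emulating a structure-based ML model) is attached as `clint_external`.
#'
#' @param spec a [library_spec()].
#' @return A list of [compound_record()] objects (class `compound_library`).
#' @examples
#' lib <- generate_library(library_spec(n_compounds = 5, seed = 42))
#' lib[[1]]
#' @export
generate_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "library_spec"))
  if (spec$n_compounds == 0) return(structure(list(),
                                              class = "compound_library"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    cats <- sample(names(spec$ion_props), n, replace = TRUE,
                   prob = spec$ion_props)
    lib <- vector("list", n)
    bc <- blood_composition()
    hct <- 0.46
    for (i in seq_len(n)) {
      cat_i <- cats[i]
      pka_acid <- switch(cat_i,
        acidic = rnorm_trunc(1, 4.2, 0.7, c(2.5, 6.0)),
        zwitterion = rnorm_trunc(1, 4.0, 0.6, c(2.5, 5.5)),
        numeric(0))
      pka_base <- switch(cat_i,
        basic = rnorm_trunc(1, 8.7, 0.8, c(7.9, 10.5)),
        zwitterion = rnorm_trunc(1, 9.0, 0.5, c(8.5, 10.5)),
        numeric(0))
      ion <- ionization_from_pka(pka_acid, pka_base)

      mw <- rnorm_trunc(1, spec$mw_mean, spec$mw_sd, spec$mw_range)
      logd <- rnorm_trunc(1, spec$logd_mean, spec$logd_sd, spec$logd_range)
      s_aq <- 10^stats::rnorm(1, spec$saq_log10_mean, spec$saq_log10_sd)
      papp <- 10^stats::rnorm(1, spec$papp_log10_mean, spec$papp_log10_sd)
      clint <- 10^stats::rnorm(1, spec$clint_log10_mean,
                               spec$clint_log10_sd)
      # mild lipophilicity-binding coupling: more lipophilic compounds are
      # more plasma-bound, keeping the composition-implied BP physiological
      fup_mu <- spec$fup_log10_mean - 0.3 * (logd - spec$logd_mean)
      repeat {
        fup <- 10^stats::rnorm(1, fup_mu, spec$fup_log10_sd)
        if (fup <= 1) break
      }

      P <- 10^logd
      lipid_bc <- P * bc$f_nl_bc + (0.3 * P + 0.7) * bc$f_np_bc
      if (length(pka_base) && max(pka_base) >= 7) {
        pka <- max(pka_base)
        X <- 10^(pka - bc$ph_plasma)
        Yb <- 10^(pka - bc$ph_bc)
        ka_ap <- 10^stats::rnorm(1, log10(8), 0.4)
        kpu_bc <- bc$f_iw_bc * (1 + Yb) / (1 + X) + lipid_bc +
          ka_ap * bc$ap_bc * Yb / (1 + X)
      } else {
        ratio <- hh_factor(bc$ph_bc, pka_acid, pka_base) /
          hh_factor(bc$ph_plasma, pka_acid, pka_base)
        kpu_bc <- (bc$f_iw_bc * ratio + lipid_bc) *
          10^stats::rnorm(1, 0, 0.08)
      }
      bp <- 1 - hct + hct * fup * kpu_bc

      if (stats::runif(1) < spec$p_biorelevant) {
        sr <- min(50, 10^stats::rnorm(1, -1.1 + 0.35 * logd, 0.5))
        s_fassif <- s_aq * (1 + 3 * sr)
        s_fessif <- s_aq * (1 + 15 * sr)
      } else {
        s_fassif <- s_fessif <- NA_real_
      }

      lib[[i]] <- compound_record(
        sprintf("SYN-%04d", i),
        in_vitro_inputs(logd74 = logd, s_aq = s_aq,
                        papp_llcpk1 = papp, clint_heps = clint,
                        fup = fup, bp = bp, mw = mw,
                        s_fassif = s_fassif, s_fessif = s_fessif),
        ion,
        clint_external = clint * 10^stats::rnorm(1, 0, 0.45))
    }
    structure(lib, class = "compound_library")
  })
}

#' Generate pseudo-observed study arms by forward simulation
#'
#' For each compound a "true" in vivo whole-body intrinsic clearance is
#' drawn by perturbing the in vitro value (scaled under `generating_method`,
#' default direct scaling) with the `gsd_clint` lognormal disconnect; IV and
#' PO arms are then forward-simulated at doses sampled log-uniformly from
#' the spec ranges, NCA parameters extracted, and multiplicative
#' observation noise (`gsd_obs`) applied. With both GSDs at 1 the package's
#' own pipeline recovers the observations exactly (parameter-recovery
#' harness).
#'
#' PO formulations are `"suspension"` when the absolute dose exceeds the
#' dissolved capacity of roughly 10 mL of biorelevant-solubility fluid,
#' `"solution"` otherwise.
#'
#' @param library a `compound_library` from [generate_library()].
#' @param spec the [library_spec()] (dose ranges and arm-count rates).
#' @param noise a [noise_model()].
#' @param seed integer seed for dose sampling, perturbations and noise.
#' @param phys a [rat_physiology()].
#' @param routes routes to generate (`c("IV", "PO")` by default).
#' @param model disposition model used for the forward simulation
#'   (`"full"` or `"reduced"`).
#' @param generating_method the fu_inc assumption treated as the true
#'   scaling (default direct).
#' @return A data.frame of study arms (class `study_arms`): `compound_id`,
#'   `route`, `dose`, `formulation`, `observed_cl`, `observed_vss`,
#'   `observed_aucinf`, `observed_cmax`, `observed_foral`, `fe`, and the
#'   generator-internal `clint_u_wb_true` (kept for diagnostics).
#' @export
generate_observations <- function(library, spec = library_spec(),
                                  noise = noise_model(), seed = 1L,
                                  phys = rat_physiology(),
                                  routes = c("IV", "PO"),
                                  model = c("full", "reduced"),
                                  generating_method = scaling_method("direct")) {
  stopifnot(inherits(library, "compound_library"),
            inherits(noise, "noise_model"))
  model <- match.arg(model)
  routes <- match.arg(routes, c("IV", "PO"), several.ok = TRUE)
  rlnorm_gsd <- function(n, gsd)
    if (gsd == 1) rep(1, n) else exp(stats::rnorm(n, 0, log(gsd)))
  with_seed(seed, {
    rows <- list()
    for (cmpd in library) {
      iv <- cmpd$in_vitro
      fu_inc <- compute_fu_inc(generating_method, iv$fup, iv$logd74,
                               classify_ionization(cmpd$ionization),
                               cmpd$ionization$pka_base)
      clint_u_wb <- scale_to_whole_body(
        unbound_clint(iv$clint_heps, fu_inc), phys) *
        rlnorm_gsd(1, noise$gsd_clint)
      kps <- compute_kp_set(cmpd, phys)
      vss <- compute_vss(kps, iv$bp, phys)

      if ("IV" %in% routes) {
        n_iv <- 1 + stats::rpois(1, spec$iv_arm_lambda)
        sim1 <- if (model == "full")
          simulate_iv(cmpd, 1, clint_u_wb, kps = kps, phys = phys)
        else simulate_reduced(cmpd, 1, "IV", clint_u_wb, vss = vss,
                              phys = phys)
        pk1 <- suppressWarnings(nca(sim1))
        for (a in seq_len(n_iv)) {
          dose <- exp(stats::runif(1, log(spec$iv_dose_range[1]),
                                   log(spec$iv_dose_range[2])))
          rows[[length(rows) + 1L]] <- data.frame(
            compound_id = cmpd$compound_id, route = "IV", dose = dose,
            formulation = "solution",
            observed_cl = pk1$cl * rlnorm_gsd(1, noise$gsd_obs),
            observed_vss = pk1$vss * rlnorm_gsd(1, noise$gsd_obs),
            observed_aucinf = pk1$aucinf * dose *
              rlnorm_gsd(1, noise$gsd_obs),
            observed_cmax = pk1$cmax * dose * rlnorm_gsd(1, noise$gsd_obs),
            observed_foral = NA_real_, fe = 0,
            clint_u_wb_true = clint_u_wb,
            stringsAsFactors = FALSE)
        }
      }
      if ("PO" %in% routes) {
        n_po <- 1 + stats::rpois(1, spec$po_arm_lambda)
        s_ref <- if (is.finite(iv$s_fassif)) iv$s_fassif else iv$s_aq
        for (a in seq_len(n_po)) {
          dose <- exp(stats::runif(1, log(spec$po_dose_range[1]),
                                   log(spec$po_dose_range[2])))
          form <- if (dose * phys$bw > s_ref * 1e-3 * 10)
            "suspension" else "solution"
          sim <- if (model == "full")
            simulate_po(cmpd, dose, clint_u_wb, formulation = form,
                        kps = kps, phys = phys)
          else simulate_reduced(cmpd, dose, "PO", clint_u_wb, vss = vss,
                                phys = phys, formulation = form)
          pk <- suppressWarnings(nca(sim))
          auc <- if (is.finite(pk$aucinf)) pk$aucinf else pk$auclast
          rows[[length(rows) + 1L]] <- data.frame(
            compound_id = cmpd$compound_id, route = "PO", dose = dose,
            formulation = form,
            observed_cl = NA_real_, observed_vss = NA_real_,
            observed_aucinf = auc * rlnorm_gsd(1, noise$gsd_obs),
            observed_cmax = pk$cmax * rlnorm_gsd(1, noise$gsd_obs),
            observed_foral = sim$foral * rlnorm_gsd(1, noise$gsd_obs),
            fe = 0, clint_u_wb_true = clint_u_wb,
            stringsAsFactors = FALSE)
        }
      }
    }
    arms <- do.call(rbind, rows)
    class(arms) <- c("study_arms", "data.frame")
    arms
  })
}
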