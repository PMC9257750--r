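#' Bile-salt solubilization ratio from biorelevant solubilities
#'
#' Per-mM solubilization ratio estimated from the enhancement of FaSSIF
#' (3 mM bile salt) and/or FeSSIF (15 mM) solubility over aqueous
#' solubility: `SR = max over media of (S_medium / S_aq - 1) / C_bs`,
#' clipped at zero. With no biorelevant value available the ratio falls back
#' to 0 (aqueous-only) with a warning.
#'
#' @param s_aq aqueous solubility, ug/mL (> 0).
#' @param s_fassif,s_fessif biorelevant solubilities, ug/mL (`NA` if absent).
#' @return Solubilization ratio per mM bile salt (unitless, >= 0).
#' @examples
#' estimate_solubilization_ratio(1, s_fassif = 4)    # (4-1)/3 = 1
#' @export
estimate_solubilization_ratio <- function(s_aq, s_fassif = NA_real_,
                                          s_fessif = NA_real_) {
  stopifnot(is.finite(s_aq), s_aq > 0)
  ratios <- c(if (is.finite(s_fassif)) (s_fassif / s_aq - 1) / 3,
              if (is.finite(s_fessif)) (s_fessif / s_aq - 1) / 15)
  if (!length(ratios)) {
    warning("no biorelevant solubility available; solubilization ratio ",
            "set to 0 (aqueous solubility only)")
    return(0)
  }
  max(0, ratios)
}

#' Luminal solubility model
#'
#' Reference aqueous solubility plus the ionization constants and bile-salt
#' solubilization ratio needed to evaluate local solubility along the gut.
#'
#' @param s_aq reference aqueous solubility, ug/mL (> 0).
#' @param ref_ph pH of the reference measurement (default 6.5).
#' @param pka_acid,pka_base dissociation constants.
#' @param sr solubilization ratio per mM bile salt (>= 0).
#' @param max_amplification cap on the pH-driven solubility amplification
#'   relative to the reference (default 1e4-fold).
#' @return An object of class `solubility_model`.
#' @export
solubility_model <- function(s_aq, ref_ph = 6.5, pka_acid = numeric(0),
                             pka_base = numeric(0), sr = 0,
                             max_amplification = 1e4) {
  stopifnot(is.finite(s_aq), s_aq > 0, sr >= 0, max_amplification >= 1)
  structure(list(s_aq = s_aq, ref_ph = ref_ph,
                 pka_acid = as.numeric(pka_acid),
                 pka_base = as.numeric(pka_base), sr = sr,
                 max_amplification = max_amplification),
            class = "solubility_model")
}

# total:neutral solubility factor at a pH (Henderson-Hasselbalch,
# independent sites)
hh_factor <- function(ph, pka_acid, pka_base) {
  f <- 1
  if (length(pka_acid)) f <- f + sum(10^(ph - pka_acid))
  if (length(pka_base)) f <- f + sum(10^(pka_base - ph))
  f
}

#' Local solubility in a gut compartment
#'
#' Henderson-Hasselbalch rescaling of the reference solubility to the
#' compartment pH (capped at `max_amplification`-fold), then multiplied by
#' the bile-salt enhancement `1 + SR * C_bs`.
#'
#' @param model a [solubility_model()].
#' @param compartment one row of a [rat_gut()] table (uses `ph` and
#'   `bile_salt`).
#' @return Solubility, ug/mL.
#' @export
local_solubility <- function(model, compartment) {
  stopifnot(inherits(model, "solubility_model"))
  amp <- hh_factor(compartment$ph, model$pka_acid, model$pka_base) /
    hh_factor(model$ref_ph, model$pka_acid, model$pka_base)
  amp <- min(amp, model$max_amplification)
  model$s_aq * amp * (1 + model$sr * compartment$bile_salt)
}

# Diffusion coefficient from molecular weight (empirical power law),
# cm^2/min.
diffusion_coefficient <- function(mw) 9.9e-5 * mw^(-0.453) * 60

#' Particle dissolution rate (shrinking monodisperse spheres)
#'
#' Nernst-Brunner / Noyes-Whitney rate for a monodisperse suspension:
#' `rate = 3 D M (Cs - C) / (rho h_eff r)`, zero when the dissolved
#' concentration has reached saturation (supersaturation is clamped, no
#' precipitation is modeled). The diffusion-layer thickness is the particle
#' radius capped at 30 um.
#'
#' @param m_undissolved undissolved mass (mg or mg/kg; the rate has the same
#'   mass unit per minute).
#' @param radius current particle radius, cm.
#' @param cs local saturation solubility, mg/mL.
#' @param c_diss local dissolved concentration, mg/mL.
#' @param d_diff diffusion coefficient, cm^2/min (from molecular weight when
#'   `NULL` is not allowed here; see [diffusion_coefficient()]).
#' @param rho particle density, g/mL (default 1.2).
#' @param h_cap diffusion-layer cap, cm (default 30 um).
#' @return Dissolution rate, mass unit of `m_undissolved` per minute.
#' @export
dissolution_rate <- function(m_undissolved, radius, cs, c_diss, d_diff,
                             rho = 1.2, h_cap = 30e-4) {
  stopifnot(all(m_undissolved >= 0), radius > 0)
  h_eff <- pmin(radius, h_cap)
  rate <- 3 * d_diff * m_undissolved * (cs - c_diss) /
    (rho * 1000 * h_eff * radius)
  pmax(rate, 0)
}

# Assemble the linear part of the PO system and its gut metadata.
# model "full": disposition matrix + lumen states, absorbed flux -> liver.
# model "reduced": central compartment of volume vss, absorbed flux split
# Fh -> central / (1 - Fh) -> amet (hepatic first pass as fractional loss).
build_po_system <- function(compound, clint_u_wb, phys, gut, formulation,
                            model = c("full", "reduced"), kps = NULL,
                            vss = NULL, peff_rat = NULL) {
  model <- match.arg(model)
  iv <- compound$in_vitro
  bp <- iv$bp; fup <- iv$fup
  if (is.null(peff_rat))
    peff_rat <- peff_human_to_rat(papp_to_peff_human(iv$papp_llcpk1))
  ka <- ifelse(gut$absorb, 2 * (peff_rat * 1e-4) * 60 / gut$radius, 0)

  sr <- if (is.finite(iv$s_fassif) || is.finite(iv$s_fessif)) {
    estimate_solubilization_ratio(iv$s_aq, iv$s_fassif, iv$s_fessif)
  } else 0
  smod <- solubility_model(iv$s_aq, pka_acid = compound$ionization$pka_acid,
                           pka_base = compound$ionization$pka_base, sr = sr)
  cs <- vapply(seq_len(nrow(gut)), function(i)
    local_solubility(smod, gut[i, ]), numeric(1)) * 1e-3   # mg/mL
  vol_lumen <- gut$volume / phys$bw                        # mL/kg

  suspended <- formulation == "suspension"
  gd <- paste0("gd_", gut$compartment)
  gs <- if (suspended) paste0("gs_", gut$compartment) else character(0)

  if (model == "full") {
    if (is.null(kps)) kps <- compute_kp_set(compound, phys)
    A_disp <- build_disposition_matrix(phys, kps, bp, fup, clint_u_wb)
    target <- if ("liver" %in% colnames(A_disp)) "liver" else "ven"
    fh_split <- c(1, 0)               # all absorbed mass enters the liver
  } else {
    cl_p <- well_stirred_cl(clint_u_wb, fup, bp, phys)
    v_ml <- vss * 1000
    A_disp <- matrix(0, 2, 2, dimnames = list(c("central", "amet"),
                                              c("central", "amet")))
    A_disp["central", "central"] <- -cl_p / v_ml
    A_disp["amet", "central"] <- cl_p / v_ml
    target <- "central"
    clh_blood <- well_stirred_cl(clint_u_wb, fup, bp, phys) / bp
    fh <- 1 - clh_blood / phys$qh
    fh_split <- c(fh, 1 - fh)
  }

  states <- c(colnames(A_disp), gd, gs, "aexcr")
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  A[seq_len(nrow(A_disp)), seq_len(nrow(A_disp))] <- A_disp
  ix <- function(s) match(s, states)
  kt <- gut$kt / 60                                       # 1/min
  ng <- nrow(gut)
  for (i in seq_len(ng)) {
    di <- ix(gd[i])
    dn <- if (i < ng) ix(gd[i + 1]) else ix("aexcr")
    A[dn, di] <- A[dn, di] + kt[i]
    A[di, di] <- A[di, di] - kt[i]
    if (ka[i] > 0) {
      A[di, di] <- A[di, di] - ka[i]
      A[ix(target), di] <- A[ix(target), di] + ka[i] * fh_split[1]
      if (fh_split[2] > 0)
        A[ix("amet"), di] <- A[ix("amet"), di] + ka[i] * fh_split[2]
    }
    if (suspended) {
      si <- ix(gs[i])
      sn <- if (i < ng) ix(gs[i + 1]) else ix("aexcr")
      A[sn, si] <- A[sn, si] + kt[i]
      A[si, si] <- A[si, si] - kt[i]
    }
  }
  if (max(abs(colSums(A))) > 1e-9 * max(abs(A)))
    stop("internal error: PO system matrix does not conserve mass")

  list(A = A, states = states, gd_idx = match(gd, states),
       gs_idx = if (suspended) match(gs, states) else integer(0),
       cs = cs, vol_lumen = vol_lumen, suspended = suspended,
       kps = kps, vss = vss, model = model,
       d_diff = diffusion_coefficient(iv$mw), peff_rat = peff_rat)
}

# Strang-splitting integration of the suspension system: exact linear steps
# (precomputed matrix exponentials) interleaved with closed-form dissolution
# transfers at frozen dissolved concentration. Mass-conserving by
# construction. Returns list(time_min, X).
integrate_suspension <- function(sys, x0, t_end_min = 2880,
                                 dt_fine = 0.25, t_fine = 240,
                                 dt_coarse = NULL, r0 = 25e-4, rho = 1.2,
                                 h_cap = 30e-4) {
  # keep the late-time step count bounded for extended horizons
  if (is.null(dt_coarse)) dt_coarse <- max(2, t_end_min / 1440)
  tgrid <- c(seq(0, min(t_fine, t_end_min), by = dt_fine),
             if (t_end_min > t_fine)
               seq(t_fine + dt_coarse, t_end_min, by = dt_coarse))
  tgrid <- tgrid[tgrid <= t_end_min]
  P_fine <- as.matrix(Matrix::expm(Matrix::Matrix(sys$A * dt_fine)))
  P_coarse <- if (t_end_min > t_fine)
    as.matrix(Matrix::expm(Matrix::Matrix(sys$A * dt_coarse)))

  id <- sys$gd_idx; is <- sys$gs_idx
  s_tot0 <- sum(x0[is])
  rho_mg <- rho * 1000
  r <- r0
  dissolve <- function(x, tau) {
    S <- x[is]
    C <- x[id] / sys$vol_lumen
    drive <- sys$cs - C
    act <- which(S > 1e-15 & drive > 0)
    if (length(act)) {
      h_eff <- min(r, h_cap)
      k <- 3 * sys$d_diff * drive[act] / (rho_mg * h_eff * r)
      dS <- S[act] * (1 - exp(-k * tau))
      cap <- drive[act] * sys$vol_lumen[act]
      dS <- pmin(dS, cap)
      x[id[act]] <- x[id[act]] + dS
      x[is[act]] <- x[is[act]] - dS
    }
    x
  }

  X <- matrix(0, length(tgrid), length(x0))
  X[1, ] <- x0
  x <- x0
  for (j in 2:length(tgrid)) {
    dt <- tgrid[j] - tgrid[j - 1]
    P <- if (dt == dt_fine) P_fine else P_coarse
    x <- dissolve(x, dt / 2)
    x <- as.numeric(P %*% x)
    x <- dissolve(x, dt / 2)
    s_frac <- sum(x[is]) / s_tot0
    r <- r0 * max(s_frac, 1e-12)^(1 / 3)
    X[j, ] <- x
  }
  list(time_min = tgrid, X = X)
}

#' Oral PBPK simulation with compartmental absorption-transit
#'
#' Simulates a PO dose through the nine-compartment gut model (stomach,
#' duodenum, two jejunum, three ileum, caecum, colon): first-order transit,
#' regional pH- and bile-salt-dependent solubility, absorption at
#' `ka = 2 Peff_rat / R` from the dissolved lumen pool, and (for
#' suspensions) shrinking-sphere particle dissolution with a saturation
#' clamp. Absorbed drug enters the liver (hepatic first pass) of the
#' whole-body disposition model. Solution formulations start fully dissolved
#' in the stomach and the whole system is linear (solved exactly);
#' suspensions start as solid and are integrated by a mass-conserving
#' splitting scheme.
#'
#' Derived fractions: `Fabs` is the fraction of dose crossing the gut wall;
#' `Fg = 1` (no gut-wall metabolism is modeled); `Fh = 1 - CLh,blood / Qh`
#' at the well-stirred operating point; `Foral` is the dose-normalized
#' AUCinf ratio against a matched IV simulation (falling back to the AUC to
#' the last time point, with a flag, when no terminal phase is identifiable).
#'
#' @inheritParams simulate_iv
#' @param dose PO dose, mg/kg.
#' @param formulation `"solution"` or `"suspension"`.
#' @param gut a [rat_gut()] configuration.
#' @param peff_rat rat effective permeability in 1e-4 cm/s; derived from the
#'   compound's LLC-PK1 permeability via the regression chain when `NULL`.
#' @param particle_diameter suspension particle diameter, um (default 50).
#' @param particle_density particle density, g/mL (default 1.2).
#' @return A `simulation_result` with additional elements `fabs`, `fg`,
#'   `fh`, `foral`.
#' @seealso [simulate_reduced()] for the single-compartment variant.
#' @export
simulate_po <- function(compound, dose, clint_u_wb,
                        formulation = c("solution", "suspension"),
                        kps = NULL, phys = rat_physiology(),
                        gut = rat_gut(), peff_rat = NULL,
                        particle_diameter = 50, particle_density = 1.2,
                        times = default_time_grid()) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(compound, "compound_record"), dose > 0,
            clint_u_wb >= 0, particle_diameter > 0)
  sys <- build_po_system(compound, clint_u_wb, phys, gut, formulation,
                         model = "full", kps = kps, peff_rat = peff_rat)
  finish_po(sys, compound, dose, clint_u_wb, phys, gut, times,
            particle_diameter, particle_density,
            iv_fun = function(d) simulate_iv(compound, d, clint_u_wb,
                                             kps = sys$kps, phys = phys,
                                             times = times))
}

# Reduced-model PO: same gut train coupled to the one-compartment
# disposition; called from simulate_reduced().
simulate_po_reduced <- function(compound, dose, clint_u_wb, vss, phys,
                                formulation, gut, peff_rat, times) {
  sys <- build_po_system(compound, clint_u_wb, phys, gut, formulation,
                         model = "reduced", vss = vss, peff_rat = peff_rat)
  finish_po(sys, compound, dose, clint_u_wb, phys, gut, times,
            particle_diameter = 50, particle_density = 1.2,
            iv_fun = function(d) simulate_reduced(compound, d, "IV",
                                                  clint_u_wb, vss = vss,
                                                  phys = phys,
                                                  times = times))
}

# shared tail of the PO simulators: integrate, assemble result, derive
# Fabs/Fh/Foral
finish_po <- function(sys, compound, dose, clint_u_wb, phys, gut, times,
                      particle_diameter, particle_density, iv_fun) {
  bp <- compound$in_vitro$bp
  fup <- compound$in_vitro$fup
  x0 <- stats::setNames(numeric(length(sys$states)), sys$states)
  if (sys$suspended) x0[sys$gs_idx[1]] <- dose else x0[sys$gd_idx[1]] <- dose

  if (sys$suspended) {
    out <- integrate_suspension(sys, x0, t_end_min = max(times) * 60,
                                r0 = particle_diameter / 2 * 1e-4,
                                rho = particle_density)
    time_h <- out$time_min / 60
    X <- out$X
  } else {
    time_h <- times
    X <- solve_linear_ode(sys$A, x0, times * 60)
  }
  colnames(X) <- sys$states

  lumen_idx <- c(sys$gd_idx, sys$gs_idx)
  absorbed <- dose - rowSums(X[, lumen_idx, drop = FALSE]) - X[, "aexcr"]
  X <- cbind(X, aabs = absorbed)

  flags <- if (clint_u_wb == 0) "auc_divergent" else character(0)
  if (sys$model == "full") {
    res <- new_simulation_result(time_h, X, phys, sys$kps, bp, "PO", dose,
                                 flags)
  } else {
    v_ml <- sys$vss * 1000
    plasma <- pmax(0, X[, "central"] / v_ml * 1e6)
    res <- list(time = time_h, plasma = plasma,
                conc = matrix(plasma, dimnames = list(NULL, "central")),
                amounts = X, route = "PO", dose = dose,
                cumulative = list(metabolized = X[, "amet"],
                                  absorbed = absorbed,
                                  gut_excreted = X[, "aexcr"]),
                flags = flags, model = "reduced", vss = sys$vss)
    class(res) <- "simulation_result"
  }

  clh_blood <- well_stirred_cl(clint_u_wb, fup, bp, phys) / bp
  res$fabs <- absorbed[length(absorbed)] / dose
  res$fg <- 1
  res$fh <- 1 - clh_blood / phys$qh
  res$model <- sys$model

  if (max(res$plasma) <= 0) {      # nothing absorbed (e.g. Peff = 0)
    res$foral <- 0
    res$flags <- c(res$flags, "no_absorption")
    return(res)
  }

  # Foral: dose-normalized AUC ratio against a matched IV simulation
  iv_sim <- iv_fun(dose)
  nca_po <- suppressWarnings(nca(res))
  nca_iv <- suppressWarnings(nca(iv_sim))
  if (is.finite(nca_po$aucinf) && is.finite(nca_iv$aucinf)) {
    res$foral <- nca_po$aucinf / nca_iv$aucinf
  } else {
    res$foral <- nca_po$auclast / nca_iv$auclast
    res$flags <- c(res$flags, "foral_from_auclast")
  }
  res
}
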