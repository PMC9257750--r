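#' Whole-body IV PBPK simulation
#'
#' Simulates a single IV bolus dose in the perfusion-limited whole-body rat
#' model: venous and arterial whole-blood pools, the tissue compartments of
#' the physiology (11 by default) linked by blood flows, gut and spleen
#' draining portally into the liver, and hepatic elimination at the unbound
#' liver concentration (`fup * CLint,u,wb * C_liver / Kp_liver`). The system
#' is linear and is solved exactly (eigendecomposition / matrix exponential),
#' so no solver tolerances apply; machine-precision mass balance is
#' maintained, including the cumulative metabolized amount.
#'
#' @param compound a [compound_record()].
#' @param dose IV bolus dose, mg/kg (> 0), administered into venous blood.
#' @param clint_u_wb whole-body unbound intrinsic clearance, mL/min/kg
#'   (see [scale_to_whole_body()]).
#' @param kps optional [compute_kp_set()] result; computed from the compound
#'   when `NULL`.
#' @param phys a [rat_physiology()].
#' @param times output grid in hours (default: log-spaced to 48 h).
#' @return A `simulation_result`: `time` (h), `plasma` (venous plasma
#'   concentration, ng/mL), `conc` (per-compartment concentrations, ng/mL),
#'   `amounts` (state amounts, mg/kg), `cumulative$metabolized`, and a
#'   `auc_divergent` flag when there is no elimination.
#' @examples
#' cmpd <- compound_record("ex1",
#'   in_vitro_inputs(logd74 = 2, s_aq = 10, papp_llcpk1 = 2e-5,
#'                   clint_heps = 10, fup = 0.2, bp = 1, mw = 400),
#'   ionization_from_pka())
#' sim <- simulate_iv(cmpd, dose = 1, clint_u_wb = 100)
#' head(sim$plasma)
#' @export
simulate_iv <- function(compound, dose, clint_u_wb, kps = NULL,
                        phys = rat_physiology(),
                        times = default_time_grid()) {
  stopifnot(inherits(compound, "compound_record"), dose > 0,
            clint_u_wb >= 0)
  bp <- compound$in_vitro$bp
  fup <- compound$in_vitro$fup
  if (is.null(kps)) kps <- compute_kp_set(compound, phys)
  A <- build_disposition_matrix(phys, kps, bp, fup, clint_u_wb)
  x0 <- stats::setNames(numeric(nrow(A)), colnames(A))
  x0["ven"] <- dose
  X <- solve_linear_ode(A, x0, times * 60)
  colnames(X) <- colnames(A)
  flags <- if (clint_u_wb == 0) "auc_divergent" else character(0)
  new_simulation_result(times, X, phys, kps, bp, "IV", dose, flags)
}

#' Reduced (high-throughput) PK simulation
#'
#' Single-central-compartment disposition for fast batch prediction: the
#' central volume is the mechanistic Vss (from [compute_vss()]) and
#' elimination is the well-stirred hepatic plasma clearance. For the oral
#' route the central compartment is coupled to the compartmental
#' absorption-transit model; absorbed drug undergoes hepatic first pass as a
#' fractional loss `1 - Fh` with `Fh = 1 - CLh,blood / Qh`.
#'
#' The IV profile is the closed-form mono-exponential
#' `C(t) = (Dose / Vss) exp(-CL t / Vss)`.
#'
#' @inheritParams simulate_iv
#' @param route `"IV"` or `"PO"`.
#' @param vss central volume, L/kg; computed mechanistically when `NULL`.
#' @param formulation,gut,peff_rat oral-absorption settings, as in
#'   [simulate_po()] (PO route only).
#' @return A `simulation_result`; for PO it carries `fabs`, `fg`, `fh`,
#'   `foral` like [simulate_po()].
#' @export
simulate_reduced <- function(compound, dose, route = c("IV", "PO"),
                             clint_u_wb, vss = NULL,
                             phys = rat_physiology(),
                             formulation = "solution", gut = rat_gut(),
                             peff_rat = NULL,
                             times = default_time_grid()) {
  route <- match.arg(route)
  stopifnot(inherits(compound, "compound_record"), dose > 0,
            clint_u_wb >= 0)
  bp <- compound$in_vitro$bp
  fup <- compound$in_vitro$fup
  if (is.null(vss)) {
    kps <- compute_kp_set(compound, phys)
    vss <- compute_vss(kps, bp, phys)
  }
  stopifnot(vss > 0)
  cl_p <- well_stirred_cl(clint_u_wb, fup, bp, phys)   # mL/min/kg
  v_ml <- vss * 1000                                   # mL/kg

  if (route == "IV") {
    k <- cl_p / v_ml                                   # 1/min
    amt <- dose * exp(-k * times * 60)
    amounts <- cbind(central = amt, amet = dose - amt)
    plasma <- amt / v_ml * 1e6
    flags <- if (clint_u_wb == 0) "auc_divergent" else character(0)
    res <- list(time = times, plasma = plasma,
                conc = matrix(plasma, dimnames = list(NULL, "central")),
                amounts = amounts, route = "IV", dose = dose,
                cumulative = list(metabolized = amounts[, "amet"]),
                flags = flags, model = "reduced", vss = vss, cl = cl_p)
    class(res) <- "simulation_result"
    return(res)
  }
  simulate_po_reduced(compound, dose, clint_u_wb, vss, phys, formulation,
                      gut, peff_rat, times)
}
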