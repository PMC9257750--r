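#' Clearance scaling method
#'
#' Names one of the clearance-derivation routes used by the pipeline:
#' the four incubation-binding (fu_inc) assumptions for scaling hepatocyte
#' intrinsic clearance (`direct`, `dilution`, `unbound`, `austin`), the
#' reverse well-stirred `back_calculated` route from observed plasma
#' clearance, and `external_predicted` for an intrinsic clearance supplied as
#' an ordinary input column (e.g. a structure-based ML prediction).
#'
#' @param name method name.
#' @param df dilution factor for the `dilution` method (incubation plasma
#'   protein level relative to plasma; default 0.1 for a 10% serum-albumin
#'   incubation). Must lie in `(0, 1]`; at `df = 1` the dilution method
#'   reduces to direct scaling.
#' @return An object of class `scaling_method`.
#' @export
scaling_method <- function(name = c("direct", "dilution", "unbound", "austin",
                                    "back_calculated", "external_predicted"),
                           df = 0.1) {
  name <- match.arg(name)
  if (!is.finite(df) || df <= 0 || df > 1) stop("df must lie in (0, 1]")
  structure(list(name = name, df = df), class = "scaling_method")
}

#' Fraction unbound in the hepatocyte incubation
#'
#' The binding correction applied to measured hepatocyte intrinsic clearance
#' before IVIVE, under the selected assumption:
#' \describe{
#'   \item{direct}{`fu_inc = fup` -- incubation binding mirrors plasma
#'     binding, so the two cancel in the well-stirred model.}
#'   \item{dilution}{`fu_inc = 1 / (1 + df * (1/fup - 1))` -- plasma-protein
#'     binding diluted by factor `df` in the incubation
#'     (Berezhkovskiy-type correction).}
#'   \item{unbound}{`fu_inc = 1` -- measured clearance taken as unbound.}
#'   \item{austin}{`fu_inc = 1 / (1 + 10^(0.4 L - 1.38))` -- lipophilicity
#'     regression for hepatocyte binding, with `L = logP` for bases
#'     (reconstructed from the strongest basic pKa when available, otherwise
#'     logD7.4 with a warning) and `L = logD7.4` otherwise.}
#' }
#'
#' @param method a [scaling_method()] (`direct`, `dilution`, `unbound` or
#'   `austin`).
#' @param fup fraction unbound in plasma, `(0, 1]`.
#' @param logd74 distribution coefficient at pH 7.4 (used by `austin`).
#' @param ionization_category ionization class (used by `austin`).
#' @param pka_base basic pKa values, used to reconstruct logP for bases.
#' @return Fraction unbound in the incubation, in `(0, 1]`.
#' @examples
#' m <- scaling_method("dilution")
#' compute_fu_inc(m, fup = 0.1)      # 1/(1 + 0.1*9) = 0.526
#' @export
compute_fu_inc <- function(method, fup, logd74 = NA_real_,
                           ionization_category = "neutral",
                           pka_base = numeric(0)) {
  stopifnot(inherits(method, "scaling_method"))
  if (!is.finite(fup) || fup <= 0 || fup > 1) stop("fup must lie in (0, 1]")
  switch(method$name,
    direct = fup,
    dilution = 1 / (1 + method$df * (1 / fup - 1)),
    unbound = 1,
    austin = {
      if (!is.finite(logd74))
        stop("austin method requires logd74")
      L <- logd74
      if (identical(ionization_category, "basic")) {
        if (length(pka_base) && any(is.finite(pka_base))) {
          # logP of the neutral species from logD at 7.4 for a monoprotic base
          L <- logd74 + log10(1 + 10^(max(pka_base, na.rm = TRUE) - 7.4))
        } else {
          warning("austin method: no basic pKa available, using logD7.4 ",
                  "in place of logP")
        }
      }
      1 / (1 + 10^(0.4 * L - 1.38))
    },
    stop("compute_fu_inc is defined for the four fu_inc assumptions only, ",
         "not for method '", method$name, "'")
  )
}

#' Unbound intrinsic clearance in hepatocytes
#'
#' Corrects the measured hepatocyte intrinsic clearance for nonspecific
#' binding in the incubation: `CLint,u = CLint,heps / fu_inc`.
#'
#' @param clint_heps measured intrinsic clearance, uL/min/10^6 cells (>= 0).
#' @param fu_inc fraction unbound in the incubation, `(0, 1]`.
#' @return Unbound intrinsic clearance, uL/min/10^6 cells.
#' @export
unbound_clint <- function(clint_heps, fu_inc) {
  stopifnot(all(clint_heps >= 0))
  if (any(!is.finite(fu_inc) | fu_inc <= 0))
    stop("fu_inc must be > 0")
  clint_heps / fu_inc
}

#' Scale per-cell intrinsic clearance to the whole body
#'
#' `CLint,u[mL/min/kg] = CLint,u[uL/min/10^6 cells] * HPGL * LW / 1000`.
#' With the default rat physiology (HPGL 120, LW 40 g/kg) the factor is 4.8.
#'
#' @param clint_u unbound intrinsic clearance, uL/min/10^6 cells (>= 0).
#' @param phys a [rat_physiology()].
#' @return Whole-body unbound intrinsic clearance, mL/min/kg.
#' @export
scale_to_whole_body <- function(clint_u, phys = rat_physiology()) {
  stopifnot(all(clint_u >= 0), inherits(phys, "rat_physiology"))
  clint_u * phys$hpgl * phys$lw / 1000
}

#' Forward well-stirred hepatic clearance
#'
#' `fub = fup / BP`;
#' `CL_blood = Qh * fub * CLint,u / (Qh + fub * CLint,u)`;
#' plasma clearance is `CL_blood * BP`. Monotone nondecreasing in `CLint,u`
#' and bounded above by `Qh * BP` on the plasma basis.
#'
#' @param clint_u_wb whole-body unbound intrinsic clearance, mL/min/kg.
#' @param fup fraction unbound in plasma.
#' @param bp blood-to-plasma ratio.
#' @param phys a [rat_physiology()].
#' @return Plasma clearance, mL/min/kg.
#' @examples
#' well_stirred_cl(600, fup = 0.1, bp = 1)   # 30 mL/min/kg
#' @export
well_stirred_cl <- function(clint_u_wb, fup, bp, phys = rat_physiology()) {
  stopifnot(all(clint_u_wb >= 0), fup > 0, fup <= 1, bp > 0)
  fub <- fup / bp
  cl_blood <- phys$qh * fub * clint_u_wb / (phys$qh + fub * clint_u_wb)
  cl_blood * bp
}

#' Back-calculate hepatocyte intrinsic clearance from observed clearance
#'
#' Inverts the well-stirred liver model to recover the in vivo unbound
#' intrinsic clearance from an observed plasma clearance:
#' `CLh = CLp * (1 - fe)`; `CLh,blood = CLh / BP`;
#' `CLint,u[mL/min/kg] = Qh * CLh,blood / (fub * (Qh - CLh,blood))`;
#' then converted to per-cell units by the inverse whole-body scaling factor
#' (divide by `HPGL * LW / 1000`, 4.8 at defaults). When no urinary excretion
#' information is available `fe` defaults to zero (clearance assumed purely
#' hepatic).
#'
#' When the implied hepatic blood clearance reaches the hepatic blood flow
#' the inversion blows up; such arms are excluded by raising a condition of
#' class `htpbpk_flow_exceeded` (the comparison uses a safety margin,
#' default `0.99 * Qh`).
#'
#' @param cl_plasma_obs observed plasma clearance, mL/min/kg (>= 0).
#' @param fup,bp plasma unbound fraction and blood-to-plasma ratio.
#' @param fe fraction excreted unchanged in urine (default 0).
#' @param phys a [rat_physiology()].
#' @param margin exclusion threshold as a fraction of Qh (default 0.99).
#' @return Unbound intrinsic clearance, uL/min/10^6 cells.
#' @examples
#' back_calculate_clint(30, fup = 0.1, bp = 1)   # 125 uL/min/10^6 cells
#' @export
back_calculate_clint <- function(cl_plasma_obs, fup, bp, fe = 0,
                                 phys = rat_physiology(), margin = 0.99) {
  stopifnot(cl_plasma_obs >= 0, fup > 0, fup <= 1, bp > 0,
            fe >= 0, fe <= 1, margin > 0, margin <= 1)
  clh_blood <- cl_plasma_obs * (1 - fe) / bp
  if (clh_blood >= margin * phys$qh) {
    cond <- structure(
      class = c("htpbpk_flow_exceeded", "error", "condition"),
      list(message = sprintf(
             "hepatic blood clearance %.3g mL/min/kg reaches the liver blood flow limit (%.3g * Qh = %.3g); intrinsic clearance not calculated",
             clh_blood, margin, margin * phys$qh),
           call = sys.call()))
    stop(cond)
  }
  fub <- fup / bp
  clint_u_wb <- phys$qh * clh_blood / (fub * (phys$qh - clh_blood))
  clint_u_wb * 1000 / (phys$hpgl * phys$lw)
}
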