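#' Ionization profile of a compound at physiological pH
#'
#' Species fractions at pH 7.4 (anionic, cationic, neutral, zwitterionic)
#' plus the acid/base dissociation constants driving them. Fractions must lie
#' in `[0, 1]` and, when all four are supplied, sum to 1 within 1e-6.
#'
#' @param f_anion,f_cation,f_union,f_zwitter species fractions at pH 7.4.
#' @param pka_acid,pka_base numeric vectors of acidic / basic pKa values.
#' @return An object of class `ionization_profile`.
#' @seealso [ionization_from_pka()] to derive the fractions from pKa values,
#'   [classify_ionization()].
#' @export
ionization_profile <- function(f_anion = NA_real_, f_cation = NA_real_,
                               f_union = NA_real_, f_zwitter = NA_real_,
                               pka_acid = numeric(0), pka_base = numeric(0)) {
  f <- c(f_anion = f_anion, f_cation = f_cation,
         f_union = f_union, f_zwitter = f_zwitter)
  ok <- !is.na(f)
  if (any(f[ok] < 0 | f[ok] > 1))
    stop("ionization fractions must lie in [0, 1]")
  if (all(ok) && abs(sum(f) - 1) > 1e-6)
    stop("ionization fractions must sum to 1 (got ", signif(sum(f), 8), ")")
  structure(list(f_anion = f_anion, f_cation = f_cation, f_union = f_union,
                 f_zwitter = f_zwitter,
                 pka_acid = as.numeric(pka_acid),
                 pka_base = as.numeric(pka_base)),
            class = "ionization_profile")
}

#' Derive species fractions from pKa values
#'
#' Henderson-Hasselbalch with independent (strongest) acid and base sites:
#' the deprotonation probability of the acid site and the protonation
#' probability of the base site are combined multiplicatively into the four
#' species fractions.
#'
#' @param pka_acid,pka_base numeric vectors (may be empty).
#' @param ph pH at which to evaluate (default 7.4).
#' @return An [ionization_profile()].
#' @examples
#' ionization_from_pka(pka_base = 9)   # mostly cationic at pH 7.4
#' @export
ionization_from_pka <- function(pka_acid = numeric(0), pka_base = numeric(0),
                                ph = 7.4) {
  p_a <- if (length(pka_acid)) 1 / (1 + 10^(min(pka_acid) - ph)) else 0
  p_b <- if (length(pka_base)) 1 / (1 + 10^(ph - max(pka_base))) else 0
  ionization_profile(f_anion = p_a * (1 - p_b), f_cation = (1 - p_a) * p_b,
                     f_union = (1 - p_a) * (1 - p_b), f_zwitter = p_a * p_b,
                     pka_acid = pka_acid, pka_base = pka_base)
}

#' In vitro input set for one compound
#'
#' The minimal measured (or predicted) input set for bottom-up PBPK
#' simulation: lipophilicity, solubilities, permeability, hepatocyte
#' stability, plasma binding, blood partitioning and molecular weight.
#'
#' @param logd74 log octanol/water distribution coefficient at pH 7.4.
#' @param s_aq aqueous solubility at pH 6.5, ug/mL.
#' @param papp_llcpk1 apparent permeability in LLC-PK1 cells, cm/s.
#' @param clint_heps intrinsic clearance in suspended rat hepatocytes,
#'   uL/min/10^6 cells.
#' @param fup fraction unbound in rat plasma, in `(0, 1]`.
#' @param bp blood-to-plasma concentration ratio (> 0).
#' @param mw molecular weight, g/mol.
#' @param s_fassif,s_fessif optional FaSSIF / FeSSIF solubilities, ug/mL.
#' @return An object of class `in_vitro_inputs`.
#' @export
in_vitro_inputs <- function(logd74, s_aq, papp_llcpk1, clint_heps, fup, bp,
                            mw, s_fassif = NA_real_, s_fessif = NA_real_) {
  stopifnot(is.finite(logd74), is.finite(mw), mw > 0)
  if (!is.finite(fup) || fup <= 0 || fup > 1)
    stop("fup must lie in (0, 1]")
  if (!is.finite(bp) || bp <= 0) stop("bp must be > 0")
  nonneg <- c(s_aq = s_aq, papp_llcpk1 = papp_llcpk1,
              clint_heps = clint_heps)
  if (any(nonneg < 0, na.rm = TRUE))
    stop("solubility, papp and clint must be >= 0")
  if (!is.na(s_fassif) && s_fassif < 0) stop("s_fassif must be >= 0")
  if (!is.na(s_fessif) && s_fessif < 0) stop("s_fessif must be >= 0")
  structure(list(logd74 = logd74, s_aq = s_aq, s_fassif = s_fassif,
                 s_fessif = s_fessif, papp_llcpk1 = papp_llcpk1,
                 clint_heps = clint_heps, fup = fup, bp = bp, mw = mw),
            class = "in_vitro_inputs")
}

#' Compound record
#'
#' Binds a compound identifier to its in vitro inputs and ionization profile.
#'
#' @param compound_id unique identifier string.
#' @param in_vitro an [in_vitro_inputs()] object.
#' @param ionization an [ionization_profile()] object.
#' @param smiles optional structure string (carried through, never parsed).
#' @param clint_external optional externally predicted intrinsic clearance
#'   (uL/min/10^6 cells), e.g. from a structure-based ML model; used by the
#'   `external_predicted` scaling method as an ordinary input column.
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(compound_id, in_vitro, ionization,
                            smiles = NA_character_,
                            clint_external = NA_real_) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            nzchar(compound_id),
            inherits(in_vitro, "in_vitro_inputs"),
            inherits(ionization, "ionization_profile"))
  if (!is.na(clint_external) && clint_external < 0)
    stop("clint_external must be >= 0")
  structure(list(compound_id = compound_id, in_vitro = in_vitro,
                 ionization = ionization, smiles = smiles,
                 clint_external = clint_external),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  iv <- x$in_vitro
  cat("<compound_record>", x$compound_id,
      sprintf("(MW %.0f, LogD %.2f, fup %.3f, BP %.2f, CLint %.2f)\n",
              iv$mw, iv$logd74, iv$fup, iv$bp, iv$clint_heps))
  invisible(x)
}

#' Study arm: one dosing experiment with observed PK
#'
#' @param compound_id compound identifier.
#' @param route `"IV"` or `"PO"`.
#' @param dose dose, mg/kg. Checked against the plausible early-discovery
#'   ranges (IV 0.03-10, PO 0.2-34 mg/kg) with a warning when outside.
#' @param formulation `"solution"` or `"suspension"` (suspension: PO only).
#' @param observed_cl observed plasma clearance, mL/min/kg (IV).
#' @param observed_vss observed steady-state volume, L/kg (IV).
#' @param observed_aucinf observed AUCinf, ng.h/mL.
#' @param observed_cmax observed Cmax, ng/mL.
#' @param observed_foral observed oral bioavailability, fraction.
#' @param fe fraction excreted unchanged in urine, in `[0, 1]` (default 0).
#' @return An object of class `study_arm`.
#' @export
study_arm <- function(compound_id, route = c("IV", "PO"), dose,
                      formulation = c("solution", "suspension"),
                      observed_cl = NA_real_, observed_vss = NA_real_,
                      observed_aucinf = NA_real_, observed_cmax = NA_real_,
                      observed_foral = NA_real_, fe = 0) {
  route <- match.arg(route)
  formulation <- match.arg(formulation)
  stopifnot(is.finite(dose), dose > 0)
  if (route == "IV" && formulation == "suspension")
    stop("suspension formulation is PO only")
  rng <- if (route == "IV") c(0.03, 10) else c(0.2, 34)
  if (dose < rng[1] || dose > rng[2])
    warning(sprintf("%s dose %.3g mg/kg outside typical range [%g, %g]",
                    route, dose, rng[1], rng[2]))
  if (!is.finite(fe) || fe < 0 || fe > 1) stop("fe must lie in [0, 1]")
  structure(list(compound_id = compound_id, route = route, dose = dose,
                 formulation = formulation, observed_cl = observed_cl,
                 observed_vss = observed_vss,
                 observed_aucinf = observed_aucinf,
                 observed_cmax = observed_cmax,
                 observed_foral = observed_foral, fe = fe),
            class = "study_arm")
}

#' Classify ionization state at pH 7.4
#'
#' Zwitterionic when the zwitterion fraction reaches 0.5 (checked first, since
#' the four fractions sum to one), acidic when the anion fraction exceeds 0.5,
#' basic when the cation fraction exceeds 0.5, neutral otherwise.
#'
#' @param profile an [ionization_profile()].
#' @return `"acidic"`, `"basic"`, `"neutral"` or `"zwitterion"`.
#' @examples
#' classify_ionization(ionization_profile(0.05, 0.9, 0.05, 0))   # "basic"
#' @export
classify_ionization <- function(profile) {
  stopifnot(inherits(profile, "ionization_profile"))
  f <- c(profile$f_anion, profile$f_cation, profile$f_union,
         profile$f_zwitter)
  if (all(is.na(f)))
    stop("cannot classify ionization: all species fractions missing")
  f[is.na(f)] <- 0
  if (f[4] >= 0.5) return("zwitterion")
  if (f[1] > 0.5) return("acidic")
  if (f[2] > 0.5) return("basic")
  "neutral"
}

#' Extended clearance classification system (ECCS) class
#'
#' Varma decision table from permeability class (high when
#' Papp >= 5e-6 cm/s), ionization class (acids/zwitterions vs
#' bases/neutrals) and molecular weight (<= 400 vs > 400 g/mol). Classes 1a
#' and 2 imply metabolic clearance, 1b hepatic uptake, 3a/4 renal clearance,
#' 3b transporter-mediated hepatic uptake or renal clearance. Boundaries are
#' inclusive on the high-permeability and low-MW side.
#'
#' @param papp apparent permeability, cm/s.
#' @param ionization_category one of `"acidic"`, `"basic"`, `"neutral"`,
#'   `"zwitterion"` (see [classify_ionization()]).
#' @param mw molecular weight, g/mol.
#' @return One of `"1a"`, `"1b"`, `"2"`, `"3a"`, `"3b"`, `"4"`.
#' @export
classify_eccs <- function(papp, ionization_category, mw) {
  stopifnot(papp >= 0, mw > 0)
  ionization_category <- match.arg(ionization_category,
                                   c("acidic", "basic", "neutral",
                                     "zwitterion"))
  high_perm <- papp >= 5e-6
  acidic_like <- ionization_category %in% c("acidic", "zwitterion")
  if (acidic_like) {
    if (high_perm) { if (mw <= 400) "1a" else "1b" }
    else           { if (mw <= 400) "3a" else "3b" }
  } else {
    if (high_perm) "2" else "4"
  }
}

#' Systemic blood-clearance category
#'
#' Bins blood clearance relative to hepatic blood flow (60 mL/min/kg):
#' very low < 6, low 6-18, moderate 18-42, high 42-60 mL/min/kg. Values above
#' 60 are clipped into `"high"`.
#'
#' @param cl_blood blood clearance, mL/min/kg (>= 0).
#' @return One of `"very_low"`, `"low"`, `"moderate"`, `"high"`.
#' @export
classify_clearance <- function(cl_blood) {
  if (!is.finite(cl_blood) || cl_blood < 0)
    stop("cl_blood must be a nonnegative number")
  if (cl_blood < 6) "very_low"
  else if (cl_blood < 18) "low"
  else if (cl_blood < 42) "moderate"
  else "high"
}

#' Plasma protein binding category
#'
#' `"high"` binding when the fraction unbound in rat plasma is below 2%,
#' `"moderate"` otherwise (boundary 0.02 is moderate).
#'
#' @param fup fraction unbound in plasma, in `(0, 1]`.
#' @return `"high"` or `"moderate"`.
#' @export
classify_binding <- function(fup) {
  if (!is.finite(fup) || fup <= 0 || fup > 1) stop("fup must lie in (0, 1]")
  if (fup < 0.02) "high" else "moderate"
}

#' Human effective intestinal permeability from LLC-PK1 permeability
#'
#' Log-log correlation calibrated on reference drugs with known jejunal
#' permeability: `log10(Peff) = 0.607 log10(Papp) + 2.014`, with Papp in cm/s
#' and Peff returned in 1e-4 cm/s (the intercept encodes the unit change).
#'
#' @param papp_llcpk1 apparent permeability, cm/s (> 0).
#' @return Human Peff in 1e-4 cm/s.
#' @examples
#' papp_to_peff_human(1e-5)    # ~0.0953 x 1e-4 cm/s
#' @export
papp_to_peff_human <- function(papp_llcpk1) {
  if (any(!is.finite(papp_llcpk1) | papp_llcpk1 <= 0))
    stop("papp must be > 0")
  10^(0.607 * log10(papp_llcpk1) + 2.014)
}

#' Rat effective permeability from human effective permeability
#'
#' Fixed interspecies scalar: `Peff_rat = 1.14 * Peff_human` (same units).
#'
#' @param peff_human human Peff (>= 0), any units.
#' @return Rat Peff in the same units.
#' @export
peff_human_to_rat <- function(peff_human) {
  stopifnot(all(peff_human >= 0))
  1.14 * peff_human
}
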