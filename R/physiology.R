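#' Rat physiology for whole-body PBPK simulation
#'
#' Assembles the physiological parameter set used throughout the package:
#' scalar constants (body weight, hepatic blood flow, liver weight,
#' hepatocellularity, hematocrit), the 11-tissue table of volumes, perfusion
#' flows and Rodgers-Rowland composition data, and the blood pool volumes.
#'
#' The scalar constants default to the standard rat values used for clearance
#' IVIVE: hepatic blood flow 60 mL/min/kg, liver weight 40 g/kg, 120 million
#' hepatocytes per gram liver, body weight 0.25 kg. Tissue volumes, flows and
#' composition are taken from the standard literature compendia for the rat
#' (Brown-type tables; Rodgers-Rowland composition data) and are deliberately
#' exposed as data so alternates can be swapped in.
#'
#' Tissue table columns:
#' \describe{
#'   \item{tissue}{compartment name}
#'   \item{v}{tissue volume, mL/kg body weight}
#'   \item{q}{perfusion blood flow, mL/min/kg (lung flow is the total cardiac
#'     output and is handled structurally, its `q` is `NA`)}
#'   \item{f_ew, f_iw}{extra-/intracellular water volume fractions}
#'   \item{f_nl, f_np}{neutral lipid and neutral phospholipid fractions}
#'   \item{ap}{acidic phospholipid content, mg/g}
#'   \item{ratp}{tissue:plasma albumin-type protein ratio (extracellular
#'     protein binding term for acids/neutrals/weak bases)}
#' }
#'
#' @param bw body weight, kg.
#' @param qh total hepatic blood flow (hepatic artery + portal), mL/min/kg.
#' @param lw liver weight, g/kg.
#' @param hpgl hepatocellularity, 10^6 cells per g liver.
#' @param hct hematocrit (fraction).
#' @param tissues optional replacement tissue table (same columns as above).
#'   May contain any subset of compartments; `liver` is required for hepatic
#'   elimination and `gut`/`spleen` drain portally when present.
#' @param v_ven,v_art venous and arterial blood volumes, mL/kg.
#'
#' @return An object of class `rat_physiology`: a list with elements `bw`,
#'   `qh`, `lw`, `hpgl`, `hct`, `co` (cardiac output, mL/min/kg), `v_ven`,
#'   `v_art`, and `tissues`.
#' @examples
#' phys <- rat_physiology()
#' phys$qh                      # 60 mL/min/kg
#' subset(phys$tissues, tissue == "liver")
#' @export
rat_physiology <- function(bw = 0.25, qh = 60, lw = 40, hpgl = 120,
                           hct = 0.46, tissues = NULL,
                           v_ven = 40, v_art = 20) {
  stopifnot(bw > 0, qh > 0, lw > 0, hpgl > 0, hct > 0, hct < 1,
            v_ven > 0, v_art > 0)
  if (is.null(tissues)) tissues <- rat_tissue_table(qh = qh, lw = lw)
  required <- c("tissue", "v", "q", "f_ew", "f_iw", "f_nl", "f_np",
                "ap", "ratp")
  if (!all(required %in% names(tissues)))
    stop("tissue table must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(tissues$tissue))
    stop("duplicate tissue names in physiology table")
  qsum <- sum(tissues$q[tissues$tissue != "lung"], na.rm = TRUE)
  structure(list(bw = bw, qh = qh, lw = lw, hpgl = hpgl, hct = hct,
                 co = qsum, v_ven = v_ven, v_art = v_art,
                 tissues = tissues),
            class = "rat_physiology")
}

# Default rat tissue compendium (per kg body weight). Liver volume follows the
# 40 g/kg convention (density ~1 g/mL); hepatic-artery flow is qh minus the
# portal inflow (gut + spleen) so the total liver outflow equals qh exactly.
rat_tissue_table <- function(qh = 60, lw = 40) {
  q_gut <- 44; q_spleen <- 4
  q_ha <- qh - q_gut - q_spleen
  if (q_ha <= 0) stop("qh must exceed portal flow (gut + spleen = 48)")
  data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "skin", "spleen"),
    v = c(70, 50, 5.7, 27, 3.3, 7.3, lw, 5, 404, 190, 2),
    q = c(20, 25, 6, q_gut, 15, 41, q_ha, NA, 75, 18, q_spleen),
    f_ew = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273,
             0.161, 0.336, 0.118, 0.382, 0.207),
    f_iw = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483,
             0.573, 0.446, 0.630, 0.291, 0.579),
    f_nl = c(0.853, 0.017, 0.039, 0.038, 0.014, 0.012,
             0.014, 0.022, 0.010, 0.060, 0.0077),
    f_np = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0240,
             0.0240, 0.0128, 0.0072, 0.0044, 0.0113),
    ap = c(0.40, 0.67, 0.40, 2.41, 2.25, 5.03,
           4.56, 3.91, 1.53, 1.32, 3.18),
    ratp = c(0.049, 0.100, 0.048, 0.158, 0.157, 0.130,
             0.086, 0.212, 0.064, 0.277, 0.097),
    stringsAsFactors = FALSE
  )
}

# Blood-cell and plasma composition constants (Rodgers-Rowland):
# intracellular water / lipid fractions of erythrocytes, their acidic
# phospholipid content, intracellular pH values, and plasma lipid fractions.
blood_composition <- function() {
  list(f_iw_bc = 0.603, f_nl_bc = 0.0017, f_np_bc = 0.0029, ap_bc = 0.5,
       ph_plasma = 7.4, ph_iw = 7.0, ph_bc = 7.22,
       f_nl_plasma = 0.0023, f_np_plasma = 0.0013)
}

#' @export
print.rat_physiology <- function(x, ...) {
  cat("Rat physiology: bw", x$bw, "kg, Qh", x$qh, "mL/min/kg, CO", x$co,
      "mL/min/kg, Hct", x$hct, "\n")
  cat(nrow(x$tissues), "tissue compartments:",
      paste(x$tissues$tissue, collapse = ", "), "\n")
  invisible(x)
}

#' Rat gut physiology for the compartmental absorption-transit model
#'
#' Nine-compartment fasted-state rat gastrointestinal geometry: luminal fluid
#' volumes, pH, first-order transit rates, radii and regional bile-salt
#' concentrations. Values are a documented configuration assembled from
#' published rat GI physiology (small-intestinal transit ~1.6 h, high
#' continuous biliary bile-salt output, large caecum); they can be replaced
#' wholesale via the `gut` argument of [simulate_po()].
#'
#' Columns: `compartment`, `volume` (mL, absolute for a 0.25 kg rat),
#' `ph`, `kt` (transit rate, 1/h), `radius` (cm), `bile_salt` (mM),
#' `absorb` (logical; absorption enabled).
#'
#' @param colon_absorption logical; keep absorption on in caecum/colon
#'   (default `TRUE`).
#' @return A data.frame of class `rat_gut`.
#' @examples
#' rat_gut()
#' @export
rat_gut <- function(colon_absorption = TRUE) {
  g <- data.frame(
    compartment = c("stomach", "duodenum", "jejunum1", "jejunum2",
                    "ileum1", "ileum2", "ileum3", "caecum", "colon"),
    volume = c(1.1, 0.30, 0.60, 0.60, 0.50, 0.40, 0.30, 5.0, 1.5),
    ph     = c(3.5, 6.2, 6.4, 6.6, 6.8, 7.0, 7.2, 6.2, 6.6),
    kt     = 1 / c(0.25, 0.18, 0.28, 0.28, 0.28, 0.28, 0.28, 2.5, 6.0),
    radius = c(0.40, 0.18, 0.17, 0.16, 0.15, 0.14, 0.13, 0.50, 0.30),
    bile_salt = c(0, 10, 8, 6, 4, 3, 2, 0.5, 0.25),
    stringsAsFactors = FALSE
  )
  g$absorb <- c(FALSE, rep(TRUE, 6), colon_absorption, colon_absorption)
  class(g) <- c("rat_gut", "data.frame")
  g
}
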