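#' Tissue:plasma partition coefficient (composition-based)
#'
#' Rodgers-Rowland tissue-composition partitioning with the logD-based lipid
#' term modification: membrane affinity is taken as `P = 10^logD7.4` (the
#' measured distribution coefficient at plasma pH) and applied to the neutral
#' lipid and neutral phospholipid fractions without further neutral-fraction
#' scaling; water and electrostatic terms follow the original class split.
#'
#' Moderate-to-strong bases (any basic pKa >= 7) partition into tissue water,
#' neutral lipids/phospholipids, and bind electrostatically to acidic
#' phospholipids with an association constant back-calculated from the
#' blood-cell partition implied by the measured blood-to-plasma ratio and the
#' hematocrit. Acids, neutrals, weak bases and zwitterions use water + lipid
#' partitioning plus extracellular (albumin-type) protein binding scaled by
#' `1/fup - 1`.
#'
#' @param tissue one row of the physiology tissue table (see
#'   [rat_physiology()]).
#' @param fup fraction unbound in plasma, `(0, 1]`.
#' @param bp blood-to-plasma ratio.
#' @param logd74 log distribution coefficient at pH 7.4.
#' @param ionization an [ionization_profile()] (pKa lists drive the class
#'   split and ionization corrections).
#' @param hct hematocrit (default 0.46).
#' @return Kp, the tissue:plasma partition coefficient (unitless, > 0).
#' @seealso [compute_kp_set()], [compute_vss()]
#' @export
compute_kp <- function(tissue, fup, bp, logd74, ionization, hct = 0.46) {
  stopifnot(fup > 0, fup <= 1, bp > 0, is.finite(logd74),
            inherits(ionization, "ionization_profile"))
  bc <- blood_composition()
  P <- 10^logd74
  lipid <- function(f_nl, f_np) P * f_nl + (0.3 * P + 0.7) * f_np
  lipid_t <- lipid(tissue$f_nl, tissue$f_np)

  pka_b <- ionization$pka_base[is.finite(ionization$pka_base)]
  pka_a <- ionization$pka_acid[is.finite(ionization$pka_acid)]
  # any compound with a basic site of pKa >= 7 (zwitterions included) takes
  # the acidic-phospholipid binding route, dominated by the cationic species
  strong_base <- length(pka_b) > 0 && max(pka_b) >= 7

  if (strong_base) {
    pka <- max(pka_b)
    X  <- 10^(pka - bc$ph_plasma)   # ionized:neutral in plasma
    Yt <- 10^(pka - bc$ph_iw)       # ionized:neutral in tissue cell water
    Yb <- 10^(pka - bc$ph_bc)       # ionized:neutral in blood cells
    kpu_bc <- (hct - 1 + bp) / (hct * fup)
    if (kpu_bc <= 0)
      stop("blood-to-plasma ratio ", signif(bp, 4), " with hematocrit ", hct,
           " implies a negative blood-cell partition; check BP input")
    ka <- (kpu_bc - bc$f_iw_bc * (1 + Yb) / (1 + X) -
             lipid(bc$f_nl_bc, bc$f_np_bc)) * (1 + X) / (bc$ap_bc * Yb)
    if (ka < 0)
      stop("blood-to-plasma ratio ", signif(bp, 4),
           " is below the partition explained by blood-cell water and lipid",
           " alone (implied acidic-phospholipid association constant < 0);",
           " check BP/fup/logD consistency")
    kpu <- tissue$f_ew + tissue$f_iw * (1 + Yt) / (1 + X) + lipid_t +
      ka * tissue$ap * Yt / (1 + X)
  } else {
    # ionized:neutral ratios at plasma and intracellular pH
    ion_ratio <- function(ph) {
      r <- 0
      if (length(pka_a)) r <- r + sum(10^(ph - pka_a))
      if (length(pka_b)) r <- r + sum(10^(pka_b - ph))
      r
    }
    X <- ion_ratio(bc$ph_plasma)
    Y <- ion_ratio(bc$ph_iw)
    lipid_p <- lipid(bc$f_nl_plasma, bc$f_np_plasma)
    prot <- max(0, 1 / fup - 1 - lipid_p) * tissue$ratp
    kpu <- tissue$f_ew + tissue$f_iw * (1 + Y) / (1 + X) + lipid_t + prot
  }
  kp <- kpu * fup
  if (!is.finite(kp) || kp <= 0)
    stop("computed Kp for ", tissue$tissue, " is not positive")
  kp
}

#' Partition coefficients for all tissues of a physiology
#'
#' @param compound a [compound_record()].
#' @param phys a [rat_physiology()].
#' @param fup,bp optional overrides; default to the compound's in vitro
#'   values.
#' @return Named numeric vector of Kp values (class `kp_set`), one per
#'   tissue row.
#' @export
compute_kp_set <- function(compound, phys = rat_physiology(),
                           fup = NULL, bp = NULL) {
  stopifnot(inherits(compound, "compound_record"),
            inherits(phys, "rat_physiology"))
  if (is.null(fup)) fup <- compound$in_vitro$fup
  if (is.null(bp)) bp <- compound$in_vitro$bp
  tt <- phys$tissues
  kps <- vapply(seq_len(nrow(tt)), function(i)
    compute_kp(tt[i, ], fup, bp, compound$in_vitro$logd74,
               compound$ionization, hct = phys$hct), numeric(1))
  names(kps) <- tt$tissue
  class(kps) <- "kp_set"
  kps
}

#' Mechanistic steady-state volume of distribution
#'
#' Plasma-referenced: `Vss = Vplasma + V_bc * K_bc + sum_t Kp_t * V_t`, where
#' the erythrocyte partition `K_bc = (BP - (1 - Hct)) / Hct` folds the
#' blood-cell space in via the blood-to-plasma ratio, and the sum runs over
#' every tissue of the physiology (lung included).
#'
#' @param kps named Kp vector from [compute_kp_set()]; must cover every
#'   tissue in `phys$tissues`.
#' @param bp blood-to-plasma ratio.
#' @param phys a [rat_physiology()].
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kps, bp, phys = rat_physiology()) {
  stopifnot(inherits(phys, "rat_physiology"), bp > 0)
  tt <- phys$tissues
  missing_t <- setdiff(tt$tissue, names(kps))
  if (length(missing_t))
    stop("Kp missing for tissue(s): ", paste(missing_t, collapse = ", "))
  k_bc <- (bp - (1 - phys$hct)) / phys$hct
  if (k_bc < 0)
    stop("blood-to-plasma ratio ", signif(bp, 4),
         " implies a negative erythrocyte partition")
  v_blood <- phys$v_ven + phys$v_art
  v_plasma <- v_blood * (1 - phys$hct)
  v_bc <- v_blood * phys$hct
  (v_plasma + v_bc * k_bc +
      sum(kps[tt$tissue] * tt$v)) / 1000
}
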