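#' Read and write compound datasets as CSV
#'
#' One row per compound. Columns (units as in [in_vitro_inputs()]):
#' `compound_id`, `mw`, `logd74`, `s_aq`, `s_fassif`, `s_fessif`,
#' `papp_llcpk1`, `clint_heps`, `fup`, `bp`, `f_anion`, `f_cation`,
#' `f_union`, `f_zwitter`, `pka_acid`, `pka_base` (semicolon-separated
#' lists), `clint_external`, `smiles`. Missing optional values are empty
#' fields. Every record passes through the validating constructors on read.
#'
#' @param library a `compound_library`.
#' @param path CSV file path.
#' @return `write_compound_csv` returns `path` invisibly;
#'   `read_compound_csv` returns a `compound_library`.
#' @export
write_compound_csv <- function(library, path) {
  df <- as.data.frame(library)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_compound_csv
#' @export
read_compound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "mw", "logd74", "s_aq", "papp_llcpk1",
            "clint_heps", "fup", "bp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("compound CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id values in ", path)
  opt <- function(col, i) if (col %in% names(df) && !is.na(df[[col]][i]) &&
                              df[[col]][i] != "") df[[col]][i] else NA
  parse_list <- function(s) if (is.na(s) || s == "") numeric(0) else
    as.numeric(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
  lib <- lapply(seq_len(nrow(df)), function(i) {
    ion <- ionization_profile(
      f_anion = as.numeric(opt("f_anion", i)),
      f_cation = as.numeric(opt("f_cation", i)),
      f_union = as.numeric(opt("f_union", i)),
      f_zwitter = as.numeric(opt("f_zwitter", i)),
      pka_acid = parse_list(opt("pka_acid", i)),
      pka_base = parse_list(opt("pka_base", i)))
    compound_record(
      df$compound_id[i],
      in_vitro_inputs(logd74 = df$logd74[i], s_aq = df$s_aq[i],
                      papp_llcpk1 = df$papp_llcpk1[i],
                      clint_heps = df$clint_heps[i], fup = df$fup[i],
                      bp = df$bp[i], mw = df$mw[i],
                      s_fassif = as.numeric(opt("s_fassif", i)),
                      s_fessif = as.numeric(opt("s_fessif", i))),
      ion,
      smiles = as.character(opt("smiles", i)),
      clint_external = as.numeric(opt("clint_external", i)))
  })
  structure(lib, class = "compound_library")
}

#' @export
`[.compound_library` <- function(x, i) {
  structure(unclass(x)[i], class = "compound_library")
}

#' Flatten a compound library to a data.frame
#'
#' @param x a `compound_library`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.compound_library <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(cmpd) {
    iv <- cmpd$in_vitro; ion <- cmpd$ionization
    fmt_list <- function(v) if (length(v)) paste(v, collapse = ";") else ""
    data.frame(compound_id = cmpd$compound_id, mw = iv$mw,
               logd74 = iv$logd74, s_aq = iv$s_aq,
               s_fassif = iv$s_fassif, s_fessif = iv$s_fessif,
               papp_llcpk1 = iv$papp_llcpk1, clint_heps = iv$clint_heps,
               fup = iv$fup, bp = iv$bp,
               f_anion = ion$f_anion, f_cation = ion$f_cation,
               f_union = ion$f_union, f_zwitter = ion$f_zwitter,
               pka_acid = fmt_list(ion$pka_acid),
               pka_base = fmt_list(ion$pka_base),
               clint_external = cmpd$clint_external,
               smiles = cmpd$smiles, stringsAsFactors = FALSE)
  }))
}

#' Read and write study-arm tables as CSV
#'
#' One row per (compound, route, dose, experiment). Columns: `compound_id`,
#' `route` (IV/PO), `dose` (mg/kg), `formulation` (solution/suspension),
#' `observed_cl` (mL/min/kg), `observed_vss` (L/kg), `observed_aucinf`
#' (ng.h/mL), `observed_cmax` (ng/mL), `observed_foral` (fraction), `fe`
#' (fraction, empty read as 0). Each row is validated through
#' [study_arm()].
#'
#' @param arms a `study_arms` data.frame.
#' @param path CSV file path.
#' @return `write_arms_csv` returns `path` invisibly; `read_arms_csv` a
#'   validated `study_arms` data.frame.
#' @export
write_arms_csv <- function(arms, path) {
  keep <- intersect(c("compound_id", "route", "dose", "formulation",
                      "observed_cl", "observed_vss", "observed_aucinf",
                      "observed_cmax", "observed_foral", "fe"),
                    names(arms))
  utils::write.csv(arms[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_arms_csv
#' @export
read_arms_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "route", "dose")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("arms CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!"formulation" %in% names(df)) df$formulation <- "solution"
  if (!"fe" %in% names(df)) df$fe <- 0
  df$fe[is.na(df$fe)] <- 0
  for (col in c("observed_cl", "observed_vss", "observed_aucinf",
                "observed_cmax", "observed_foral"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  # row-wise validation through the constructor
  for (i in seq_len(nrow(df)))
    suppressWarnings(study_arm(df$compound_id[i], df$route[i], df$dose[i],
                               df$formulation[i], fe = df$fe[i]))
  class(df) <- c("study_arms", "data.frame")
  df
}
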