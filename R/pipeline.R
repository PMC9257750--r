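#' Batch run configuration
#'
#' Bundles the settings of an evaluation run: which clearance-derivation
#' methods to apply, which disposition model(s), which routes, the seed, and
#' the dilution factor. Validated here so the pipeline can fail fast.
#'
#' @param methods character vector from `direct`, `dilution`, `unbound`,
#'   `austin`, `back_calculated`, `external_predicted` (at least one).
#' @param model `"full"`, `"reduced"` or `"both"`.
#' @param routes subset of `c("IV", "PO")` (at least one).
#' @param seed integer seed echoed into outputs for provenance.
#' @param df dilution factor for the dilution method.
#' @param strat_min_n smallest stratum size for which stratified metric
#'   panels are reported (smaller strata are suppressed with a note).
#' @return An object of class `run_config`.
#' @export
run_config <- function(methods = c("direct", "dilution", "unbound",
                                   "austin", "back_calculated",
                                   "external_predicted"),
                       model = c("full", "reduced", "both"),
                       routes = c("IV", "PO"), seed = 1L, df = 0.1,
                       strat_min_n = 5) {
  model <- match.arg(model)
  if (length(methods) < 1) stop("at least one method is required")
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("direct", "dilution", "unbound",
                                   "austin", "back_calculated",
                                   "external_predicted"))
  routes <- match.arg(routes, c("IV", "PO"), several.ok = TRUE)
  if (length(routes) < 1) stop("at least one route is required")
  structure(list(methods = methods, model = model, routes = routes,
                 seed = as.integer(seed), df = df,
                 strat_min_n = strat_min_n),
            class = "run_config")
}

# Derive the whole-body unbound intrinsic clearance for one compound under
# one method. Returns the value or raises htpbpk_flow_exceeded /
# htpbpk_missing_input conditions.
derive_clint_u_wb <- function(cmpd, method, arms_iv, phys, df = 0.1) {
  iv <- cmpd$in_vitro
  ion_cat <- classify_ionization(cmpd$ionization)
  if (method == "back_calculated") {
    cl_obs <- arms_iv$observed_cl[is.finite(arms_iv$observed_cl)]
    if (!length(cl_obs))
      stop(structure(class = c("htpbpk_missing_input", "error",
                               "condition"),
                     list(message = "no observed IV clearance to back-calculate from",
                          call = NULL)))
    cl_obs <- exp(mean(log(pmax(cl_obs, 1e-12))))
    clint_heps_u <- back_calculate_clint(cl_obs, iv$fup, iv$bp,
                                         fe = arms_iv$fe[1], phys = phys)
    return(scale_to_whole_body(clint_heps_u, phys))
  }
  if (method == "external_predicted") {
    if (!is.finite(cmpd$clint_external))
      stop(structure(class = c("htpbpk_missing_input", "error",
                               "condition"),
                     list(message = "no external predicted CLint available",
                          call = NULL)))
    # external model predicts unbound intrinsic clearance directly
    return(scale_to_whole_body(cmpd$clint_external, phys))
  }
  fu_inc <- compute_fu_inc(scaling_method(method, df = df), iv$fup,
                           iv$logd74, ion_cat, cmpd$ionization$pka_base)
  scale_to_whole_body(unbound_clint(iv$clint_heps, fu_inc), phys)
}

#' Run a full prediction-vs-observation evaluation
#'
#' Reproduces the study design of a bottom-up prediction assessment: for
#' every study arm and every requested clearance-derivation method, derive
#' the whole-body unbound intrinsic clearance, simulate the arm (IV
#' whole-body or oral ACAT-coupled, full or reduced disposition), extract
#' NCA parameters, and tabulate predicted vs observed with the complete
#' error-metric panel, overall and stratified by protein-binding category,
#' clearance category and ECCS class. Arms that cannot be simulated under a
#' method (hepatic blood clearance at the flow limit during
#' back-calculation; missing inputs) are excluded with an itemized reason,
#' and per-method arm counts plus exclusions always add up to the input arm
#' count.
#'
#' @param compounds a `compound_library` (list of [compound_record()]).
#' @param arms a `study_arms` data.frame (see [generate_observations()] or
#'   [read_arms_csv()]).
#' @param config a [run_config()].
#' @param phys a [rat_physiology()].
#' @param gut a [rat_gut()].
#' @return An object of class `prediction_report`: list with `predictions`
#'   (long table: compound, arm, method, model, parameter, predicted,
#'   observed, fold_error, classifications), `panels` (metric panels per
#'   parameter x method x model with `stratum` columns), `exclusions`, and
#'   the echoed `config`.
#' @export
run_evaluation <- function(compounds, arms, config = run_config(),
                           phys = rat_physiology(), gut = rat_gut()) {
  stopifnot(inherits(config, "run_config"))
  if (!nrow(arms)) stop("no study arms supplied")
  models <- if (config$model == "both") c("full", "reduced") else config$model
  by_id <- stats::setNames(compounds,
                           vapply(compounds, `[[`, "", "compound_id"))
  missing_cmpd <- setdiff(unique(arms$compound_id), names(by_id))
  if (length(missing_cmpd))
    stop("arms reference unknown compounds: ",
         paste(missing_cmpd, collapse = ", "))
  arms <- arms[arms$route %in% config$routes, , drop = FALSE]
  arms$arm_id <- seq_len(nrow(arms))

  preds <- list(); excl <- list()
  for (model in models) {
    for (method in config$methods) {
      for (id in unique(arms$compound_id)) {
        cmpd <- by_id[[id]]
        a_c <- arms[arms$compound_id == id, , drop = FALSE]
        clint <- tryCatch(
          derive_clint_u_wb(cmpd, method,
                            a_c[a_c$route == "IV", , drop = FALSE],
                            phys, config$df),
          condition = function(e) e)
        if (inherits(clint, "condition")) {
          reason <- if (inherits(clint, "htpbpk_flow_exceeded"))
            "blood_flow_exceeded" else if (inherits(clint,
                                                    "htpbpk_missing_input"))
            "missing_input" else conditionMessage(clint)
          excl[[length(excl) + 1L]] <- data.frame(
            compound_id = id, method = method, model = model,
            arm_id = a_c$arm_id, reason = reason,
            stringsAsFactors = FALSE)
          next
        }
        preds[[length(preds) + 1L]] <-
          predict_compound_arms(cmpd, a_c, clint, method, model, phys, gut)
      }
    }
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(compound_id = character(0), arm_id = integer(0),
               method = character(0), model = character(0),
               route = character(0), parameter = character(0),
               predicted = numeric(0), observed = numeric(0),
               fold_error = numeric(0), ionization = character(0),
               eccs = character(0), binding = character(0),
               clearance_category = character(0))
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(compound_id = character(0), method = character(0),
               model = character(0), arm_id = integer(0),
               reason = character(0))
  panels <- build_panels(predictions, config$strat_min_n)
  structure(list(predictions = predictions, panels = panels,
                 exclusions = exclusions, config = config,
                 n_arms = nrow(arms)),
            class = "prediction_report")
}

# Predict all arms of one compound under one method/model; returns the long
# prediction table rows.
predict_compound_arms <- function(cmpd, a_c, clint_u_wb, method, model,
                                  phys, gut) {
  iv <- cmpd$in_vitro
  ion_cat <- classify_ionization(cmpd$ionization)
  eccs <- classify_eccs(iv$papp_llcpk1, ion_cat, iv$mw)
  binding <- classify_binding(iv$fup)
  kps <- compute_kp_set(cmpd, phys)
  vss_mech <- compute_vss(kps, iv$bp, phys)
  cl_p <- well_stirred_cl(clint_u_wb, iv$fup, iv$bp, phys)
  times <- default_time_grid(pk_horizon(cl_p, vss_mech))
  out <- list()

  iv_rows <- a_c[a_c$route == "IV", , drop = FALSE]
  if (nrow(iv_rows)) {
    sim1 <- if (model == "full")
      simulate_iv(cmpd, 1, clint_u_wb, kps = kps, phys = phys,
                  times = times)
    else simulate_reduced(cmpd, 1, "IV", clint_u_wb, vss = vss_mech,
                          phys = phys, times = times)
    pk1 <- suppressWarnings(nca(sim1))
    for (j in seq_len(nrow(iv_rows))) {
      arm <- iv_rows[j, ]
      cl_cat <- if (is.finite(arm$observed_cl))
        classify_clearance(arm$observed_cl / iv$bp) else NA_character_
      out[[length(out) + 1L]] <- long_rows(
        cmpd$compound_id, arm$arm_id, method, model, "IV",
        params = c(cl = pk1$cl, vss = pk1$vss,
                   aucinf = pk1$aucinf * arm$dose,
                   cmax = pk1$cmax * arm$dose),
        observed = c(cl = arm$observed_cl, vss = arm$observed_vss,
                     aucinf = arm$observed_aucinf,
                     cmax = arm$observed_cmax),
        ion_cat, eccs, binding, cl_cat)
    }
  }
  po_rows <- a_c[a_c$route == "PO", , drop = FALSE]
  for (j in seq_len(nrow(po_rows))) {
    arm <- po_rows[j, ]
    sim <- if (model == "full")
      simulate_po(cmpd, arm$dose, clint_u_wb,
                  formulation = arm$formulation, kps = kps, phys = phys,
                  gut = gut, times = times)
    else simulate_reduced(cmpd, arm$dose, "PO", clint_u_wb,
                          vss = vss_mech, phys = phys,
                          formulation = arm$formulation, gut = gut,
                          times = times)
    pk <- suppressWarnings(nca(sim))
    auc <- if (is.finite(pk$aucinf)) pk$aucinf else pk$auclast
    out[[length(out) + 1L]] <- long_rows(
      cmpd$compound_id, arm$arm_id, method, model, "PO",
      params = c(aucinf = auc, cmax = pk$cmax, foral = sim$foral,
                 fabs = sim$fabs, fh = sim$fh),
      observed = c(aucinf = arm$observed_aucinf,
                   cmax = arm$observed_cmax,
                   foral = arm$observed_foral,
                   fabs = NA_real_, fh = NA_real_),
      ion_cat, eccs, binding, NA_character_)
  }
  do.call(rbind, out)
}

long_rows <- function(id, arm_id, method, model, route, params, observed,
                      ion_cat, eccs, binding, cl_cat) {
  data.frame(compound_id = id, arm_id = arm_id, method = method,
             model = model, route = route, parameter = names(params),
             predicted = unname(params),
             observed = unname(observed[names(params)]),
             fold_error = unname(params / observed[names(params)]),
             ionization = ion_cat, eccs = eccs, binding = binding,
             clearance_category = cl_cat,
             stringsAsFactors = FALSE)
}

# metric panels per parameter x method x model, overall plus strata
build_panels <- function(predictions, strat_min_n = 5) {
  if (is.null(predictions) || !nrow(predictions)) return(NULL)
  strata <- list(overall = NULL, binding = "binding",
                 clearance = "clearance_category", eccs = "eccs")
  panels <- list()
  keys <- unique(predictions[, c("parameter", "method", "model")])
  for (i in seq_len(nrow(keys))) {
    sub <- merge(predictions, keys[i, ])
    sub <- sub[is.finite(sub$predicted) & is.finite(sub$observed) &
                 sub$predicted > 0 & sub$observed > 0, , drop = FALSE]
    for (sname in names(strata)) {
      col <- strata[[sname]]
      groups <- if (is.null(col)) list(all = sub) else
        split(sub, sub[[col]])
      for (g in names(groups)) {
        gg <- groups[[g]]
        if (nrow(gg) < max(2, if (is.null(col)) 2 else strat_min_n)) next
        pan <- suppressMessages(
          fold_error_panel(gg$predicted, gg$observed))
        panels[[length(panels) + 1L]] <- cbind(
          keys[i, ], stratification = sname, stratum = g, pan,
          row.names = NULL)
      }
    }
  }
  do.call(rbind, panels)
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>", x$n_arms, "arms x",
      length(x$config$methods), "method(s), model:", x$config$model, "\n")
  cat("  predictions:", nrow(x$predictions), "rows; exclusions:",
      nrow(x$exclusions), "\n")
  ov <- x$panels[x$panels$stratification == "overall", , drop = FALSE]
  if (!is.null(ov) && nrow(ov)) {
    cat("  overall panels:\n")
    print(ov[, c("parameter", "method", "model", "n", "pct_2fe",
                 "pct_3fe", "afe", "aafe", "rmsle", "spearman_rho")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Compare full and reduced disposition models arm by arm
#'
#' Runs the same arms under the whole-body and the single-compartment
#' (high-throughput) disposition models with identical parameter derivation
#' and pairs the predictions, so that differences isolate the disposition
#' model. Summarizes concordance per parameter with Spearman rank
#' correlation and the AAFE between the two model variants.
#'
#' @inheritParams run_evaluation
#' @param method single clearance-derivation method (default
#'   `"back_calculated"`).
#' @return List with `paired` (wide table of predictions under both models)
#'   and `summary` (per-parameter `spearman_rho` and `aafe`).
#' @export
compare_full_vs_reduced <- function(compounds, arms,
                                    method = "back_calculated",
                                    config = run_config(methods = method,
                                                        model = "both"),
                                    phys = rat_physiology(),
                                    gut = rat_gut()) {
  config$methods <- method
  config$model <- "both"
  rep <- run_evaluation(compounds, arms, config, phys, gut)
  p <- rep$predictions
  wide <- merge(
    p[p$model == "full", c("compound_id", "arm_id", "parameter",
                           "predicted")],
    p[p$model == "reduced", c("compound_id", "arm_id", "parameter",
                              "predicted")],
    by = c("compound_id", "arm_id", "parameter"),
    suffixes = c("_full", "_reduced"))
  summ <- do.call(rbind, lapply(split(wide, wide$parameter), function(d) {
    ok <- is.finite(d$predicted_full) & is.finite(d$predicted_reduced) &
      d$predicted_full > 0 & d$predicted_reduced > 0
    d <- d[ok, ]
    if (nrow(d) < 3) return(NULL)
    data.frame(parameter = d$parameter[1], n = nrow(d),
               spearman_rho = stats::cor(d$predicted_full,
                                         d$predicted_reduced,
                                         method = "spearman"),
               aafe = 10^mean(abs(log10(d$predicted_full /
                                          d$predicted_reduced))))
  }))
  list(paired = wide, summary = summ, report = rep)
}
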