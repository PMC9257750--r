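#' Noncompartmental analysis of a concentration-time profile
#'
#' Computes the standard NCA parameter set from a plasma profile: AUC by the
#' linear-up/log-down trapezoid, terminal slope `lambda_z` by log-linear
#' regression over the terminal window with the best adjusted R-squared
#' (window sizes of at least 3 points), `AUCinf = AUClast + Clast/lambda_z`,
#' and for the IV route `CL = Dose / AUCinf` and `Vss = CL * MRT` with
#' `MRT = AUMCinf / AUCinf`. When no negative terminal slope is identifiable
#' the extrapolation is omitted with a warning and flag, leaving `aucinf`,
#' `cl` and `vss` as `NA`.
#'
#' @param x either a `simulation_result` (its venous plasma profile is used,
#'   along with its dose and route) or a numeric vector of times in hours.
#' @param conc concentrations, ng/mL (when `x` is a time vector).
#' @param dose dose, mg/kg (when `x` is a time vector).
#' @param route `"IV"` or `"PO"` (when `x` is a time vector).
#' @param max_terminal_points largest terminal window considered
#'   (default 30).
#' @param lloq_frac concentrations below this fraction of Cmax are treated
#'   as below the limit of quantification and set to zero before analysis
#'   (default 1e-8; protects the terminal fit from numerical round-off in
#'   simulated profiles, and mirrors assay LLOQ handling for sampled data).
#' @return An object of class `pk_parameters`: list with `cl` (mL/min/kg),
#'   `vss` (L/kg), `aucinf` and `auclast` (ng.h/mL), `cmax` (ng/mL), `tmax`
#'   (h), `lambda_z` (1/h), `mrt` (h), `route`, `dose`, `flags`.
#' @examples
#' t <- seq(0, 24, by = 0.25)
#' conc <- 1000 * exp(-0.3 * t)
#' nca(t, conc = conc, dose = 1, route = "IV")
#' @export
nca <- function(x, conc = NULL, dose = NULL, route = NULL,
                max_terminal_points = 30, lloq_frac = 1e-8) {
  if (inherits(x, "simulation_result")) {
    time <- x$time; conc <- x$plasma; dose <- x$dose; route <- x$route
  } else {
    time <- x
    stopifnot(!is.null(conc), !is.null(dose), !is.null(route))
  }
  stopifnot(length(time) == length(conc), dose > 0)
  ok <- is.finite(time) & is.finite(conc)
  time <- time[ok]; conc <- conc[ok]
  o <- order(time)
  time <- time[o]; conc <- conc[o]
  conc[conc < max(conc) * lloq_frac] <- 0
  npos <- sum(conc > 0)
  if (npos < 3)
    stop("NCA requires at least 3 positive concentrations (got ", npos, ")")

  # truncate trailing zeros (post-last-quantifiable)
  last_pos <- max(which(conc > 0))
  time <- time[seq_len(last_pos)]; conc <- conc[seq_len(last_pos)]
  n <- length(time)

  auc <- aumc <- 0
  for (i in seq_len(n - 1)) {
    dt <- time[i + 1] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1]
    if (c2 < c1 && c2 > 0) {                       # log-down
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (time[i] * c1 - time[i + 1] * c2) / k + (c1 - c2) / k^2
    } else {                                       # linear
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (time[i] * c1 + time[i + 1] * c2) / 2
    }
  }

  lz <- estimate_lambda_z(time, conc, max_terminal_points)
  flags <- character(0)
  if (is.na(lz)) {
    flags <- "no_terminal_phase"
    warning("terminal slope not identifiable; AUC extrapolation omitted")
    aucinf <- NA_real_; aumcinf <- NA_real_
  } else {
    clast <- conc[n]; tlast <- time[n]
    aucinf <- auc + clast / lz
    aumcinf <- aumc + clast * tlast / lz + clast / lz^2
  }

  cl <- vss <- mrt <- NA_real_
  if (route == "IV" && is.finite(aucinf)) {
    cl <- dose * 1e6 / aucinf / 60          # mL/min/kg
    mrt <- aumcinf / aucinf                 # h
    vss <- cl * mrt * 60 / 1000             # L/kg
  }
  structure(list(cl = cl, vss = vss, aucinf = aucinf, auclast = auc,
                 cmax = max(conc), tmax = time[which.max(conc)],
                 lambda_z = lz, mrt = mrt, route = route, dose = dose,
                 flags = flags),
            class = "pk_parameters")
}

# best-adjusted-R^2 log-linear terminal fit over windows of >= 3 points;
# fits explaining less than adj_r2_min of the log-variance are rejected so
# that numerically flat (non-eliminating) tails are flagged rather than
# extrapolated from round-off noise
estimate_lambda_z <- function(time, conc, max_points = 30,
                              adj_r2_min = 0.8) {
  pos <- which(conc > 0)
  if (length(pos) < 3) return(NA_real_)
  time <- time[pos]; lc <- log(conc[pos])
  n <- length(time)
  best <- NA_real_; best_r2 <- -Inf
  for (k in 3:min(max_points, n)) {
    idx <- (n - k + 1):n
    tt <- time[idx]; yy <- lc[idx]
    sxx <- sum((tt - mean(tt))^2)
    if (sxx == 0) next
    slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    if (slope >= 0) next
    # require a meaningful decline (>= 5%) across the window, so that
    # numerically flat non-eliminating tails are not extrapolated
    if (yy[1] - yy[k] < 0.05) next
    fit <- mean(yy) + slope * (tt - mean(tt))
    sse <- sum((yy - fit)^2)
    sst <- sum((yy - mean(yy))^2)
    if (sst == 0) next
    adj_r2 <- 1 - (sse / (k - 2)) / (sst / (k - 1))
    if (adj_r2 < adj_r2_min) next
    if (adj_r2 > best_r2 + 1e-12) { best_r2 <- adj_r2; best <- -slope }
  }
  if (is.finite(best) && best > 0) best else NA_real_
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>", x$route, sprintf("dose %.3g mg/kg\n", x$dose))
  cat(sprintf("  AUCinf %.4g ng.h/mL, Cmax %.4g ng/mL", x$aucinf, x$cmax))
  if (is.finite(x$cl)) cat(sprintf(", CL %.3g mL/min/kg, Vss %.3g L/kg",
                                   x$cl, x$vss))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
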