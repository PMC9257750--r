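# Linear ODE machinery for the disposition and absorption models.
#
# Every model in this package is a linear system x' = A x except for
# suspension dissolution. Linear systems are solved exactly by
# eigendecomposition (with a Matrix::expm stepping fallback when the
# eigenvector basis is ill-conditioned); the dissolution nonlinearity is
# handled by a Strang-type splitting in the ACAT stepper (see acat.R).
# Because every column of A sums to zero (amounts move between states,
# cumulative sinks included), both routes conserve mass to machine precision.

# Solve x' = A x, x(0) = x0, at the requested times. Returns a
# length(times) x n matrix of states.
solve_linear_ode <- function(A, x0, times) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, length(x0) == n)
  eg <- try(eigen(A), silent = TRUE)
  use_eigen <- FALSE
  if (!inherits(eg, "try-error")) {
    sv <- try(svd(eg$vectors, nu = 0, nv = 0)$d, silent = TRUE)
    if (!inherits(sv, "try-error") && min(sv) > 0 &&
        max(sv) / min(sv) < 1e10)
      use_eigen <- TRUE
  }
  if (use_eigen) {
    c0 <- solve(eg$vectors, as.complex(x0))
    E <- exp(outer(eg$values, times))   # n x m
    X <- eg$vectors %*% (c0 * E)
    t(Re(X))
  } else {
    # scaling-and-squaring stepping; exact for each interval
    out <- matrix(0, length(times), n)
    ord <- order(times)
    ts <- times[ord]
    x <- x0
    tprev <- 0
    for (i in seq_along(ts)) {
      dt <- ts[i] - tprev
      if (dt > 0) {
        P <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
        x <- as.numeric(P %*% x)
        tprev <- ts[i]
      }
      out[ord[i], ] <- x
    }
    out
  }
}

# Build the linear disposition matrix over the given physiology.
#
# States: ven, art, one per tissue row, amet (cumulative metabolized).
# Whole-blood pools; tissue outflow at C_t * BP / Kp_t; gut and spleen drain
# into the liver when a liver is present; hepatic elimination at
# fup * CLint_u_wb * C_liver / Kp_liver (unbound plasma basis). Units:
# amounts mg/kg, volumes mL/kg, flows mL/min/kg; time in minutes.
build_disposition_matrix <- function(phys, kps, bp, fup, clint_u_wb) {
  tt <- phys$tissues
  tn <- tt$tissue
  has_lung <- "lung" %in% tn
  has_liver <- "liver" %in% tn
  if (!has_liver && clint_u_wb > 0)
    stop("hepatic elimination requested but physiology has no liver")
  missing_kp <- setdiff(tn, names(kps))
  if (length(missing_kp))
    stop("Kp missing for tissue(s): ", paste(missing_kp, collapse = ", "))

  states <- c("ven", "art", tn, "amet")
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  ix <- function(s) match(s, states)
  co <- phys$co
  iven <- ix("ven"); iart <- ix("art")

  # venous -> lung -> arterial (or venous -> arterial directly)
  if (has_lung) {
    il <- ix("lung")
    k_out <- bp / (kps[["lung"]] * tt$v[tn == "lung"])
    A[il, iven] <- A[il, iven] + co / phys$v_ven
    A[iven, iven] <- A[iven, iven] - co / phys$v_ven
    A[il, il] <- A[il, il] - co * k_out
    A[iart, il] <- A[iart, il] + co * k_out
  } else {
    A[iart, iven] <- A[iart, iven] + co / phys$v_ven
    A[iven, iven] <- A[iven, iven] - co / phys$v_ven
  }

  portal <- intersect(c("gut", "spleen"), tn)
  liver_q_extra <- 0
  for (i in seq_len(nrow(tt))) {
    t_name <- tn[i]
    if (t_name == "lung") next
    it <- ix(t_name)
    q <- tt$q[i]
    k_out <- q * bp / (kps[[t_name]] * tt$v[i])
    A[it, iart] <- A[it, iart] + q / phys$v_art
    A[iart, iart] <- A[iart, iart] - q / phys$v_art
    A[it, it] <- A[it, it] - k_out
    dest <- if (has_liver && t_name %in% portal) ix("liver") else iven
    if (has_liver && t_name == "liver") dest <- NA  # handled below
    if (!is.na(dest)) A[dest, it] <- A[dest, it] + k_out
    if (has_liver && t_name %in% portal) liver_q_extra <- liver_q_extra + q
  }

  if (has_liver) {
    i <- which(tn == "liver")
    il <- ix("liver")
    q_out <- tt$q[i] + liver_q_extra          # artery + portal inflow
    k_out <- q_out * bp / (kps[["liver"]] * tt$v[i])
    # replace the perfusion outflow added above (which used only q_artery)
    A[il, il] <- -k_out
    A[iven, il] <- A[iven, il] + k_out
    k_met <- fup * clint_u_wb / (kps[["liver"]] * tt$v[i])
    A[il, il] <- A[il, il] - k_met
    A[ix("amet"), il] <- A[ix("amet"), il] + k_met
  }

  if (max(abs(colSums(A))) > 1e-9 * max(abs(A)))
    stop("internal error: disposition matrix does not conserve mass")
  A
}

# Default output grid in hours: dense log-spaced sampling over the
# 48 h study window (plus t = 0). Starts at 6 s so the initial venous
# mixing transient after an IV bolus is resolved by the trapezoid.
default_time_grid <- function(t_end_h = 48, n = 240) {
  c(0, 10^seq(log10(1 / 600), log10(t_end_h), length.out = n))
}

# Simulation horizon (h) long enough to resolve the terminal phase:
# ~6 elimination half-lives, floored at the 48 h study window and capped at
# two weeks. Predictions report asymptotic AUCinf, so their NCA should not
# be truncation-biased even for slow compounds.
pk_horizon <- function(cl_plasma, vss_lkg, t_min = 48, t_max = 336) {
  if (!is.finite(cl_plasma) || cl_plasma <= 0 || !is.finite(vss_lkg))
    return(t_min)
  t_half <- log(2) * vss_lkg * 1000 / cl_plasma / 60
  min(t_max, max(t_min, 6 * t_half))
}

new_simulation_result <- function(time_h, amounts, phys, kps, bp, route,
                                  dose, flags = character(0),
                                  extra = list()) {
  states <- colnames(amounts)
  tt <- phys$tissues
  conc <- matrix(0, nrow(amounts), 0)
  vols <- c(ven = phys$v_ven, art = phys$v_art,
            stats::setNames(tt$v, tt$tissue))
  keep <- intersect(states, names(vols))
  conc <- sweep(amounts[, keep, drop = FALSE], 2, vols[keep], "/") * 1e6
  plasma <- pmax(0, amounts[, "ven"] / (phys$v_ven * bp) * 1e6)
  res <- c(list(time = time_h, plasma = plasma, conc = pmax(conc, 0),
                amounts = amounts, route = route, dose = dose,
                cumulative = list(
                  metabolized = amounts[, "amet"],
                  absorbed = if ("aabs" %in% states) amounts[, "aabs"],
                  gut_excreted = if ("aexcr" %in% states)
                    amounts[, "aexcr"]),
                flags = flags),
           extra)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$route, sprintf("dose %.3g mg/kg,", x$dose),
      length(x$time), "time points to", max(x$time), "h\n")
  cat(sprintf("  Cmax (venous plasma) %.4g ng/mL", max(x$plasma)))
  if (!is.null(x$foral)) cat(sprintf(", Fabs %.3f, Foral %.3f",
                                     x$fabs, x$foral))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy concentration table from a simulation
#'
#' @param x a `simulation_result`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `time` (h), `compartment`,
#'   `concentration` (ng/mL; venous plasma reported as `plasma`).
#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  comps <- c("plasma", colnames(x$conc))
  vals <- cbind(plasma = x$plasma, x$conc)
  data.frame(
    time = rep(x$time, times = ncol(vals)),
    compartment = rep(comps, each = length(x$time)),
    concentration = as.numeric(vals),
    stringsAsFactors = FALSE
  )
}
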