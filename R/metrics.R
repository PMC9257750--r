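#' Prediction-success metric panel
#'
#' The standard panel used to judge PK parameter predictions against
#' observations, computed on paired positive values:
#' \describe{
#'   \item{pct_2fe / pct_3fe / pct_10fe}{percentage of predictions within
#'     2-, 3-, 10-fold of observed, boundary inclusive
#'     (`max(p/o, o/p) <= x`).}
#'   \item{afe}{average fold error `10^mean(log10(p/o))` -- geometric bias;
#'     below 1 indicates underprediction.}
#'   \item{aafe}{absolute average fold error `10^mean(|log10(p/o)|)` --
#'     geometric precision, always >= max(afe, 1/afe).}
#'   \item{rmsle}{root-mean-square log10 error.}
#'   \item{ccc_log, ccc_lin}{Lin's concordance correlation coefficient on
#'     log10 and on linear values.}
#'   \item{spearman_rho}{Spearman rank correlation.}
#'   \item{r2_linear, r2_log}{squared Pearson correlation on linear and
#'     log10 values.}
#' }
#' Pairs with a nonpositive or missing member are excluded (count reported
#' in `n_excluded` and messaged).
#'
#' @param pred,obs equal-length numeric vectors of predicted and observed
#'   values (positive values are used).
#' @param folds fold levels for the within-x-fold percentages
#'   (default `c(2, 3, 10)`).
#' @return An object of class `metric_panel` (a one-row data.frame with the
#'   fields above plus `n`, `n_excluded`).
#' @examples
#' fold_error_panel(c(10, 1), c(1, 10))   # AFE 1, AAFE 10
#' @export
fold_error_panel <- function(pred, obs, folds = c(2, 3, 10)) {
  stopifnot(length(pred) == length(obs), all(folds > 0))
  ok <- is.finite(pred) & is.finite(obs) & pred > 0 & obs > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " pair(s) excluded (nonpositive or missing)")
  p <- pred[ok]; o <- obs[ok]
  if (length(p) < 2)
    stop("fold_error_panel needs at least 2 valid pairs")
  le <- log10(p / o)
  pct <- vapply(folds, function(x) 100 * mean(pmax(p / o, o / p) <= x),
                numeric(1))
  names(pct) <- paste0("pct_", folds, "fe")
  out <- data.frame(
    n = length(p), n_excluded = n_excluded,
    t(pct),
    afe = 10^mean(le),
    aafe = 10^mean(abs(le)),
    rmsle = sqrt(mean(le^2)),
    ccc_log = lin_ccc(log10(p), log10(o)),
    ccc_lin = lin_ccc(p, o),
    spearman_rho = safe_cor(p, o, method = "spearman"),
    r2_linear = safe_cor(p, o)^2,
    r2_log = safe_cor(log10(p), log10(o))^2
  )
  class(out) <- c("metric_panel", "data.frame")
  out
}

# correlation that returns NA (no warning) on zero-variance input
safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

# Lin's concordance correlation coefficient (population moments)
lin_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' @export
print.metric_panel <- function(x, ...) {
  cat("Prediction-success panel (n =", x$n, ")\n")
  fmt <- function(v) formatC(v, digits = 3, format = "g")
  cat("  %2fe ", fmt(x$pct_2fe), "  %3fe ", fmt(x$pct_3fe),
      "  %10fe ", fmt(x$pct_10fe), "\n", sep = "")
  cat("  AFE ", fmt(x$afe), "  AAFE ", fmt(x$aafe),
      "  RMSLE ", fmt(x$rmsle), "\n", sep = "")
  cat("  CCC(log) ", fmt(x$ccc_log), "  rho ", fmt(x$spearman_rho),
      "  R2 ", fmt(x$r2_linear), "  R2(log) ", fmt(x$r2_log), "\n", sep = "")
  invisible(x)
}
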