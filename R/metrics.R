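#' Correlation-type goodness statistic (R)
#'
#' `R = sqrt(max(0, 1 - SSE/SST))` with `SSE = sum (y_i - yhat_i)^2` and
#' `SST = sum (y_i - mean(y))^2`. This is the square-root convention
#' (R, not R-squared) used for both cross-validation (R_CV) and
#' prediction (R_P) statistics; it equals the Pearson correlation only
#' for an unbiased fit.
#'
#' @param y_true Measured values (positive variance required, `n >= 2`).
#' @param y_pred Predicted values.
#' @return R in `[0, 1]`.
#' @export
compute_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0) stop("y_true has zero variance")
  sqrt(max(0, 1 - sum((y_true - y_pred)^2) / sst))
}

#' Root-mean-squared error
#'
#' @inheritParams compute_r
#' @return RMSE in the units of `y` (degrees Brix).
#' @export
compute_rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

rpd_band <- function(rpd) {
  if (rpd < 1.5) "insufficient"
  else if (rpd < 2) "rough"
  else if (rpd < 2.5) "reliable"
  else if (rpd <= 3) "good"
  else "excellent"
}

#' Residual predictive deviation (RPD)
#'
#' `RPD = SD / RMSEP`, where SD is the standard deviation (n-1
#' denominator) of the measured prediction-set values. Interpretation
#' bands: 1.5-2 rough quantitative prediction, 2-2.5 reliable, above 3
#' excellent.
#'
#' @param sd_pred_set Prediction-set SD (degrees Brix), or alternatively
#'   the vector of measured prediction-set values.
#' @param rmsep Prediction RMSE (> 0).
#' @return RPD with attribute `quality_band`.
#' @export
compute_rpd <- function(sd_pred_set, rmsep) {
  if (length(sd_pred_set) > 1) sd_pred_set <- stats::sd(sd_pred_set)
  if (rmsep < 0) stop("rmsep must be nonnegative")
  if (rmsep == 0) {
    warning("rmsep is zero; RPD reported as Inf")
    return(structure(Inf, quality_band = "excellent"))
  }
  rpd <- sd_pred_set / rmsep
  structure(rpd, quality_band = rpd_band(rpd))
}

#' Ratio of error range (RER)
#'
#' `RER = P_r / RMSEP`, with `P_r` the range (max minus min) of the
#' measured prediction-set values. RER above 10 indicates excellent
#' prediction accuracy.
#'
#' @param range_pred_set Prediction-set range `P_r` (degrees Brix), or
#'   the vector of measured prediction-set values.
#' @param rmsep Prediction RMSE (> 0).
#' @return RER with attribute `quality_band` (`"excellent"` above 10).
#' @export
compute_rer <- function(range_pred_set, rmsep) {
  if (length(range_pred_set) > 1)
    range_pred_set <- diff(range(range_pred_set))
  if (rmsep < 0) stop("rmsep must be nonnegative")
  if (rmsep == 0) {
    warning("rmsep is zero; RER reported as Inf")
    return(structure(Inf, quality_band = "excellent"))
  }
  rer <- range_pred_set / rmsep
  structure(rer, quality_band = if (rer > 10) "excellent" else "limited")
}

#' Pool subset RMSEPs into a whole-set RMSEP
#'
#' The RMSEP of a union of disjoint subsets is the size-weighted root
#' mean of the squared subset RMSEPs:
#' `sqrt(sum n_k rmsep_k^2 / sum n_k)`. Used to combine the noisy and
#' non-noisy prediction subsets of the noise-injection experiment into
#' the whole-set error.
#'
#' @param subset_rmseps List of `c(rmsep, n)` pairs, or a 2-column
#'   matrix/data.frame with columns rmsep and n.
#' @return Pooled RMSEP (degrees Brix).
#' @export
pooled_rmsep <- function(subset_rmseps) {
  if (is.data.frame(subset_rmseps) || is.matrix(subset_rmseps)) {
    m <- as.matrix(subset_rmseps)
  } else {
    if (length(subset_rmseps) == 0) stop("empty subset list")
    m <- do.call(rbind, lapply(subset_rmseps, function(p) as.numeric(p[1:2])))
  }
  if (nrow(m) == 0) stop("empty subset list")
  if (any(m[, 2] < 1)) stop("subset sizes must be >= 1")
  sqrt(sum(m[, 2] * m[, 1]^2) / sum(m[, 2]))
}

#' Evaluate a fitted model on a prediction set
#'
#' Builds the standard report: R_P and RMSEP on the prediction set,
#' RPD and RER from the measured prediction-set spread, plus the
#' cross-validation statistics when a `cv_result` is supplied. The
#' Pearson correlation is reported alongside the square-root-convention
#' R for transparency.
#'
#' @param model A `calibration_model`.
#' @param X_pred Prediction-set spectra (matrix or `spectra_set`).
#' @param y_pred Measured prediction-set SSC values.
#' @param cv Optional `cv_result` from the calibration set.
#' @param n_cal Calibration-set size (reported only).
#' @return An object of class `eval_report`.
#' @export
evaluate_model <- function(model, X_pred, y_pred, cv = NULL, n_cal = NA_integer_) {
  if (inherits(X_pred, "spectra_set") && missing(y_pred)) y_pred <- X_pred$ssc
  yhat <- predict(model, X_pred)
  rmsep <- compute_rmse(y_pred, yhat)
  rpd <- compute_rpd(stats::sd(y_pred), rmsep)
  rer <- compute_rer(diff(range(y_pred)), rmsep)
  rep_ <- list(
    model = model$kind,
    lvs = model$n_factors,
    r_cv = if (!is.null(cv)) cv$r_cv_by_factor[model$n_factors] else NA_real_,
    rmsecv = if (!is.null(cv)) cv$rmsecv_by_factor[model$n_factors] else NA_real_,
    r_p = compute_r(y_pred, yhat),
    r_p_pearson = suppressWarnings(stats::cor(y_pred, yhat)),
    rmsep = rmsep,
    rpd = as.numeric(rpd),
    rer = as.numeric(rer),
    quality_band = attr(rpd, "quality_band"),
    n_cal = n_cal,
    n_pred = length(y_pred))
  class(rep_) <- "eval_report"
  rep_
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s] LVs=%d  R_CV=%.4f RMSECV=%.4f  R_P=%.4f RMSEP=%.4f  RPD=%.3f RER=%.3f (%s)\n",
              x$model, x$lvs, x$r_cv, x$rmsecv, x$r_p, x$rmsep,
              x$rpd, x$rer, x$quality_band))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(model = x$model, lvs = x$lvs, r_cv = x$r_cv,
             rmsecv = x$rmsecv, r_p = x$r_p, rmsep = x$rmsep,
             rpd = x$rpd, rer = x$rer, quality_band = x$quality_band,
             n_cal = x$n_cal, n_pred = x$n_pred,
             stringsAsFactors = FALSE)
}
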