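#' Add white Gaussian noise to selected spectra at a target SNR
#'
#' For each selected row the noise variance is `sigma^2 = P /
#' 10^(snr_db/10)` with `P` the mean squared value of that row (signal
#' power over all wavelengths), and i.i.d. zero-mean Gaussian noise of
#' that variance is added. Unselected rows are untouched.
#'
#' @param spectra A [spectra_set()] (or matrix).
#' @param indices Row indices to contaminate.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Seed for the noise draw.
#' @return Object of the same type as `spectra` with contaminated rows;
#'   for a `spectra_set` the attribute `wgn` records indices and snr.
#' @export
add_wgn <- function(spectra, indices, snr_db, seed = 1L) {
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  X <- as_spectra_matrix(spectra)
  indices <- as.integer(indices)
  if (length(indices) == 0) {
    warning("no indices supplied; spectra returned unchanged")
    return(spectra)
  }
  if (any(indices < 1 | indices > nrow(X))) stop("indices out of range")
  W <- ncol(X)
  noise <- withr::with_seed(seed, {
    t(vapply(indices, function(i) {
      p_sig <- mean(X[i, ]^2)
      stats::rnorm(W, 0, sqrt(p_sig / 10^(snr_db / 10)))
    }, numeric(W)))
  })
  X[indices, ] <- X[indices, ] + noise
  if (inherits(spectra, "spectra_set")) {
    out <- spectra_set(spectra$wavelengths, X, sample_ids = spectra$sample_ids,
                       ssc = spectra$ssc, mode = spectra$mode)
    attr(out, "wgn") <- list(indices = indices, snr_db = snr_db, seed = seed)
    out
  } else X
}

default_model_specs <- function(A = NULL, eta = 0.5) {
  list(plsr = list(kind = "plsr", A = A),
       splsr = list(kind = "splsr", A = A, eta = eta),
       sprmr = list(kind = "sprmr", A = A, eta = eta))
}

# weighted calibration-set correlation: the Fig-5-style sweep statistic.
# For robust fits the case weights discount samples the model has
# flagged as abnormal, so the statistic reflects the fit to the samples
# the model actually trusts.
weighted_cal_r <- function(y, yhat, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  ym <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ym)^2)
  if (sst <= 0) return(NA_real_)
  sqrt(max(0, 1 - sum(w * (y - yhat)^2) / sst))
}

fit_spec <- function(spec, X, y) {
  switch(spec$kind,
    plsr = fit_plsr(X, y, spec$A),
    splsr = fit_splsr(X, y, spec$A, eta = spec$eta %||% 0.5),
    sprmr = suppressWarnings(
      fit_sprmr(X, y, spec$A, eta = spec$eta %||% 0.5,
                c_tune = spec$c_tune %||% 4)),
    stop("unknown model kind '", spec$kind, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the white-Gaussian-noise reliability experiment
#'
#' The validity test for robust calibration: `n_noisy` samples are drawn
#' (seeded) from the calibration set and `n_noisy` from the prediction
#' set; both are contaminated with WGN at each SNR level; every model
#' spec is retrained on the contaminated calibration set and evaluated
#' on the contaminated prediction set, reporting the RMSEP over the
#' contaminated prediction samples (`rmsep_noisy`), over the remainder
#' (`rmsep_clean`), and over the whole set (`rmsep_whole`, which equals
#' the size-weighted pooling of the two subsets by construction), plus
#' R_P for the SNR sweep. Contaminated index sets are drawn once and
#' held fixed across SNR levels so the sweep is comparable.
#'
#' @param spectra A [spectra_set()] with `ssc`.
#' @param split A [partition_samples()] result.
#' @param model_specs Named list of model specs, each a list with
#'   `kind` (`"plsr"`, `"splsr"`, `"sprmr"`), `A` and optionally `eta`.
#'   When `A` is `NULL` (the default) the factor count is chosen per
#'   contamination level by 10-fold CV with the F-test rule — ordinary
#'   CV for plsr/splsr, trimmed CV (`trim = 0.1`) for sprmr, pairing
#'   the robust estimator with a robust selection criterion.
#' @param snr_levels SNR levels in dB.
#' @param n_noisy Number of contaminated samples per set (`N`).
#' @param A_max Largest factor count scanned when `A` is chosen by CV.
#' @param seed Master seed (index draws and noise).
#' @return An object of class `noise_experiment`: `results` data.frame
#'   (model, snr_db, lvs, rmsep_noisy, rmsep_clean, rmsep_whole, r_p,
#'   r_cal — the weighted calibration correlation used for the
#'   R-vs-SNR sweep — and failed), `noisy_cal_indices`,
#'   `noisy_pred_indices`, per-SNR SPRMR `weight_reports`, `seed`.
#' @export
run_noise_experiment <- function(spectra, split,
                                 model_specs = default_model_specs(),
                                 snr_levels = c(-10, 10, 50),
                                 n_noisy = 10, A_max = 10, seed = 1L) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(split, "calibration_split"))
  if (is.null(spectra$ssc)) stop("spectra must carry ssc reference values")
  cal <- split$calibration; pred <- split$prediction
  if (n_noisy > min(length(cal), length(pred)))
    stop("n_noisy exceeds the size of a set")
  idx <- withr::with_seed(seed, list(
    cal = sort(sample(cal, n_noisy)),
    pred = sort(sample(pred, n_noisy))))
  y <- spectra$ssc
  rows <- list()
  weight_reports <- list()
  for (li in seq_along(snr_levels)) {
    snr <- snr_levels[li]
    contaminated <- if (n_noisy > 0)
      add_wgn(spectra, c(idx$cal, idx$pred), snr, seed = seed + li)
    else spectra
    Xc <- contaminated$reflectance
    for (mn in names(model_specs)) {
      res <- tryCatch({
        spec <- model_specs[[mn]]
        if (is.null(spec$A)) {
          cv <- suppressWarnings(cross_validate(
            Xc[cal, , drop = FALSE], y[cal], kind = spec$kind,
            A_max = A_max, eta = spec$eta %||% 0,
            scheme = "kfold", k = 10,
            trim = if (spec$kind == "sprmr") 0.1 else 0,
            seed = seed))
          spec$A <- select_factors(cv)
        }
        m <- fit_spec(spec, Xc[cal, , drop = FALSE], y[cal])
        yhat <- predict(m, Xc[pred, , drop = FALSE])
        noisy_pos <- match(idx$pred, pred)
        clean_pos <- setdiff(seq_along(pred), noisy_pos)
        rn <- if (length(noisy_pos)) compute_rmse(y[pred][noisy_pos], yhat[noisy_pos]) else NA_real_
        rc <- compute_rmse(y[pred][clean_pos], yhat[clean_pos])
        rw <- compute_rmse(y[pred], yhat)
        if (m$kind == "sprmr")
          weight_reports[[paste(mn, snr, sep = "@")]] <-
            case_weight_report(m, match(idx$cal, cal))
        r_cal <- weighted_cal_r(y[cal], predict(m, Xc[cal, , drop = FALSE]),
                                m$case_weights)
        data.frame(model = mn, snr_db = snr, lvs = m$n_factors,
                   rmsep_noisy = rn, rmsep_clean = rc, rmsep_whole = rw,
                   r_p = compute_r(y[pred], yhat), r_cal = r_cal,
                   failed = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("model '%s' failed at SNR %g dB: %s", mn, snr,
                        conditionMessage(e)))
        data.frame(model = mn, snr_db = snr, lvs = NA_integer_,
                   rmsep_noisy = NA_real_, rmsep_clean = NA_real_,
                   rmsep_whole = NA_real_, r_p = NA_real_,
                   r_cal = NA_real_, failed = TRUE, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  structure(list(results = do.call(rbind, rows),
                 snr_levels = snr_levels, n_noisy = as.integer(n_noisy),
                 noisy_cal_indices = idx$cal, noisy_pred_indices = idx$pred,
                 weight_reports = weight_reports, seed = as.integer(seed)),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat(sprintf("noise_experiment: N = %d noisy per set, SNR levels %s dB\n",
              x$n_noisy, paste(x$snr_levels, collapse = ", ")))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Summarise SPRMR case weights on contaminated calibration samples
#'
#' Reports the median converged case weight of contaminated vs clean
#' calibration samples and the separation AUC — the probability that a
#' randomly chosen clean sample receives a larger weight than a
#' randomly chosen contaminated one (weights as a classifier of
#' contamination; 0.5 means no separation).
#'
#' @param model A fitted SPRMR `calibration_model`.
#' @param noisy_cal_indices Positions (within the calibration set) of
#'   the contaminated samples.
#' @return List with `median_weight_noisy`, `median_weight_clean`,
#'   `auc`, `n_noisy`, `n_clean`.
#' @export
case_weight_report <- function(model, noisy_cal_indices) {
  if (!inherits(model, "calibration_model") || model$kind != "sprmr")
    stop("case_weight_report requires an SPRMR model")
  w <- model$case_weights
  noisy_cal_indices <- as.integer(noisy_cal_indices)
  clean <- setdiff(seq_along(w), noisy_cal_indices)
  wn <- w[noisy_cal_indices]; wc <- w[clean]
  auc <- if (length(wn) && length(wc)) {
    r <- rank(c(wc, wn))
    (sum(r[seq_along(wc)]) - length(wc) * (length(wc) + 1) / 2) /
      (length(wc) * length(wn))
  } else NA_real_
  list(median_weight_noisy = if (length(wn)) stats::median(wn) else NA_real_,
       median_weight_clean = stats::median(wc),
       auc = auc,
       n_noisy = length(wn), n_clean = length(wc))
}
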