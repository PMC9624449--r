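#' Monte-Carlo uninformative variable elimination (MCUVE)
#'
#' Ranks wavelengths by the stability of their PLS regression
#' coefficients under Monte-Carlo resampling: over `M` seeded draws of
#' `ceiling(r * n)` calibration samples a PLSR with `A` factors is
#' fitted and its coefficient vector recorded; the stability of variable
#' `j` is `s_j = mean_m(b_j) / sd_m(b_j)`. Variables are ranked by
#' `|s_j|` (descending). Informative-subset selection is either
#' `"cv"` (default): for each candidate size `k` in `k_grid` a PLSR on
#' the top-`k` variables is cross-validated and the `k` minimising
#' RMSECV wins (ties to smaller `k`); or `"threshold"`: retain variables
#' with `|s_j|` above the `threshold_quantile` of all `|s_j|`.
#'
#' @param X `n x W` calibration spectra (matrix or `spectra_set`).
#' @param y Calibration SSC values.
#' @param A PLS factor count used in the resampled fits (typically the
#'   full-model CV choice).
#' @param M Number of Monte-Carlo runs (`>= 50`).
#' @param r Sampling ratio in `[0.5, 1)`.
#' @param k_grid Candidate subset sizes for `"cv"` selection; default 50
#'   log-spaced values in `[10, W]`.
#' @param select `"cv"` or `"threshold"`.
#' @param threshold_quantile Quantile cutoff on `|s_j|` for
#'   `"threshold"` selection.
#' @param cv_folds Folds of the inner RMSECV loop.
#' @param seed Master seed for the resampling and the inner CV folds.
#' @return An object of class `mcuve_result`: `stability`, `ranking`,
#'   `selected_mask`, `rmsecv_curve` (data.frame k/rmsecv, `"cv"` mode),
#'   `n_runs`, `sampling_ratio`, `seed`.
#' @export
mcuve_select <- function(X, y, A, M = 500, r = 0.8, k_grid = NULL,
                         select = c("cv", "threshold"),
                         threshold_quantile = 0.75, cv_folds = 10,
                         seed = 1L) {
  select <- match.arg(select)
  d <- prepare_xy(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X); W <- ncol(X)
  if (M < 50) stop("M must be at least 50")
  if (r < 0.5 || r >= 1) stop("sampling ratio r must lie in [0.5, 1)")
  n_sub <- ceiling(r * n)
  B <- withr::with_seed(seed, {
    vapply(seq_len(M), function(m) {
      idx <- sample.int(n, n_sub)
      fit_plsr(X[idx, , drop = FALSE], y[idx], A)$coefficients
    }, numeric(W))
  })
  mu <- rowMeans(B)
  sdv <- apply(B, 1, stats::sd)
  s <- mu / sdv
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " variable(s) with zero coefficient spread; stability set to +/-Inf")
    s[sdv == 0] <- sign(mu[sdv == 0]) * Inf
    s[sdv == 0 & mu == 0] <- Inf
  }
  ranking <- order(abs(s), decreasing = TRUE)

  rmsecv_curve <- NULL
  if (select == "threshold") {
    cut <- stats::quantile(abs(s[is.finite(s)]), threshold_quantile)
    mask <- abs(s) >= cut
  } else {
    if (is.null(k_grid)) {
      k_grid <- unique(round(exp(seq(log(min(10, W)), log(W), length.out = 50))))
    }
    k_grid <- sort(unique(pmin(pmax(as.integer(k_grid), 1L), W)))
    folds <- withr::with_seed(seed + 1L, {
      k <- min(cv_folds, n)
      split(sample.int(n), rep_len(seq_len(k), n))
    })
    rmsecv <- vapply(k_grid, function(k) {
      vars <- ranking[seq_len(k)]
      Ak <- min(A, k)
      pred <- numeric(n)
      for (f in folds) {
        m <- fit_plsr(X[-f, vars, drop = FALSE], y[-f], Ak)
        pred[f] <- predict(m, X[f, vars, drop = FALSE])
      }
      compute_rmse(y, pred)
    }, numeric(1))
    rmsecv_curve <- data.frame(k = k_grid, rmsecv = rmsecv)
    k_best <- k_grid[which.min(rmsecv)]  # which.min takes the first = smallest k on ties
    mask <- logical(W)
    mask[ranking[seq_len(k_best)]] <- TRUE
  }
  structure(list(stability = s, ranking = ranking, selected_mask = mask,
                 rmsecv_curve = rmsecv_curve, n_runs = as.integer(M),
                 sampling_ratio = r, n_factors = as.integer(A),
                 seed = as.integer(seed)),
            class = "mcuve_result")
}

#' @export
print.mcuve_result <- function(x, ...) {
  cat(sprintf("mcuve_result: %d/%d variables selected (M = %d, r = %.2f, A = %d)\n",
              sum(x$selected_mask), length(x$selected_mask),
              x$n_runs, x$sampling_ratio, x$n_factors))
  invisible(x)
}

#' Plot MCUVE stability against wavelength
#'
#' @param x An `mcuve_result`.
#' @param wavelengths Optional wavelength grid for the x axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mcuve_result <- function(x, wavelengths = NULL, ...) {
  s <- x$stability
  s[!is.finite(s)] <- max(abs(s[is.finite(s)])) * sign(s[!is.finite(s)])
  wl <- if (is.null(wavelengths)) seq_along(s) else wavelengths
  graphics::plot(wl, s, type = "h",
                 col = ifelse(x$selected_mask, "firebrick", "grey60"),
                 xlab = if (is.null(wavelengths)) "variable index" else "wavelength (nm)",
                 ylab = "stability s_j", ...)
  invisible(x)
}
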