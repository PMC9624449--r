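#' Savitzky-Golay smoothing
#'
#' Row-wise least-squares polynomial smoothing. Filter coefficients are
#' taken from [signal::sgolay()]; edges are handled by symmetric
#' reflection padding so output length equals input length. Rows that are
#' exact polynomials of degree `<= polyorder` are reproduced exactly at
#' interior points.
#'
#' @param X `N x W` matrix (or `spectra_set`) of spectra, one row per
#'   sample.
#' @param window Odd filter length, `3 <= window <= W`.
#' @param polyorder Polynomial order, `< window`.
#' @return Matrix of the same dimension as `X`.
#' @export
sgs_smooth <- function(X, window = 15, polyorder = 2) {
  X <- as_spectra_matrix(X)
  W <- ncol(X)
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 3 || window > W) stop("window must satisfy 3 <= window <= W")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  h <- (window - 1) / 2
  # central row of the SG projection matrix = smoothing coefficients
  coef <- signal::sgolay(p = polyorder, n = window)[h + 1, ]
  apply_fir_sym(X, as.numeric(coef), h)
}

#' Norris-Williams smoothing
#'
#' Centred moving average over `segment` points; when `gap > 0` the
#' averaged points on each side of the centre start after skipping `gap`
#' immediate neighbours. Edges are handled by window shrinkage.
#'
#' @param X `N x W` matrix or `spectra_set`.
#' @param segment Odd segment length `>= 1`.
#' @param gap Number of points skipped on each side (`>= 0`).
#' @return Matrix of the same dimension as `X`.
#' @export
nws_smooth <- function(X, segment = 5, gap = 0) {
  X <- as_spectra_matrix(X)
  W <- ncol(X)
  if (segment %% 2 == 0) stop("segment must be odd")
  if (segment > W) stop("segment must not exceed the number of wavelengths")
  if (gap < 0) stop("gap must be >= 0")
  h <- (segment - 1) / 2
  offs <- if (h == 0) 0L else c(0L, as.integer(outer(gap + seq_len(h), c(-1L, 1L))))
  out <- matrix(0, nrow(X), W)
  cnt <- numeric(W)
  for (o in offs) {
    j <- seq_len(W) + o
    ok <- j >= 1 & j <= W
    out[, ok] <- out[, ok] + X[, j[ok], drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  sweep(out, 2, cnt, "/")
}

# wavelet kernels: antisymmetric, zero-sum, support [-scale, scale]
cwd_kernel <- function(wavelet, scale) {
  if (scale < 1) stop("scale must be >= 1")
  supported <- c("haar", "gauss1")
  if (!wavelet %in% supported)
    stop("unsupported wavelet family '", wavelet, "'; supported: ",
         paste(supported, collapse = ", "))
  if (wavelet == "haar") {
    m <- seq(-ceiling(scale), ceiling(scale))
    t <- m / scale
    k <- sign(t) * (abs(t) <= 1)
  } else {
    m <- seq(-ceiling(4 * scale), ceiling(4 * scale))
    t <- m / scale
    k <- t * exp(-t^2 / 2)
  }
  k / sqrt(scale)
}

#' Continuous wavelet derivative
#'
#' Single-scale continuous wavelet transform of each row with an
#' antisymmetric wavelet, acting as a smoothed derivative: constants map
#' to zero and a linear ramp maps to a constant proportional to its
#' slope (positive slope, positive output). Output length is preserved
#' via symmetric reflection padding.
#'
#' @param X `N x W` matrix or `spectra_set`.
#' @param wavelet Wavelet family: `"haar"` (antisymmetric square wave on
#'   `[-scale, scale]`) or `"gauss1"` (first derivative of a Gaussian).
#' @param scale Positive scale `>= 1`, in grid points.
#' @return Matrix of the same dimension as `X`.
#' @export
cwd_derivative <- function(X, wavelet = "haar", scale = 10) {
  X <- as_spectra_matrix(X)
  k <- cwd_kernel(wavelet, scale)
  h <- (length(k) - 1) / 2
  if (2 * h + 1 > 2 * ncol(X))
    stop("wavelet support exceeds the spectrum length")
  apply_fir_sym(X, k, h)
}

# row-wise FIR filter with symmetric reflection padding, length preserving;
# kernel indexed -h..h, y_j = sum_m k[m] x[j+m]
apply_fir_sym <- function(X, k, h) {
  W <- ncol(X)
  if (h == 0) return(X * k)
  idx <- c((h + 1):2, 1:W, (W - 1):(W - h))  # reflect without repeating edges
  Xp <- X[, idx, drop = FALSE]
  out <- matrix(0, nrow(X), W)
  for (m in -h:h)
    out <- out + k[m + h + 1] * Xp[, (h + 1 + m):(h + W + m), drop = FALSE]
  out
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on `(1, reference)` by ordinary least squares
#' giving per-sample offset `a_i` and slope `b_i`, and returns
#' `(x_i - a_i) / b_i`. Rows whose slope magnitude falls below
#' `slope_tol` are returned uncorrected with a warning.
#'
#' @param X `N x W` matrix or `spectra_set`.
#' @param reference Reference spectrum (length `W`); defaults to the
#'   column mean of `X`. When correcting prediction spectra, pass the
#'   reference frozen from the calibration set.
#' @param slope_tol Minimum admissible `|b_i|`.
#' @return Corrected matrix with attribute `reference`.
#' @export
msc_correct <- function(X, reference = NULL, slope_tol = 1e-10) {
  X <- as_spectra_matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match the number of wavelengths")
  if (stats::var(reference) <= 0) stop("reference must have positive variance")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  b <- as.numeric(X %*% rc) / denom  # sum(rc) = 0, so centring of X cancels
  a <- rowMeans(X) - b * mean(reference)
  bad <- abs(b) < slope_tol
  if (any(bad)) {
    warning(sum(bad), " row(s) with vanishing scatter slope left uncorrected")
    b[bad] <- 1; a[bad] <- 0
  }
  out <- (X - a) / b
  attr(out, "reference") <- reference
  attr(out, "scatter") <- cbind(offset = a, slope = b)
  out
}

# Tukey-biweight weight on standardized residuals, cutoff cc
biweight_w <- function(u, cc = 3) {
  w <- (1 - (u / cc)^2)^2
  w[abs(u) >= cc] <- 0
  w
}

#' Variable sorting for normalization (VSN)
#'
#' Robust scatter correction: per spectrum, the offset/slope regression
#' on `(1, reference)` is fitted by iteratively reweighted least squares
#' where wavelengths dominated by chemical signal (large standardized
#' residuals) are downweighted with a Tukey-biweight influence function.
#' With `max_iter = 0` (weights pinned at 1) the result equals
#' [msc_correct()].
#'
#' @inheritParams msc_correct
#' @param weight_threshold Weights `>=` this value mark wavelengths
#'   treated as scatter-dominated (reported, not used in the fit).
#' @param cutoff Biweight cutoff on standardized residuals.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance on the weight vector (max norm).
#' @return Corrected matrix with attributes `reference`, `weights` (mean
#'   converged weight per wavelength) and `scatter_fraction` (share of
#'   wavelengths with mean weight `>= weight_threshold`).
#' @export
vsn_correct <- function(X, reference = NULL, weight_threshold = 0.5,
                        cutoff = 3, max_iter = 50, tol = 1e-6) {
  X <- as_spectra_matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match the number of wavelengths")
  if (stats::var(reference) <= 0) stop("reference must have positive variance")
  n <- nrow(X); W <- ncol(X)
  Wts <- matrix(1, n, W)
  out <- matrix(0, n, W)
  converged <- TRUE
  for (i in seq_len(n)) {
    x <- X[i, ]
    w <- rep(1, W)
    a <- 0; b <- 1
    iter <- 0
    repeat {
      sw <- sum(w)
      mx <- sum(w * x) / sw; mr <- sum(w * reference) / sw
      rc <- reference - mr
      denom <- sum(w * rc^2)
      if (denom <= 0) break
      b <- sum(w * (x - mx) * rc) / denom
      a <- mx - b * mr
      if (iter >= max_iter) {
        if (max_iter > 0) converged <- FALSE
        break
      }
      res <- x - a - b * reference
      s <- stats::mad(res)
      # residual scale collapse: the weighted channels fit exactly, so
      # the iteration has converged with the current weights
      if (s < 1e-12) break
      w_new <- biweight_w(res / s, cutoff)
      iter <- iter + 1
      if (max(abs(w_new - w)) < tol) { w <- w_new; break }
      w <- w_new
    }
    Wts[i, ] <- w
    out[i, ] <- if (abs(b) > 1e-10) (x - a) / b else x
  }
  if (!converged)
    warning("VSN weight iteration did not converge for some rows; last iterate returned")
  attr(out, "reference") <- reference
  attr(out, "weights") <- colMeans(Wts)
  attr(out, "scatter_fraction") <- mean(colMeans(Wts) >= weight_threshold)
  out
}

#' Apply a named preprocessing method
#'
#' Dispatcher over the five supported transforms (or `"raw"` for
#' identity). For `"msc"` and `"vsn"` the reference spectrum defaults to
#' the column mean of `X` and is returned in the `reference` attribute;
#' pass the calibration-set reference explicitly when transforming
#' prediction spectra so that no information leaks across the split.
#'
#' @param X `N x W` matrix or `spectra_set`.
#' @param method One of `"raw"`, `"nws"`, `"sgs"`, `"cwd"`, `"msc"`,
#'   `"vsn"` (case-insensitive).
#' @param ... Method parameters passed through to the underlying
#'   transform.
#' @param reference Frozen reference spectrum for `"msc"`/`"vsn"`.
#' @return Preprocessed matrix.
#' @export
preprocess <- function(X, method = "raw", ..., reference = NULL) {
  method <- tolower(method)
  X <- as_spectra_matrix(X)
  switch(method,
    raw = X,
    nws = nws_smooth(X, ...),
    sgs = sgs_smooth(X, ...),
    cwd = cwd_derivative(X, ...),
    msc = msc_correct(X, reference = reference, ...),
    vsn = vsn_correct(X, reference = reference, ...),
    stop("unknown preprocessing method '", method,
         "'; use raw, nws, sgs, cwd, msc or vsn"))
}
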