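# NIPALS PLS1 with optional soft-thresholded (sparse) weight vectors.
# Xc, yc are already centred. Returns weights/loadings/y-loadings and the
# coefficient path b(1..A) assembled from R = W (P'W)^{-1}.
nipals_spls <- function(Xc, yc, ncomp, eta = 0, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc)
  Wm <- matrix(0, p, ncomp); Pm <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    z <- as.numeric(crossprod(Xc, yc))
    if (eta > 0) {
      thr <- eta * max(abs(z))
      z <- sign(z) * pmax(abs(z) - thr, 0)
    }
    zn <- sqrt(sum(z^2))
    if (!is.finite(zn) || zn < tol) break
    w <- z / zn
    t_ <- as.numeric(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < tol) break
    p_ <- as.numeric(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
    Wm[, a] <- w; Pm[, a] <- p_; q[a] <- q_
    a_used <- a
  }
  if (a_used == 0) {
    return(list(weights = matrix(0, p, 1), loadings = matrix(0, p, 1),
                y_loadings = 0, rotation = matrix(0, p, 1),
                b_path = matrix(0, p, 1), ncomp = 0L))
  }
  Wm <- Wm[, seq_len(a_used), drop = FALSE]
  Pm <- Pm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  R <- Wm %*% solve(crossprod(Pm, Wm))
  b_path <- sapply(seq_len(a_used), function(a)
    R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  b_path <- matrix(b_path, nrow = p)
  list(weights = Wm, loadings = Pm, y_loadings = q, rotation = R,
       b_path = b_path, ncomp = a_used)
}

new_calibration_model <- function(kind, fit, x_center, y_center, n_factors,
                                  eta = 0, case_weights = NULL,
                                  variable_mask = NULL, extra = list()) {
  A <- min(n_factors, fit$ncomp)
  if (A < 1) A <- 1L
  b <- fit$b_path[, A]
  m <- c(list(kind = kind,
              x_center = x_center, y_center = y_center,
              weights = fit$weights, loadings = fit$loadings,
              y_loadings = fit$y_loadings, rotation = fit$rotation,
              coefficients = b,
              intercept = y_center - sum(x_center * b),
              n_factors = as.integer(A), eta = eta,
              case_weights = case_weights,
              variable_mask = variable_mask,
              b_path = fit$b_path), extra)
  class(m) <- "calibration_model"
  m
}

check_factors <- function(A, n, p) {
  A_max <- min(n - 1, p)
  if (A > A_max) {
    warning(sprintf("requested %d factors, feasible maximum is %d; clipped", A, A_max))
    A <- A_max
  }
  as.integer(max(1, A))
}

prepare_xy <- function(X, y, mask = NULL) {
  X <- as_spectra_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (nrow(X) < 2) stop("need at least two samples")
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (!is.null(mask)) {
    if (length(mask) == ncol(X)) X <- X[, mask, drop = FALSE]
    else if (sum(mask) != ncol(X))
      stop("variable mask length does not match X")
  }
  list(X = X, y = y)
}

#' Fit a PLS regression by NIPALS
#'
#' Classical single-response partial least squares: `X` and `y` are
#' mean-centred (no variance scaling; reflectance channels share units),
#' then per component the weight vector `w proportional to X'y` is
#' normalised, scores `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`
#' are computed and `X`, `y` deflated. The regression vector is
#' `b = W (P'W)^{-1} q`.
#'
#' @param X `n x W` predictor matrix (or `spectra_set`).
#' @param y Response vector (degrees Brix).
#' @param A Number of latent variables.
#' @param variable_mask Optional logical mask selecting the modelled
#'   wavelengths out of the full grid.
#' @return A `calibration_model` (kind `"plsr"`).
#' @export
fit_plsr <- function(X, y, A, variable_mask = NULL) {
  fit_splsr(X, y, A, eta = 0, variable_mask = variable_mask, kind = "plsr")
}

#' Fit a sparse PLS regression
#'
#' NIPALS where each weight vector is soft-thresholded before
#' normalisation: `w_j = sign(z_j) (|z_j| - eta * max|z_k|)_+` with
#' `z = X'y` at the current deflation step. `eta = 0` reduces exactly to
#' [fit_plsr()]; larger `eta` zeroes more wavelengths out of the model
#' support.
#'
#' @inheritParams fit_plsr
#' @param eta Sparsity parameter in `[0, 1)`.
#' @param kind Internal label override.
#' @return A `calibration_model` (kind `"splsr"`).
#' @export
fit_splsr <- function(X, y, A, eta = 0.5, variable_mask = NULL,
                      kind = "splsr") {
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  d <- prepare_xy(X, y, variable_mask)
  A <- check_factors(A, nrow(d$X), ncol(d$X))
  x_center <- colMeans(d$X); y_center <- mean(d$y)
  fit <- nipals_spls(sweep(d$X, 2, x_center), d$y - y_center, A, eta = eta)
  if (fit$ncomp < A)
    warning(sprintf("component %d had vanishing score norm; model truncated to %d factors",
                    fit$ncomp + 1L, fit$ncomp))
  new_calibration_model(kind, fit, x_center, y_center, A, eta = eta,
                        case_weights = rep(1, nrow(d$X)),
                        variable_mask = variable_mask)
}

# decreasing robustness weight functions on |u|
weight_fair <- function(u, c_tune = 4) 1 / (1 + abs(u) / c_tune)^2
weight_hampel <- function(u, a = 3, b = 6, r = 12) {
  au <- abs(u)
  w <- rep(0, length(u))
  w[au <= a] <- 1
  i <- au > a & au <= b
  w[i] <- a / au[i]
  i <- au > b & au <= r
  w[i] <- a * (r - au[i]) / ((r - b) * au[i])
  w
}

weighted_median_ <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

robust_scale_ <- function(r) {
  s <- stats::mad(r)  # 1.4826 * MAD
  if (s < 1e-12) {
    warning("MAD of residuals is zero; falling back to the standard deviation")
    s <- stats::sd(r)
  }
  if (s < 1e-12) s <- 1e-12
  s
}

#' Fit a sparse partial robust M regression (SPRMR)
#'
#' Iteratively reweighted sparse PLS with case weights that downweight
#' vertical outliers (aberrant response) and leverage points (aberrant
#' spectra). Starting weights come from robust centre/scale (median,
#' MAD) of `y` and of row distances in `X`; each iteration fits a sparse
#' PLS to the `sqrt(weight)`-scaled, weighted-mean-centred data, then
#' recomputes residual weights `w_r(r_i / sigma_hat)` (with `sigma_hat =
#' 1.4826 MAD`) and leverage weights `w_x(d_i / median(d))` from the
#' distance of each score row to the weighted coordinate-wise median of
#' the scores, using a monotone decreasing weight function. The default
#' is a Hampel-type weight (full weight 1 up to 3 robust SDs — the
#' classic three-sigma convention — descending to 0 at 12), so clean
#' samples keep weight ~1 while outliers are driven to 0; the `"fair"`
#' weight `1/(1 + |u|/c)^2` is available as an option. The converged case weights are stored in the model; weights
#' near 0 flag abnormal samples.
#'
#' @inheritParams fit_splsr
#' @param c_tune Tuning constant of the fair weight function.
#' @param tol Convergence tolerance: maximum relative change of the
#'   coefficient vector.
#' @param max_iter Maximum reweighting iterations.
#' @param weight_fn `"hampel"` (default) or `"fair"`.
#' @return A `calibration_model` (kind `"sprmr"`) with `case_weights`
#'   in `[0, 1]` and a `converged` flag.
#' @export
fit_sprmr <- function(X, y, A, eta = 0.5, c_tune = 4, tol = 1e-2,
                      max_iter = 30, variable_mask = NULL,
                      weight_fn = c("hampel", "fair")) {
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  if (c_tune <= 0) stop("c_tune must be positive")
  weight_fn <- match.arg(weight_fn)
  wf <- if (weight_fn == "fair") function(u) weight_fair(u, c_tune)
        else weight_hampel
  d <- prepare_xy(X, y, variable_mask)
  X0 <- d$X; y0 <- d$y
  n <- nrow(X0)
  A <- check_factors(A, n, ncol(X0))

  # starting weights: robust residual proxy in y, robust distance in X.
  # The start must reject gross outliers outright (weights 0 beyond 4
  # robust SDs): with W >> n even a small residual case weight lets a
  # gross outlier be partially absorbed by the fit, which inflates the
  # residual scale and masks the outlier from later iterations. The
  # harsh start plus reweighted refinement is the usual
  # high-breakdown-start / M-step pattern.
  u_y <- (y0 - stats::median(y0)) / robust_scale_(y0 - stats::median(y0))
  med_x <- apply(X0, 2, stats::median)
  dx <- sqrt(rowSums(sweep(X0, 2, med_x)^2))
  mdx <- stats::median(dx); if (mdx < 1e-12) mdx <- 1e-12
  w <- weight_hampel(u_y, 1.5, 2.5, 3.5) * weight_hampel(dx / mdx, 1.5, 2.5, 3.5)
  w <- pmax(w, 1e-6)

  b_prev <- NULL
  fit <- NULL; x_center <- NULL; y_center <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sw <- w / sum(w)
    x_center <- as.numeric(crossprod(X0, sw))
    y_center <- sum(sw * y0)
    Xc <- sweep(X0, 2, x_center)
    yc <- y0 - y_center
    rw <- sqrt(w)
    fit <- nipals_spls(Xc * rw, yc * rw, A, eta = eta)
    if (fit$ncomp == 0) break
    b <- fit$b_path[, min(A, fit$ncomp)]
    # unweighted residuals under the current model
    r <- yc - as.numeric(Xc %*% b)
    sig <- robust_scale_(r)
    w_r <- wf(r / sig)
    Tm <- Xc %*% fit$rotation
    med_t <- apply(Tm, 2, weighted_median_, w = w)
    dt <- sqrt(rowSums(sweep(Tm, 2, med_t)^2))
    mdt <- stats::median(dt); if (mdt < 1e-12) mdt <- 1e-12
    w_x <- wf(dt / mdt)
    w_new <- pmax(w_r * w_x, 1e-6)
    if (!is.null(b_prev)) {
      rel <- sqrt(sum((b - b_prev)^2)) / max(sqrt(sum(b_prev^2)), 1e-12)
      if (rel < tol) { converged <- TRUE; w <- w_new; break }
    }
    b_prev <- b
    w <- w_new
  }
  if (!converged)
    warning("SPRMR reweighting did not converge; returning the last iterate")
  m <- new_calibration_model("sprmr", fit, x_center, y_center, A, eta = eta,
                             case_weights = pmin(w, 1),
                             variable_mask = variable_mask,
                             extra = list(converged = converged,
                                          weight_fn = weight_fn,
                                          c_tune = c_tune))
  m
}

#' Predict SSC from a fitted calibration model
#'
#' Applies the variable mask, centring and the linear predictor
#' `intercept + x b`. Case weights play no role at prediction time.
#'
#' @param object A `calibration_model`.
#' @param newdata `m x W` matrix or `spectra_set` on the full wavelength
#'   grid the model was trained on (the mask, if any, is applied here).
#' @param ncomp Number of components to use (defaults to the fitted
#'   `n_factors`).
#' @param ... Ignored.
#' @return Numeric vector of predicted degrees Brix.
#' @export
predict.calibration_model <- function(object, newdata, ncomp = NULL, ...) {
  X <- as_spectra_matrix(newdata)
  if (!is.null(object$variable_mask)) {
    if (ncol(X) == length(object$variable_mask))
      X <- X[, object$variable_mask, drop = FALSE]
    else if (ncol(X) != sum(object$variable_mask))
      stop(sprintf("wavelength grid mismatch: model expects %d (full) or %d (masked) columns, found %d",
                   length(object$variable_mask), sum(object$variable_mask), ncol(X)))
  } else if (ncol(X) != length(object$x_center)) {
    stop(sprintf("wavelength grid mismatch: model expects %d columns, found %d",
                 length(object$x_center), ncol(X)))
  }
  b <- if (is.null(ncomp)) object$coefficients else {
    if (ncomp < 1 || ncomp > ncol(object$b_path))
      stop("ncomp out of the fitted component range")
    object$b_path[, ncomp]
  }
  ic <- if (is.null(ncomp)) object$intercept
        else object$y_center - sum(object$x_center * b)
  as.numeric(ic + X %*% b)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model '%s': %d factors, %d variables%s\n",
              x$kind, x$n_factors, length(x$coefficients),
              if (x$eta > 0) sprintf(", eta = %.2f (|support| = %d)",
                                     x$eta, sum(x$coefficients != 0)) else ""))
  if (x$kind == "sprmr")
    cat(sprintf("  case weights: median %.3f, min %.3f%s\n",
                stats::median(x$case_weights), min(x$case_weights),
                if (isFALSE(x$converged)) " (not converged)" else ""))
  invisible(x)
}

#' Cross-validate a calibration model over factor counts
#'
#' Assembles held-out predictions for each factor count `1..A_max` and
#' computes the RMSECV and R_CV curves. Per fold a single `A_max`-factor
#' model is fitted and its coefficient path supplies predictions for
#' every smaller factor count (for SPRMR the converged iteratively
#' reweighted fit's path is used).
#'
#' @inheritParams fit_plsr
#' @param kind `"plsr"`, `"splsr"` or `"sprmr"`.
#' @param A_max Largest factor count to evaluate (clipped to
#'   feasibility).
#' @param eta Sparsity (splsr/sprmr).
#' @param scheme `"kfold"`, `"loo"` or `"mccv"` (Monte-Carlo CV:
#'   `mccv_iter` random 80/20 splits).
#' @param k Number of folds for `"kfold"`.
#' @param mccv_iter,mccv_frac Monte-Carlo CV iterations and held-out
#'   fraction.
#' @param trim Fraction of the largest absolute held-out residuals
#'   discarded before computing RMSECV (trimmed, i.e. robust, CV).
#'   Robust estimators should be paired with a robust CV criterion:
#'   with `trim = 0` a few aberrant held-out samples dominate the curve
#'   and drag the factor choice towards over-conservative models.
#' @param seed Fold-assignment seed.
#' @param ... Extra arguments passed to the fitting function.
#' @return An object of class `cv_result`: `rmsecv_by_factor`,
#'   `r_cv_by_factor`, `chosen_A` (filled by [select_factors()]),
#'   `scheme`, `n`, `seed`.
#' @export
cross_validate <- function(X, y, kind = c("plsr", "splsr", "sprmr"),
                           A_max = 10, eta = 0,
                           scheme = c("kfold", "loo", "mccv"), k = 10,
                           mccv_iter = 30, mccv_frac = 0.2, trim = 0,
                           seed = 1L, variable_mask = NULL, ...) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  d <- prepare_xy(X, y, variable_mask)
  X <- d$X; y <- d$y
  n <- nrow(X)
  folds <- withr::with_seed(seed, switch(scheme,
    loo = as.list(seq_len(n)),
    kfold = {
      k <- min(k, n)
      split(sample.int(n), rep_len(seq_len(k), n))
    },
    mccv = lapply(seq_len(mccv_iter), function(i)
      sample.int(n, max(1, round(mccv_frac * n))))))
  A_max <- check_factors(A_max, n - max(lengths(folds)), ncol(X))
  fitfun <- switch(kind,
    plsr = function(Xt, yt) fit_plsr(Xt, yt, A_max),
    splsr = function(Xt, yt) fit_splsr(Xt, yt, A_max, eta = eta),
    sprmr = function(Xt, yt) suppressWarnings(
      fit_sprmr(Xt, yt, A_max, eta = eta, ...)))
  pred <- matrix(NA_real_, n, A_max)
  wt <- numeric(n)
  for (f in folds) {
    m <- fitfun(X[-f, , drop = FALSE], y[-f])
    for (a in seq_len(A_max)) {
      aa <- min(a, ncol(m$b_path))
      p <- predict(m, X[f, , drop = FALSE], ncomp = aa)
      if (scheme == "mccv") {
        pred[f, a] <- ifelse(is.na(pred[f, a]), 0, pred[f, a]) + p
      } else pred[f, a] <- p
    }
    wt[f] <- wt[f] + 1
  }
  if (scheme == "mccv") {
    seen <- wt > 0
    pred <- pred[seen, , drop = FALSE] / wt[seen]
    yv <- y[seen]
  } else yv <- y
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  keep_n <- max(2L, ceiling((1 - trim) * length(yv)))
  rmsecv <- apply(pred, 2, function(p) {
    r <- yv - p
    sqrt(mean(sort(r^2)[seq_len(keep_n)]))
  })
  rcv <- apply(pred, 2, function(p) compute_r(yv, p))
  structure(list(rmsecv_by_factor = rmsecv, r_cv_by_factor = rcv,
                 chosen_A = NULL, scheme = scheme, n = n, trim = trim,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' Choose the number of latent variables by the F-test rule
#'
#' Haaland-Thomas criterion: locate the global RMSECV minimum `A*` and
#' return the smallest `A <= A*` whose squared-RMSECV ratio to the
#' minimum stays below the `F(alpha; n, n)` critical value — the most
#' parsimonious model not significantly worse than the best.
#'
#' @param cv A `cv_result` (or bare RMSECV vector, with `n` supplied).
#' @param alpha F-test significance level.
#' @param n Number of calibration samples (taken from `cv` when
#'   available).
#' @return Integer chosen factor count.
#' @export
select_factors <- function(cv, alpha = 0.25, n = NULL) {
  curve <- if (inherits(cv, "cv_result")) cv$rmsecv_by_factor else as.numeric(cv)
  if (length(curve) == 0) stop("empty RMSECV curve")
  if (is.null(n)) n <- cv$n
  a_star <- which.min(curve)
  fcrit <- stats::qf(1 - alpha, n, n)
  ok <- which(curve[seq_len(a_star)]^2 / curve[a_star]^2 <= fcrit)
  as.integer(ok[1])
}
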