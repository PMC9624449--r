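#' Split samples into calibration and prediction sets
#'
#' Default method `"spxy"`: a Kennard-Stone-style greedy max-min design
#' on the joint distance `d(i,j) = d_X(i,j)/max(d_X) + d_y(i,j)/max(d_y)`
#' with `d_X` Euclidean on mean-centred spectra and `d_y = |ssc_i -
#' ssc_j|`, so that the calibration set covers the prediction set in
#' both response and spectral space. The samples with minimum and
#' maximum SSC are forced into the calibration set, guaranteeing that
#' the calibration SSC range contains the prediction range. `"random"`
#' is a seeded uniform split for testing.
#'
#' The calibration size is `round(N * cal / (cal + pred))`, the
#' remainder going to prediction: 400 samples at 2:1 yield 267/133.
#'
#' @param spectra A [spectra_set()] with `ssc` present (required for
#'   `"spxy"`), or a plain matrix together with `y`.
#' @param ratio Length-2 positive vector `c(cal, pred)`; default 2:1.
#' @param method `"spxy"` or `"random"`.
#' @param seed Seed for the random method (ignored by `"spxy"`, which is
#'   deterministic).
#' @param y Reference values when `spectra` is a plain matrix.
#' @return An object of class `calibration_split`: list with integer
#'   vectors `calibration`, `prediction` plus `method` and `seed`.
#' @export
partition_samples <- function(spectra, ratio = c(2, 1),
                              method = c("spxy", "random"),
                              seed = 1L, y = NULL) {
  method <- match.arg(method)
  X <- as_spectra_matrix(spectra)
  if (inherits(spectra, "spectra_set") && is.null(y)) y <- spectra$ssc
  n <- nrow(X)
  if (length(ratio) != 2 || any(ratio <= 0)) stop("ratio must be two positive numbers")
  n_cal <- round(n * ratio[1] / sum(ratio))
  n_cal <- max(2L, min(n - 1L, as.integer(n_cal)))
  if (method == "random") {
    cal <- withr::with_seed(seed, sort(sample.int(n, n_cal)))
  } else {
    if (is.null(y)) stop("spxy partitioning requires reference (ssc) values")
    cal <- spxy_select(X, y, n_cal)
  }
  structure(list(calibration = cal,
                 prediction = setdiff(seq_len(n), cal),
                 method = method, seed = as.integer(seed)),
            class = "calibration_split")
}

spxy_select <- function(X, y, n_cal) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  dx <- as.matrix(stats::dist(Xc))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  D <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  sel <- unique(c(which.min(y), which.max(y)))  # force SSC extremes in
  if (length(sel) == 1) sel <- c(sel, which.max(D[sel, ]))
  mind <- apply(D[, sel, drop = FALSE], 1, min)
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)  # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sort(sel)
}

#' @export
print.calibration_split <- function(x, ...) {
  cat(sprintf("calibration_split (%s): %d calibration / %d prediction samples\n",
              x$method, length(x$calibration), length(x$prediction)))
  invisible(x)
}
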