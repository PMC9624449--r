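#' Configuration for the synthetic Vis-NIR spectra generator
#'
#' Defines the generative model used throughout the package's tests and
#' simulations: a smooth reflectance baseline plus Gaussian absorption
#' bands whose amplitudes respond linearly to soluble-solids content
#' (SSC), per-sample multiplicative / additive scatter, white instrument
#' noise, and optional vertical-outlier (reference-value) and
#' leverage-point (spectrum-scaling) contamination.
#'
#' SSC is expressed in the spectrum through several independent latent
#' components (think distinct sugar/pigment/water constituents), each
#' tied to its own absorption bands: a broad water-region feature near
#' 960 nm, the medium-width visible/short-NIR trio near 570, 732 and
#' 797 nm, and a narrow chlorophyll-region band near 675 nm. The
#' component split gives the spectra the graded signal-strength
#' hierarchy of real fruit spectra — part of the SSC information rides
#' on strong broad features, part on much weaker narrow ones — which is
#' what makes calibration transfer, variable selection and noise
#' robustness behave realistically.
#'
#' The default wavelength grid is uniform over 346-1130 nm with 1044
#' points. Default SSC values follow a truncated normal with mean 12.86
#' and SD 0.95 degrees Brix on \[10.1, 15.1\]. The `"online"` mode reuses
#' the static generative model with intensity attenuation 0.8, doubled
#' scatter SDs, instrument-noise SD inflated by 1.5 and a vertical-outlier
#' fraction of 5% (vs 1% static), emulating mechanised random fruit
#' loading on a conveyor.
#'
#' @param n_samples Number of spectra to generate (>= 3).
#' @param mode `"static"` or `"online"`.
#' @param wl_min,wl_max,n_wavelengths Wavelength grid (nm, endpoints
#'   inclusive, uniform spacing).
#' @param ssc_range Length-2 truncation interval for SSC (degrees Brix).
#' @param ssc_mean,ssc_sd Location and scale of the (untruncated parent
#'   of the) SSC distribution.
#' @param band_centers,band_widths Absorption band centres and Gaussian
#'   SD widths, nm.
#' @param band_amplitudes Mean band amplitudes (reflectance units) at
#'   `ssc = ssc_mean`.
#' @param component_loadings Band-amplitude response per unit of the
#'   band's latent SSC component (reflectance units).
#' @param band_factors Integer map assigning each band to a latent SSC
#'   component.
#' @param factor_weights Relative contribution of each latent component
#'   to SSC; internally rescaled so the component SDs sum in quadrature
#'   to `ssc_sd`.
#' @param baseline_coefs Quadratic baseline coefficients `c(b0, b1, b2)`
#'   evaluated in the unit-scaled wavelength coordinate.
#' @param baseline_drift_sd SD of a per-sample random tilt added to the
#'   baseline (reflectance units).
#' @param multiplicative_scatter_sd SD of the per-sample multiplicative
#'   scatter factor (centred at 1).
#' @param additive_offset_sd SD of the per-sample additive offset.
#' @param noise_sd SD of i.i.d. Gaussian instrument noise per channel.
#' @param attenuation Intensity attenuation factor applied in online
#'   mode (< 1); ignored for static mode.
#' @param vertical_outlier_fraction Fraction of samples whose recorded
#'   SSC is perturbed (the spectrum stays truthful).
#' @param vertical_outlier_magnitude Size of the SSC perturbation, in
#'   units of `ssc_sd` (positive shift).
#' @param leverage_fraction Fraction of samples whose spectrum is scaled
#'   (the recorded SSC stays truthful).
#' @param leverage_scale Multiplicative factor applied to leverage-point
#'   spectra.
#' @param seed Integer seed; fixed seed + config gives bit-identical
#'   output.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 400,
                         mode = c("static", "online"),
                         wl_min = 346, wl_max = 1130, n_wavelengths = 1044,
                         ssc_range = c(10.1, 15.1),
                         ssc_mean = 12.86, ssc_sd = 0.95,
                         band_centers = c(570, 675, 732, 797, 880, 960),
                         band_widths = c(25, 25, 18, 16, 20, 80),
                         band_amplitudes = c(0.25, 0.06, 0.18, 0.20, 0.08, 0.22),
                         component_loadings = c(7.0e-3, 7.0e-3, 5.85e-3,
                                                4.7e-3, 7.0e-3, 1.5e-2),
                         band_factors = c(2, 3, 2, 2, 3, 1),
                         factor_weights = c(0.84, 0.315, 0.315),
                         baseline_coefs = c(0.30, 0.10, -0.12),
                         baseline_drift_sd = 0.005,
                         multiplicative_scatter_sd = 0.05,
                         additive_offset_sd = 0.01,
                         noise_sd = 1e-3,
                         attenuation = 0.8,
                         vertical_outlier_fraction = NULL,
                         vertical_outlier_magnitude = 5,
                         leverage_fraction = 0,
                         leverage_scale = 10,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(vertical_outlier_fraction))
    vertical_outlier_fraction <- if (mode == "online") 0.05 else 0.01
  cfg <- list(n_samples = as.integer(n_samples), mode = mode,
              wl_min = wl_min, wl_max = wl_max,
              n_wavelengths = as.integer(n_wavelengths),
              ssc_range = ssc_range, ssc_mean = ssc_mean, ssc_sd = ssc_sd,
              band_centers = band_centers, band_widths = band_widths,
              band_amplitudes = band_amplitudes,
              component_loadings = component_loadings,
              band_factors = as.integer(band_factors),
              factor_weights = factor_weights,
              baseline_coefs = baseline_coefs,
              baseline_drift_sd = baseline_drift_sd,
              multiplicative_scatter_sd = multiplicative_scatter_sd,
              additive_offset_sd = additive_offset_sd,
              noise_sd = noise_sd, attenuation = attenuation,
              vertical_outlier_fraction = vertical_outlier_fraction,
              vertical_outlier_magnitude = vertical_outlier_magnitude,
              leverage_fraction = leverage_fraction,
              leverage_scale = leverage_scale,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  num <- unlist(cfg[setdiff(names(cfg), "mode")], use.names = FALSE)
  if (any(!is.finite(num))) stop("synth_config contains non-finite values")
  if (cfg$n_samples < 3) stop("n_samples must be at least 3")
  if (cfg$ssc_range[1] >= cfg$ssc_range[2])
    stop("ssc_range must satisfy lo < hi")
  for (f in c("vertical_outlier_fraction", "leverage_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  k <- length(cfg$band_centers)
  if (length(cfg$band_widths) != k || length(cfg$band_amplitudes) != k ||
      length(cfg$component_loadings) != k || length(cfg$band_factors) != k)
    stop("band_centers, band_widths, band_amplitudes, component_loadings and band_factors must have equal length")
  if (max(cfg$band_factors) > length(cfg$factor_weights) ||
      min(cfg$band_factors) < 1)
    stop("band_factors must index into factor_weights")
  if (cfg$mode == "online" && (cfg$attenuation <= 0 || cfg$attenuation >= 1))
    stop("online attenuation must lie in (0, 1)")
  invisible(cfg)
}

# truncated-normal sampler by inverse-CDF (deterministic under seed)
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic Vis-NIR spectra set
#'
#' Draws SSC values from a truncated normal and decomposes each SSC
#' deviation into the configured latent components (conditionally on
#' their weighted sum equalling the deviation), builds clean spectra as
#' `baseline + sum_k amplitude_k(z) * Gaussian(band_k)` with each band's
#' amplitude responding to its component, applies per-sample
#' multiplicative and additive scatter, adds white instrument noise,
#' and injects the configured contamination. Online mode attenuates the
#' clean intensity and inflates scatter, noise and contamination (see
#' [synth_config()]).
#'
#' Contaminated sample indices are recorded in the `contamination`
#' attribute of the result (`$vertical`, `$leverage`).
#'
#' @param config A [synth_config()].
#' @return A [spectra_set()] with `ssc` present and attribute
#'   `contamination`.
#' @export
generate_spectra <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::with_seed(config$seed, generate_spectra_impl(config))
}

generate_spectra_impl <- function(cfg) {
  n <- cfg$n_samples
  wl <- seq(cfg$wl_min, cfg$wl_max, length.out = cfg$n_wavelengths)
  u <- (wl - cfg$wl_min) / (cfg$wl_max - cfg$wl_min)
  online <- cfg$mode == "online"
  scatter_sd <- cfg$multiplicative_scatter_sd * if (online) 2 else 1
  offset_sd  <- cfg$additive_offset_sd        * if (online) 2 else 1
  drift_sd   <- cfg$baseline_drift_sd         * if (online) 2 else 1
  noise_sd   <- cfg$noise_sd                  * if (online) 1.5 else 1
  atten      <- if (online) cfg$attenuation else 1

  ssc <- rtruncnorm_(n, cfg$ssc_mean, cfg$ssc_sd,
                     cfg$ssc_range[1], cfg$ssc_range[2])

  # latent SSC components: z_i ~ N(0, I_J) conditioned on c'z = ssc dev,
  # with component SDs c rescaled to sum in quadrature to ssc_sd
  J <- length(cfg$factor_weights)
  cvec <- cfg$factor_weights * cfg$ssc_sd /
    sqrt(sum(cfg$factor_weights^2))
  s2 <- sum(cvec^2)
  t_dev <- ssc - cfg$ssc_mean
  E <- matrix(stats::rnorm(n * J), n, J)
  Z <- outer(t_dev, cvec / s2) + E - tcrossprod(as.numeric(E %*% cvec) / s2, cvec)

  baseline <- cfg$baseline_coefs[1] + cfg$baseline_coefs[2] * u +
    cfg$baseline_coefs[3] * u^2
  K <- length(cfg$band_centers)
  G <- sapply(seq_len(K), function(k)
    exp(-0.5 * ((wl - cfg$band_centers[k]) / cfg$band_widths[k])^2))

  # clean spectra: rows = baseline + sum_k amp_k(z_i) g_k
  amps <- Z[, cfg$band_factors, drop = FALSE] *
    matrix(cfg$component_loadings, n, K, byrow = TRUE) +
    matrix(cfg$band_amplitudes, n, K, byrow = TRUE)
  X <- matrix(baseline, n, length(wl), byrow = TRUE) + amps %*% t(G)

  # per-sample scatter: multiplicative path-length variation of the
  # continuum baseline, a tilt drift and an additive offset. Scatter
  # acts on the continuum (not the band amplitudes): path-length
  # effects are dominated by bulk reflectance, and this keeps the
  # band-amplitude signal identifiable from scatter by linear models,
  # as scatter correction assumes.
  b_i <- 1 + stats::rnorm(n, 0, scatter_sd)
  a_i <- stats::rnorm(n, 0, offset_sd)
  d_i <- stats::rnorm(n, 0, drift_sd)
  X <- atten * (X + outer(b_i - 1, baseline)) + outer(d_i, u) + a_i
  X <- X + matrix(stats::rnorm(n * length(wl), 0, noise_sd), n)

  n_vert <- round(cfg$vertical_outlier_fraction * n)
  n_lev <- round(cfg$leverage_fraction * n)
  vert_idx <- if (n_vert > 0) sort(sample.int(n, n_vert)) else integer(0)
  lev_pool <- setdiff(seq_len(n), vert_idx)
  lev_idx <- if (n_lev > 0) sort(sample(lev_pool, min(n_lev, length(lev_pool))))
             else integer(0)
  if (length(vert_idx))
    ssc[vert_idx] <- ssc[vert_idx] +
      cfg$vertical_outlier_magnitude * cfg$ssc_sd
  if (length(lev_idx))
    X[lev_idx, ] <- X[lev_idx, ] * cfg$leverage_scale

  out <- spectra_set(wl, X, ssc = ssc, mode = cfg$mode)
  attr(out, "contamination") <- list(vertical = vert_idx, leverage = lev_idx)
  attr(out, "config") <- cfg
  out
}
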