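test_that("white Gaussian noise is injected at the requested SNR", {
  X <- matrix(rep(c(1, -1), 522), 4, 1044, byrow = TRUE)  # mean square exactly 1
  s <- spectra_set(seq(346, 1130, length.out = 1044), X)
  # realized SNR within +/- 1 dB of the request, averaged over seeds
  snr_hat <- vapply(1:20, function(i) {
    out <- add_wgn(s, indices = 2, snr_db = 10, seed = i)
    noise <- out$reflectance[2, ] - s$reflectance[2, ]
    10 * log10(mean(s$reflectance[2, ]^2) / mean(noise^2))
  }, numeric(1))
  expect_lt(abs(mean(snr_hat) - 10), 1)
  # untouched rows stay identical; huge SNR is a numerical identity
  out <- add_wgn(s, indices = 2, snr_db = 10, seed = 1)
  expect_identical(out$reflectance[-2, ], s$reflectance[-2, ])
  hi <- add_wgn(s, indices = 1:4, snr_db = 300, seed = 1)
  expect_equal(hi$reflectance, s$reflectance, tolerance = 1e-10)
  expect_warning(add_wgn(s, integer(0), 10), "unchanged")
  expect_identical(add_wgn(s, 2, 10, seed = 3)$reflectance,
                   add_wgn(s, 2, 10, seed = 3)$reflectance)
})

test_that("a zero-noise experiment reduces to the noise-free evaluation", {
  s <- generate_spectra(clean_config(n = 120, seed = 23))
  sp <- partition_samples(s)
  specs <- list(plsr = list(kind = "plsr", A = 4))
  ne <- run_noise_experiment(s, sp, model_specs = specs, snr_levels = 10,
                             n_noisy = 0, seed = 2)
  m <- fit_plsr(s$reflectance[sp$calibration, ], s$ssc[sp$calibration], 4)
  direct <- compute_rmse(s$ssc[sp$prediction],
                         predict(m, s$reflectance[sp$prediction, ]))
  expect_equal(ne$results$rmsep_whole, direct, tolerance = 1e-12)
})

test_that("whole-set RMSEP pools the noisy and clean subsets exactly", {
  s <- generate_spectra(clean_config(n = 150, seed = 29))
  sp <- partition_samples(s)
  ne <- run_noise_experiment(s, sp,
                             model_specs = list(plsr = list(kind = "plsr", A = 4),
                                                sprmr = list(kind = "sprmr", A = 4,
                                                             eta = 0.5)),
                             snr_levels = c(10, 50), n_noisy = 5, seed = 3)
  n_pred <- length(sp$prediction)
  for (i in seq_len(nrow(ne$results))) {
    row <- ne$results[i, ]
    expect_equal(row$rmsep_whole,
                 pooled_rmsep(list(c(row$rmsep_noisy, 5),
                                   c(row$rmsep_clean, n_pred - 5))),
                 tolerance = 1e-10)
  }
  expect_length(ne$noisy_cal_indices, 5)
  expect_length(ne$noisy_pred_indices, 5)
  expect_true(all(ne$noisy_cal_indices %in% sp$calibration))
  expect_true(all(ne$noisy_pred_indices %in% sp$prediction))
})

test_that("SPRMR case weights separate strongly contaminated calibration samples", {
  s <- generate_spectra(clean_config(n = 150, seed = 37))
  sp <- partition_samples(s)
  ne <- run_noise_experiment(s, sp,
                             model_specs = list(sprmr = list(kind = "sprmr",
                                                             A = 6, eta = 0.5)),
                             snr_levels = -10, n_noisy = 8, seed = 5)
  wr <- ne$weight_reports[["sprmr@-10"]]
  expect_lt(wr$median_weight_noisy, wr$median_weight_clean)
  expect_gt(wr$auc, 0.9)
  m <- fit_sprmr(s$reflectance[sp$calibration, ], s$ssc[sp$calibration],
                 A = 6, eta = 0.5)
  expect_true(all(m$case_weights >= 0 & m$case_weights <= 1))
  # no contamination signal on a clean fit: weights cannot classify
  clean_report <- case_weight_report(
    m, withr::with_seed(2, sample(seq_along(sp$calibration), 8)))
  expect_gt(clean_report$auc, 0.2)
  expect_lt(clean_report$auc, 0.8)
  expect_error(case_weight_report(fit_plsr(s$reflectance, s$ssc, 3), 1:5),
               "SPRMR")
})

test_that("the experiment is reproducible under a fixed master seed", {
  s <- generate_spectra(clean_config(n = 100, seed = 41))
  sp <- partition_samples(s)
  specs <- list(plsr = list(kind = "plsr", A = 3))
  a <- run_noise_experiment(s, sp, model_specs = specs, snr_levels = c(0, 20),
                            n_noisy = 4, seed = 8)
  b <- run_noise_experiment(s, sp, model_specs = specs, snr_levels = c(0, 20),
                            n_noisy = 4, seed = 8)
  expect_identical(a$results, b$results)
})
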