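test_that("spectra CSV round-trips exactly", {
  s <- quick_spectra(n = 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  r <- read_spectra(path)
  expect_equal(r$wavelengths, s$wavelengths, tolerance = 1e-12)
  expect_equal(r$reflectance, s$reflectance, tolerance = 1e-12)
  expect_equal(r$ssc, s$ssc, tolerance = 1e-12)
  expect_identical(r$sample_ids, s$sample_ids)
  expect_equal(ncol(r$reflectance), 1044)
})

test_that("spectra without a reference column load but refuse reference-driven stages", {
  s <- quick_spectra(n = 12, seed = 5)
  s$ssc <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  r <- read_spectra(path)
  expect_null(r$ssc)
  expect_error(partition_samples(r, method = "spxy"), "reference")
})

test_that("malformed spectra files are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,500,400,450", "a,1,2,3"), path)
  expect_error(read_spectra(path), "increasing")
  writeLines(c("sample_id,400,450", "a,1,oops"), path)
  expect_error(read_spectra(path), "non-numeric")
  writeLines(c("id,400,450", "a,1,2"), path)
  expect_error(read_spectra(path), "sample_id")
})

test_that("the spectra container enforces its invariants", {
  expect_error(spectra_set(c(1, 2, 2), matrix(0, 1, 3)), "increasing")
  expect_error(spectra_set(1:3, matrix(c(1, NA, 3), 1)), "finite")
  expect_error(spectra_set(1:3, matrix(0, 2, 3), ssc = 1), "length")
  s <- spectra_set(1:4, matrix(1:8, 2, byrow = TRUE), ssc = c(11, 12))
  expect_equal(dim(s), c(2L, 4L))
  s1 <- s[2]
  expect_equal(s1$ssc, 12)
  expect_equal(s1$reflectance, matrix(5:8, 1))
})

test_that("the pipeline produces a full summary and is byte-deterministic", {
  cfg <- pipeline_config(synth = clean_config(n = 120), A_max = 6,
                         models = list(plsr = list(kind = "plsr"),
                                       sprmr = list(kind = "sprmr", eta = 0.5)),
                         seed = 4)
  res <- run_pipeline(cfg)
  expect_named(res$summary,
               c("model", "lvs", "r_cv", "rmsecv", "r_p", "rmsep",
                 "rpd", "rer", "quality_band", "n_cal", "n_pred"))
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$provenance$seed, 4L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_pipeline_report(res, f1)
  write_pipeline_report(run_pipeline(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unknown configuration keys and model kinds are rejected", {
  expect_error(pipeline_config(models = list(x = list(kind = "svm"))),
               "unknown model kind")
  expect_error(pipeline_config(preprocess = list(method = "osc")),
               "unknown preprocessing method")
})

test_that("YAML run configs map onto pipeline_config", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("synth:", "  n_samples: 60", "  seed: 2",
               "preprocess:", "  method: sgs", "  window: 11", "  polyorder: 2",
               "A_max: 5", "seed: 3"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$synth$n_samples, 60L)
  expect_equal(cfg$preprocess$window, 11)
  expect_equal(cfg$seed, 3L)
})

test_that("MCUVE inside the pipeline masks the models consistently", {
  cfg <- pipeline_config(synth = clean_config(n = 100), A_max = 5,
                         mcuve = list(M = 50, r = 0.8,
                                      k_grid = c(50, 200, 1044)),
                         models = list(plsr = list(kind = "plsr")),
                         seed = 6)
  res <- run_pipeline(cfg)
  expect_s3_class(res$mcuve, "mcuve_result")
  expect_equal(length(res$models$plsr$coefficients), sum(res$mcuve$selected_mask))
  expect_lte(res$mcuve$rmsecv_curve$rmsecv[which(res$mcuve$rmsecv_curve$k ==
    sum(res$mcuve$selected_mask))],
    res$mcuve$rmsecv_curve$rmsecv[nrow(res$mcuve$rmsecv_curve)])
})
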