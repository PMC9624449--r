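test_that("Savitzky-Golay smoothing reproduces low-order polynomials and the impulse response", {
  x <- seq(0, 1, length.out = 41)
  for (p in 0:2) {
    row <- 2 + 3 * x - 1.5 * x^p
    sm <- sgs_smooth(matrix(row, 1), window = 7, polyorder = 2)
    expect_equal(sm[1, 4:38], row[4:38], tolerance = 1e-10)
  }
  # 5-point quadratic filter: coefficients (-3, 12, 17, 12, -3)/35
  imp <- sgs_smooth(matrix(c(0, 0, 1, 0, 0), 1), window = 5, polyorder = 2)
  expect_equal(imp[1, 3], 17 / 35, tolerance = 1e-12)
  cst <- sgs_smooth(matrix(4.2, 3, 20), window = 5, polyorder = 2)
  expect_equal(cst, matrix(4.2, 3, 20), tolerance = 1e-12)
  expect_error(sgs_smooth(matrix(0, 1, 20), window = 6), "odd")
  expect_error(sgs_smooth(matrix(0, 1, 20), window = 5, polyorder = 5), "smaller")
})

test_that("Norris-Williams smoothing is a centred moving average with edge shrinkage", {
  expect_equal(nws_smooth(matrix(1:5, 1), segment = 1, gap = 0),
               matrix(as.numeric(1:5), 1))
  out <- nws_smooth(matrix(as.numeric(1:5), 1), segment = 3, gap = 0)
  expect_equal(out[1, 2:4], c(2, 3, 4))
  expect_equal(out[1, 1], 1.5)  # shrunk edge window
  cst <- nws_smooth(matrix(2.5, 2, 11), segment = 5, gap = 2)
  expect_equal(cst, matrix(2.5, 2, 11))
  expect_error(nws_smooth(matrix(0, 1, 4), segment = 5), "exceed")
})

test_that("continuous wavelet derivative kills constants and measures slopes", {
  expect_equal(cwd_derivative(matrix(3.3, 2, 30), "haar", 4),
               matrix(0, 2, 30), tolerance = 1e-12)
  ramp <- matrix(2 * (1:40), 1)
  out <- cwd_derivative(ramp, "haar", 1)
  expect_equal(out[1, 5:35], rep(out[1, 20], 31))  # constant interior
  expect_gt(out[1, 20], 0)                         # positive slope convention
  expect_equal(out[1, 20] / 2, cwd_derivative(matrix(1:40, 1), "haar", 1)[1, 20])
  # linearity on random rows
  withr::with_seed(3, {
    x <- rnorm(50); y <- rnorm(50)
    lhs <- cwd_derivative(matrix(2 * x - 3 * y, 1), "gauss1", 5)
    rhs <- 2 * cwd_derivative(matrix(x, 1), "gauss1", 5) -
      3 * cwd_derivative(matrix(y, 1), "gauss1", 5)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  })
  expect_error(cwd_derivative(matrix(0, 1, 30), "sym4", 2), "haar, gauss1")
})

test_that("MSC inverts affine scatter against the reference", {
  withr::with_seed(4, ref <- 0.5 + abs(rnorm(25)))
  X <- rbind(2 * ref + 1, ref)
  out <- msc_correct(X, reference = ref)
  expect_equal(out[1, ], ref, tolerance = 1e-10)
  expect_equal(out[2, ], ref, tolerance = 1e-10)
  # closed-form 3-wavelength case: row (2,4,6) on reference (1,2,3)
  out3 <- msc_correct(matrix(c(2, 4, 6), 1), reference = c(1, 2, 3))
  expect_equal(out3[1, ], c(1, 2, 3), tolerance = 1e-12)
  expect_equal(attr(out3, "scatter")[1, ], c(offset = 0, slope = 2),
               tolerance = 1e-12)
  expect_warning(msc_correct(matrix(rep(1, 25), 1), reference = ref),
                 "uncorrected")
})

test_that("VSN equals MSC with pinned weights and downweights chemical bands", {
  withr::with_seed(6, {
    ref <- 1 + 0.5 * sin(seq(0, 3, length.out = 60))
    X <- t(replicate(5, (1 + rnorm(1, 0, 0.1)) * ref + rnorm(1, 0, 0.05)))
  })
  pinned <- vsn_correct(X, reference = ref, max_iter = 0)
  expect_equal(unclass(pinned), unclass(msc_correct(X, reference = ref)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # pure scatter rows: reference recovered, all weights at 1
  full <- vsn_correct(X, reference = ref, weight_threshold = 0.5)
  expect_equal(full[2, ], ref, tolerance = 1e-8)
  expect_true(all(attr(full, "weights") >= 0.5))
  # a localized chemical band must be downweighted
  Xb <- X
  Xb[, 20:28] <- Xb[, 20:28] + 1.5
  wb <- attr(vsn_correct(Xb, reference = ref), "weights")
  expect_lt(max(wb[20:28]), median(wb[-(20:28)]))
})

test_that("transforms are deterministic and row-independent", {
  withr::with_seed(8, X <- matrix(rnorm(6 * 40), 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  for (f in list(function(m) sgs_smooth(m, 7, 2),
                 function(m) nws_smooth(m, 5, 1),
                 function(m) cwd_derivative(m, "haar", 3),
                 function(m) msc_correct(m, reference = colMeans(X)),
                 function(m) vsn_correct(m, reference = colMeans(X)))) {
    expect_equal(unclass(f(X[perm, ]))[, ], unclass(f(X))[perm, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("scatter correction tightens same-composition spectra", {
  s <- generate_spectra(clean_config(n = 50, seed = 4,
                                     multiplicative_scatter_sd = 0.08))
  d0 <- mean(dist(s$reflectance))
  expect_lt(mean(dist(msc_correct(s$reflectance))), d0)
  expect_lt(mean(dist(suppressWarnings(vsn_correct(s$reflectance)))), d0)
})
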