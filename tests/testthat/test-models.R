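test_that("full-rank PLSR matches the ordinary least squares oracle", {
  withr::with_seed(1, {
    X <- matrix(rnorm(20 * 5), 20)
    y <- as.numeric(X %*% rnorm(5)) + rnorm(20, 0, 0.1)
  })
  m <- fit_plsr(X, y, A = 5)
  ols <- qr.coef(qr(cbind(1, X)), y)  # independent normal-equations oracle
  expect_equal(m$coefficients, unname(ols[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("one latent variable suffices for rank-1 data and scores are orthogonal", {
  withr::with_seed(2, {
    t1 <- rnorm(30); p1 <- rnorm(12)
    X <- tcrossprod(t1, p1)
    y <- 2 * t1 + 1
  })
  m1 <- fit_plsr(X, y, A = 1)
  expect_lt(compute_rmse(y, predict(m1, X)), 1e-10)

  lr <- make_lowrank_fixture(n = 40, W = 30, rank = 5)
  m <- fit_plsr(lr$X, lr$y, A = 5)
  scores <- sweep(lr$X, 2, m$x_center) %*% m$rotation
  gram <- crossprod(scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-10 * max(diag(gram)))
})

test_that("sparse PLS with eta = 0 reduces to PLSR and support shrinks with eta", {
  fx <- make_sparse_fixture()
  m0 <- fit_splsr(fx$X, fx$y, A = 3, eta = 0)
  mp <- fit_plsr(fx$X, fx$y, A = 3)
  expect_equal(m0$coefficients, mp$coefficients, tolerance = 1e-8)
  supports <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.9), function(e)
    sum(fit_splsr(fx$X, fx$y, A = 2, eta = e)$coefficients != 0), numeric(1))
  expect_true(all(diff(supports) <= 0))
  expect_error(fit_splsr(fx$X, fx$y, A = 2, eta = 1), "eta")
})

test_that("strong sparsity keeps the informative variables", {
  fx <- make_sparse_fixture(n = 80, W = 50, signal = c(3, 17, 40),
                            coefs = c(1, -1, 1), noise_sd = 0.1, seed = 12)
  m <- fit_splsr(fx$X, fx$y, A = 2, eta = 0.9)
  supp <- which(m$coefficients != 0)
  expect_lt(length(supp), 50)
  expect_true(all(fx$signal %in% supp))
})

test_that("SPRMR on clean data matches sparse PLS and keeps full case weights", {
  s <- generate_spectra(clean_config(n = 200, seed = 31))
  ms <- fit_sprmr(s$reflectance, s$ssc, A = 6, eta = 0.5)
  mq <- fit_splsr(s$reflectance, s$ssc, A = 6, eta = 0.5)
  expect_true(ms$converged)
  expect_gte(mean(ms$case_weights > 0.9), 0.95)
  rel <- sqrt(sum((ms$coefficients - mq$coefficients)^2)) /
    sqrt(sum(mq$coefficients^2))
  expect_lt(rel, 0.05)
})

test_that("SPRMR flags a single vertical outlier and a leverage point", {
  # classical-regime fixture (n > W) where IRLS theory applies directly
  withr::with_seed(14, {
    n <- 80; W <- 15
    scores <- matrix(rnorm(n * 3), n)
    X <- scores %*% matrix(rnorm(3 * W), 3) + matrix(rnorm(n * W, 0, 0.05), n)
    y <- as.numeric(scores %*% c(1, -0.5, 0.8)) + rnorm(n, 0, 0.1)
  })
  mc <- fit_plsr(X, y, A = 3)
  res_sd <- sd(y - predict(mc, X))
  yv <- y; yv[7] <- yv[7] + 10 * res_sd
  mv <- fit_sprmr(X, yv, A = 3, eta = 0)
  expect_lt(mv$case_weights[7], 0.2)
  expect_gt(median(mv$case_weights[-7]), 0.9)

  Xl <- X; Xl[11, ] <- Xl[11, ] * 10
  ml <- fit_sprmr(Xl, y, A = 3, eta = 0)
  expect_lt(ml$case_weights[11], 0.5)
  expect_gt(median(ml$case_weights[-11]), 0.9)
})

test_that("prediction honours masks, reproduces training fits and rejects grid mismatches", {
  lr <- make_lowrank_fixture(n = 30, W = 20, rank = 2, seed = 8)
  m <- fit_plsr(lr$X, lr$y, A = 2)
  expect_equal(predict(m, lr$X), lr$y, tolerance = 1e-8)
  # factor-space and coefficient-form predictions agree
  expect_equal(predict(m, lr$X, ncomp = m$n_factors), predict(m, lr$X),
               tolerance = 1e-12)

  mask <- rep(c(TRUE, FALSE), 10)
  mm <- fit_plsr(lr$X[, mask], lr$y, A = 2, variable_mask = mask)
  expect_equal(predict(mm, lr$X), predict(mm, lr$X[, mask]), tolerance = 1e-12)
  expect_error(predict(m, lr$X[, 1:7]), "mismatch")

  # training order does not matter
  perm <- withr::with_seed(10, sample(seq_along(lr$y)))
  m2 <- fit_plsr(lr$X[perm, ], lr$y[perm], A = 2)
  expect_equal(predict(m2, lr$X), predict(m, lr$X), tolerance = 1e-8)
})

test_that("cross-validation is exhaustive under LOO, seeded under k-fold, and exact on noiseless data", {
  lr <- make_lowrank_fixture(n = 25, W = 15, rank = 3, seed = 9)
  # rank-3 data: the 4th component degenerates, which the fitter reports
  cv <- suppressWarnings(cross_validate(lr$X, lr$y, "plsr", A_max = 4, scheme = "loo"))
  expect_length(cv$rmsecv_by_factor, 4)
  expect_lt(cv$rmsecv_by_factor[3], 1e-6)  # exact rank-3 model recovered
  k1 <- suppressWarnings(cross_validate(lr$X, lr$y, "plsr", A_max = 4,
                                        scheme = "kfold", k = 5, seed = 4))
  k2 <- suppressWarnings(cross_validate(lr$X, lr$y, "plsr", A_max = 4,
                                        scheme = "kfold", k = 5, seed = 4))
  expect_identical(k1$rmsecv_by_factor, k2$rmsecv_by_factor)
  mc <- cross_validate(lr$X, lr$y, "plsr", A_max = 3, scheme = "mccv",
                       mccv_iter = 10, seed = 2)
  expect_true(all(is.finite(mc$rmsecv_by_factor)))
})

test_that("the F-test factor rule prefers parsimony", {
  expect_equal(select_factors(c(1.0, 0.50, 0.49, 0.48), alpha = 0.25, n = 50), 2L)
  expect_equal(select_factors(rep(0.4, 6), alpha = 0.25, n = 30), 1L)
  curve <- c(2, 1.4, 0.9, 0.5, 0.2)
  expect_lte(select_factors(curve, alpha = 0.25, n = 40), 5L)
})

test_that("degenerate model inputs are rejected or clipped", {
  withr::with_seed(3, X <- matrix(rnorm(40), 10))
  expect_error(fit_plsr(X, rep(1, 10), A = 2), "zero variance")
  expect_warning(fit_plsr(X, rnorm(10), A = 9), "clipped")
})
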