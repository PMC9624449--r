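# shared fixtures, all generated in code

# gaussian design with a sparse linear signal
make_sparse_fixture <- function(n = 60, W = 50, signal = c(3, 17, 40),
                                coefs = c(1, -1, 1), noise_sd = 0.3,
                                seed = 2) {
  stopifnot(max(signal) <= W)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * W), n)
    beta <- rep(0, W)
    beta[signal] <- coefs
    y <- as.numeric(X %*% beta) + rnorm(n, 0, noise_sd)
    list(X = X, y = y, beta = beta, signal = signal)
  })
}

# small latent-structure data where exact PLS recovery holds
make_lowrank_fixture <- function(n = 40, W = 30, rank = 3, seed = 5) {
  withr::with_seed(seed, {
    scores <- matrix(rnorm(n * rank), n)
    load <- matrix(rnorm(rank * W), rank)
    X <- scores %*% load
    y <- as.numeric(scores %*% rnorm(rank))
    list(X = X, y = y)
  })
}

# a quick, small synthetic spectra set
quick_spectra <- function(n = 60, seed = 1, ...) {
  generate_spectra(synth_config(n_samples = n, seed = seed, ...))
}

clean_config <- function(n = 60, seed = 1, ...) {
  synth_config(n_samples = n, seed = seed, vertical_outlier_fraction = 0, ...)
}
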