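#' Assemble a full pipeline configuration
#'
#' Collects every stage's parameters into one validated object. Either
#' `input` (a spectra CSV path or a `spectra_set`) or `synth` (a
#' [synth_config()], used to simulate data) must be provided.
#'
#' @param input Spectra CSV path or a `spectra_set`; `NULL` to simulate.
#' @param synth A [synth_config()] used when `input` is `NULL`.
#' @param preprocess List: `method` plus method parameters (see
#'   [preprocess()]).
#' @param partition List: `ratio` (length 2), `method`.
#' @param mcuve `NULL` to skip wavelength selection, else a list of
#'   [mcuve_select()] arguments (`M`, `r`, `k_grid`, `select`, ...).
#' @param models Named list of model specs (`kind`, optional `eta`); `A`
#'   is chosen per model by cross-validation up to `A_max`.
#' @param A_max Largest factor count scanned by cross-validation.
#' @param cv List: `scheme` (`"kfold"`, `"loo"`, `"mccv"`), `k`,
#'   `alpha` (F-test level for [select_factors()]).
#' @param noise `NULL` to skip the WGN experiment, else a list with
#'   `snr_levels` and `n_noisy`.
#' @param seed Master seed driving every seeded stage.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(input = NULL, synth = synth_config(),
                            preprocess = list(method = "sgs", window = 15,
                                              polyorder = 2),
                            partition = list(ratio = c(2, 1), method = "spxy"),
                            mcuve = NULL,
                            models = list(plsr = list(kind = "plsr"),
                                          splsr = list(kind = "splsr", eta = 0.5),
                                          sprmr = list(kind = "sprmr", eta = 0.5)),
                            A_max = 10,
                            cv = list(scheme = "kfold", k = 10, alpha = 0.25),
                            noise = NULL,
                            seed = 1L) {
  allowed <- c("input", "synth", "preprocess", "partition", "mcuve",
               "models", "A_max", "cv", "noise", "seed")
  cfg <- list(input = input, synth = synth, preprocess = preprocess,
              partition = partition, mcuve = mcuve, models = models,
              A_max = as.integer(A_max), cv = cv, noise = noise,
              seed = as.integer(seed))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!is.null(preprocess$method) &&
      !tolower(preprocess$method) %in% c("raw", "nws", "sgs", "cwd", "msc", "vsn"))
    stop("unknown preprocessing method '", preprocess$method, "'")
  for (mn in names(models))
    if (!models[[mn]]$kind %in% c("plsr", "splsr", "sprmr"))
      stop("unknown model kind '", models[[mn]]$kind, "'")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. A `synth` block is passed to [synth_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  do.call(pipeline_config, raw)
}

#' Run the full calibration pipeline
#'
#' Executes simulate/ingest -> partition -> preprocess (reference frozen
#' on the calibration set) -> optional MCUVE wavelength selection ->
#' per-model cross-validated factor choice and fit -> evaluation on the
#' prediction set -> optional WGN noise experiment. The summary table
#' carries one row per model with LVs, R_CV, RMSECV, R_P, RMSEP, RPD
#' and RER. No stage mutates its inputs; a provenance block (seed,
#' package version, config) is attached to the result.
#'
#' @param config A [pipeline_config()] (or [read_run_config()]) object.
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_result`: `summary` (data.frame),
#'   `models`, `cv`, `reports`, `split`, `mcuve`, `noise`, `spectra`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  spectra <- if (is.null(config$input)) {
    say("simulating %d '%s' spectra", config$synth$n_samples, config$synth$mode)
    cfg <- config$synth; cfg$seed <- config$seed
    generate_spectra(cfg)
  } else if (inherits(config$input, "spectra_set")) config$input
  else read_spectra(config$input)
  if (is.null(spectra$ssc)) stop("pipeline requires spectra with ssc reference values")

  split <- partition_samples(spectra, ratio = config$partition$ratio %||% c(2, 1),
                             method = config$partition$method %||% "spxy",
                             seed = config$seed)
  say("partitioned %d / %d", length(split$calibration), length(split$prediction))

  pp <- config$preprocess %||% list(method = "raw")
  method <- tolower(pp$method %||% "raw")
  pp_args <- pp[setdiff(names(pp), "method")]
  X_all <- spectra$reflectance
  reference <- NULL
  if (method %in% c("msc", "vsn")) {
    reference <- colMeans(X_all[split$calibration, , drop = FALSE])
    Xp <- do.call(preprocess, c(list(X_all, method = method,
                                     reference = reference), pp_args))
  } else {
    Xp <- do.call(preprocess, c(list(X_all, method = method), pp_args))
  }
  y <- spectra$ssc
  X_cal <- Xp[split$calibration, , drop = FALSE]; y_cal <- y[split$calibration]
  X_pred <- Xp[split$prediction, , drop = FALSE]; y_pred <- y[split$prediction]

  mask <- NULL; mc <- NULL
  if (!is.null(config$mcuve)) {
    say("MCUVE selection")
    A0 <- select_factors(cross_validate(X_cal, y_cal, "plsr",
                                        A_max = config$A_max,
                                        scheme = config$cv$scheme %||% "kfold",
                                        k = config$cv$k %||% 10,
                                        seed = config$seed),
                         alpha = config$cv$alpha %||% 0.25)
    mc <- do.call(mcuve_select,
                  c(list(X_cal, y_cal, A = A0, seed = config$seed),
                    config$mcuve))
    mask <- mc$selected_mask
    say("retained %d variables", sum(mask))
  }

  cvs <- list(); fits <- list(); reports <- list()
  for (mn in names(config$models)) {
    spec <- config$models[[mn]]
    say("model %s", mn)
    cv <- cross_validate(X_cal, y_cal, kind = spec$kind,
                         A_max = config$A_max, eta = spec$eta %||% 0,
                         scheme = config$cv$scheme %||% "kfold",
                         k = config$cv$k %||% 10,
                         seed = config$seed, variable_mask = mask)
    A <- select_factors(cv, alpha = config$cv$alpha %||% 0.25)
    cv$chosen_A <- A
    m <- fit_spec(c(spec, list(A = A)),
                  if (is.null(mask)) X_cal else X_cal[, mask, drop = FALSE],
                  y_cal)
    m$variable_mask <- mask
    reports[[mn]] <- evaluate_model(m, X_pred, y_pred, cv = cv,
                                    n_cal = length(y_cal))
    cvs[[mn]] <- cv; fits[[mn]] <- m
  }
  summary_df <- do.call(rbind, lapply(reports, as.data.frame))
  rownames(summary_df) <- NULL

  noise <- NULL
  if (!is.null(config$noise)) {
    say("noise experiment")
    pre_spectra <- spectra_set(spectra$wavelengths, Xp, spectra$sample_ids,
                               ssc = y, mode = spectra$mode)
    specs <- lapply(names(config$models), function(mn)
      c(config$models[[mn]], list(A = cvs[[mn]]$chosen_A)))
    names(specs) <- names(config$models)
    noise <- run_noise_experiment(pre_spectra, split, model_specs = specs,
                                  snr_levels = config$noise$snr_levels %||% c(-10, 10, 50),
                                  n_noisy = config$noise$n_noisy %||% 10,
                                  seed = config$seed)
  }

  structure(list(summary = summary_df, models = fits, cv = cvs,
                 reports = reports, split = split, mcuve = mc,
                 noise = noise, spectra = spectra,
                 provenance = list(
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("robnir")),
                   timestamp = NULL,  # deliberately omitted: outputs must be byte-identical under a fixed seed
                   config = config)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a pipeline summary to JSON
#'
#' Serialises the summary table, the provenance block and (when
#' present) the noise-experiment table; deterministic given seed and
#' config.
#'
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  prov <- result$provenance
  prov$config <- unclass_deep(prov$config)
  out <- list(summary = result$summary,
              noise = if (!is.null(result$noise)) result$noise$results,
              provenance = prov)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
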