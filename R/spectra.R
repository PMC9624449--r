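#' Construct a spectra set
#'
#' The universal data container of the package: a wavelength grid, an
#' `N x W` reflectance matrix, optional reference values (soluble-solids
#' content, degrees Brix) and an acquisition-mode tag.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length `W`.
#' @param reflectance Numeric `N x W` matrix of reflectance intensities;
#'   all values must be finite.
#' @param sample_ids Character vector of `N` sample labels; generated as
#'   `"s0001"...` when omitted.
#' @param ssc Optional numeric vector of `N` reference SSC values
#'   (degrees Brix).
#' @param mode Acquisition mode, `"static"` or `"online"`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `reflectance`, `sample_ids`, `ssc`, `mode`.
#' @export
spectra_set <- function(wavelengths, reflectance, sample_ids = NULL,
                        ssc = NULL, mode = c("static", "online")) {
  mode <- match.arg(mode)
  wavelengths <- as.numeric(wavelengths)
  if (is.data.frame(reflectance)) reflectance <- as.matrix(reflectance)
  if (!is.matrix(reflectance)) reflectance <- matrix(reflectance, nrow = 1)
  storage.mode(reflectance) <- "double"
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(wavelengths) != ncol(reflectance))
    stop(sprintf("wavelength grid has %d points but reflectance has %d columns",
                 length(wavelengths), ncol(reflectance)))
  if (any(!is.finite(reflectance)))
    stop("reflectance contains non-finite values")
  n <- nrow(reflectance)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  if (length(sample_ids) != n)
    stop("sample_ids length does not match the number of spectra")
  if (!is.null(ssc)) {
    ssc <- as.numeric(ssc)
    if (length(ssc) != n)
      stop(sprintf("ssc has length %d but there are %d spectra",
                   length(ssc), n))
    if (any(!is.finite(ssc))) stop("ssc contains non-finite values")
  }
  dimnames(reflectance) <- NULL
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         sample_ids = as.character(sample_ids), ssc = ssc, mode = mode),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavelengths (%.1f-%.1f nm), mode '%s'\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$mode))
  if (!is.null(x$ssc))
    cat(sprintf("  SSC: %.2f-%.2f, mean %.3f, sd %.3f degrees Brix\n",
                min(x$ssc), max(x$ssc), mean(x$ssc), stats::sd(x$ssc)))
  else cat("  SSC: absent\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by sample
#'
#' @param x A `spectra_set`.
#' @param i Row (sample) index vector.
#' @param ... Ignored.
#' @return A `spectra_set` holding the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$wavelengths, x$reflectance[i, , drop = FALSE],
              sample_ids = x$sample_ids[i],
              ssc = if (!is.null(x$ssc)) x$ssc[i], mode = x$mode)
}

#' Read a spectra CSV file
#'
#' Expected layout: column 1 `sample_id`, optional column `ssc`, remaining
#' columns headed by wavelength in nm (strictly increasing).
#'
#' @param path Path to a CSV file.
#' @param mode Acquisition-mode tag to attach (`"static"` or `"online"`).
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, mode = "static") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(dt))
    stop("spectra CSV must contain a 'sample_id' column")
  ids <- as.character(dt$sample_id)
  ssc <- if ("ssc" %in% names(dt)) as.numeric(dt$ssc) else NULL
  wl_cols <- setdiff(names(dt), c("sample_id", "ssc"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("non-numeric wavelength headers: ",
         paste(utils::head(wl_cols[is.na(wl)], 5), collapse = ", "))
  if (any(diff(wl) <= 0))
    stop("wavelength headers are not strictly increasing")
  X <- as.matrix(dt[, wl_cols, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(dt[wl_cols], is.numeric, logical(1)))
    stop("non-numeric cells in spectral columns: ",
         paste(utils::head(wl_cols[bad], 5), collapse = ", "))
  }
  spectra_set(wl, X, sample_ids = ids, ssc = ssc, mode = mode)
}

#' Write a spectra set to CSV
#'
#' Inverse of [read_spectra()]: column 1 `sample_id`, column 2 `ssc`
#' (when present), remaining columns headed by wavelength in nm.
#'
#' @param x A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(x$ssc)) df$ssc <- x$ssc
  sp <- as.data.frame(x$reflectance)
  names(sp) <- as.character(x$wavelengths)
  data.table::fwrite(cbind(df, sp), path)
  invisible(path)
}

# internal: extract the reflectance matrix from spectra_set or plain matrix
as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$reflectance
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = 1)
  else stop("expected a spectra_set or a numeric matrix")
}
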