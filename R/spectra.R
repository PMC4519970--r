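#' Construct a spectrum
#'
#' A spectrum is a wavelength grid (nm) with per-wavelength values and a
#' declared kind. Absorbance is dimensionless optical density D, molar
#' extinction is in M^-1 cm^-1, emission is in arbitrary intensity units.
#'
#' @param wavelengths Numeric vector of wavelengths in nm. Must be positive;
#'   duplicates are rejected. Stored sorted ascending.
#' @param values Numeric vector of the same length as `wavelengths`.
#' @param kind One of `"absorbance"`, `"extinction"`, `"emission"`.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength` and `value` and attribute `kind`.
#' @examples
#' s <- spectrum(c(500, 545, 600), c(0, 1, 0), kind = "emission")
#' @export
spectrum <- function(wavelengths, values, kind = c("absorbance", "extinction", "emission")) {
  kind <- match.arg(kind)
  if (!is.numeric(wavelengths) || !is.numeric(values))
    stop("wavelengths and values must be numeric")
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths) == 0L) stop("spectrum is empty")
  if (anyNA(wavelengths) || anyNA(values)) stop("spectrum contains NA")
  if (any(wavelengths <= 0)) stop("wavelengths must be positive (nm)")
  if (anyDuplicated(wavelengths)) stop("duplicate wavelengths in spectrum")
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]; values <- values[ord]
  if (kind %in% c("absorbance", "extinction") && any(values < 0))
    stop(kind, " values must be nonnegative")
  out <- data.frame(wavelength = wavelengths, value = values)
  class(out) <- c("spectrum", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.7g-%.7g nm>\n",
              spectrum_kind(x), nrow(x), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Kind of a spectrum
#' @param x A `spectrum`.
#' @return `"absorbance"`, `"extinction"` or `"emission"`.
#' @export
spectrum_kind <- function(x) attr(x, "kind")

stopifnot_spectrum <- function(x, kind = NULL, arg = deparse(substitute(x))) {
  if (!inherits(x, "spectrum")) stop(arg, " is not a spectrum")
  if (!is.null(kind) && spectrum_kind(x) != kind)
    stop(arg, " must have kind '", kind, "', got '", spectrum_kind(x), "'")
  invisible(x)
}

#' Read a spectrum from a two-column text file
#'
#' Parses plain text with two numeric columns (wavelength in nm, value),
#' separated by commas and/or whitespace. Lines starting with `#` and blank
#' lines are ignored. Rows are sorted by wavelength; duplicate wavelengths
#' are an error.
#'
#' @param path Path to the file.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("absorbance", "extinction", "emission")) {
  kind <- match.arg(kind)
  tab <- read_two_column(path, min_cols = 2L, max_cols = 2L)
  spectrum(tab[[1L]], tab[[2L]], kind = kind)
}

#' Write a spectrum to a two-column text file
#'
#' Emits the same dialect [read_spectrum()] consumes: a `#` header comment
#' recording the kind, then whitespace-separated wavelength/value rows.
#'
#' @param x A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot_spectrum(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# kind: %s", spectrum_kind(x)), con)
  writeLines(sprintf("%.10g %.10g", x$wavelength, x$value), con)
  invisible(path)
}

# Shared numeric-table parser: comma/whitespace delimited, '#' comments.
# Returns a list of numeric columns; errors name the offending line.
read_two_column <- function(path, min_cols = 1L, max_cols = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty file: ", path)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop("non-numeric data at line ", i, " of ", path, ": '", lines[i], "'")
    if (length(vals) < min_cols || length(vals) > max_cols)
      stop("expected ", min_cols, "-", max_cols, " columns at line ", i,
           " of ", path)
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) stop("inconsistent column count in ", path)
  lapply(seq_len(ncols[[1L]]), function(j) vapply(rows, `[[`, numeric(1), j))
}

#' Resample two spectra onto a shared wavelength grid
#'
#' Linearly interpolates both spectra onto the grid
#' `seq(max(min_a, min_b), min(max_a, max_b), by = step)`. Values are never
#' extrapolated outside a spectrum's original support.
#'
#' @param a,b `spectrum` objects with overlapping wavelength ranges.
#' @param step Grid step in nm (default 1).
#' @return A list with elements `a` and `b`, both on the shared grid.
#' @export
resample_common_grid <- function(a, b, step = 1) {
  stopifnot_spectrum(a); stopifnot_spectrum(b)
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  lo <- max(min(a$wavelength), min(b$wavelength))
  hi <- min(max(a$wavelength), max(b$wavelength))
  if (lo > hi) stop("no spectral overlap between the two wavelength ranges")
  grid <- seq(lo, hi, by = step)
  interp <- function(s) {
    if (nrow(s) == 1L) v <- rep(s$value, length(grid))
    else v <- stats::approx(s$wavelength, s$value, xout = grid, rule = 1)$y
    spectrum(grid, v, kind = spectrum_kind(s))
  }
  list(a = interp(a), b = interp(b))
}

#' Spectral overlap integral J
#'
#' Computes the Foerster overlap integral
#' \deqn{J = \int F_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\, d\lambda,}
#' with the donor emission \eqn{F_D} area-normalised to unit integral over the
#' shared grid, by trapezoidal quadrature. With extinction in M^-1 cm^-1 and
#' wavelength in nm, J is in M^-1 cm^-1 nm^4.
#'
#' @param donor_emission Emission `spectrum` of the donor (nonnegative, with
#'   positive area on the shared grid).
#' @param acceptor_extinction Molar-extinction `spectrum` of the acceptor.
#' @param step Quadrature grid step in nm (default 1).
#' @return A list of class `overlap_integral` with elements `J`
#'   (M^-1 cm^-1 nm^4) and `wavelength_range` (the nm interval integrated).
#' @examples
#' d <- spectrum(540:550, rep(1, 11), "emission")
#' e <- spectrum(540:550, rep(1e5, 11), "extinction")
#' overlap_integral(d, e)$J  # ~ 1e5 * mean(lambda^4)
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction, step = 1) {
  stopifnot_spectrum(donor_emission, "emission")
  stopifnot_spectrum(acceptor_extinction, "extinction")
  if (any(donor_emission$value < 0))
    stop("donor emission must be nonnegative")
  rs <- resample_common_grid(donor_emission, acceptor_extinction, step = step)
  lam <- rs$a$wavelength
  area <- pracma::trapz(lam, rs$a$value)
  if (area <= 0)
    stop("donor emission has zero area on the shared grid")
  fd <- rs$a$value / area
  J <- pracma::trapz(lam, fd * rs$b$value * lam^4)
  structure(list(J = J, wavelength_range = range(lam)),
            class = "overlap_integral")
}

#' @export
print.overlap_integral <- function(x, ...) {
  cat(sprintf("J = %.6g M^-1 cm^-1 nm^4 (integrated %.7g-%.7g nm)\n",
              x$J, x$wavelength_range[1], x$wavelength_range[2]))
  invisible(x)
}

#' Correct an emission spectrum for reabsorption (inner-filter effect)
#'
#' At high sample concentration the emitted light is reabsorbed on its way out
#' of the cuvette, distorting the short-wavelength side of the emission band.
#' Taking the emission path from the centre of the cuvette, the corrected
#' intensity is \eqn{I_{corr}(\lambda) = I(\lambda)\, 10^{D(\lambda)/2}},
#' where D is the optical density at the emission wavelength.
#'
#' @param measured Emission `spectrum` as measured.
#' @param absorbance Absorbance `spectrum` of the same sample (optical density,
#'   nonnegative). Internally resampled onto the shared grid.
#' @param step Resampling step in nm (default 1).
#' @return The corrected emission `spectrum` on the shared grid.
#' @export
inner_filter_correct <- function(measured, absorbance, step = 1) {
  stopifnot_spectrum(measured, "emission")
  stopifnot_spectrum(absorbance, "absorbance")
  if (any(absorbance$value < 0)) stop("optical density must be nonnegative")
  rs <- resample_common_grid(measured, absorbance, step = step)
  spectrum(rs$a$wavelength, rs$a$value * 10^(rs$b$value / 2), kind = "emission")
}

#' Subtract a photobleached-control spectrum
#'
#' Pointwise difference of two emission spectra on their shared grid, used to
#' isolate the sensitized acceptor emission by removing the donor-only signal
#' measured on a sample whose acceptor chromophore was photobleached.
#' Negative residuals (noise artifacts) are clamped to zero; the number of
#' clamped points is recorded in attribute `n_clamped`.
#'
#' @param full Emission `spectrum` of the intact sample.
#' @param bleached Emission `spectrum` of the photobleached control.
#' @param step Resampling step in nm (default 1).
#' @return An emission `spectrum`; `attr(, "n_clamped")` counts clamped points.
#' @export
subtract_spectra <- function(full, bleached, step = 1) {
  stopifnot_spectrum(full, "emission")
  stopifnot_spectrum(bleached, "emission")
  rs <- resample_common_grid(full, bleached, step = step)
  diff <- rs$a$value - rs$b$value
  n_clamped <- sum(diff < 0)
  out <- spectrum(rs$a$wavelength, pmax(diff, 0), kind = "emission")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Intensity of a spectrum at a wavelength
#'
#' Linear interpolation within the spectrum's support; no extrapolation.
#'
#' @param x A `spectrum`.
#' @param wavelength Wavelength in nm, inside the spectrum's range.
#' @return Interpolated value.
#' @export
spectrum_at <- function(x, wavelength) {
  stopifnot_spectrum(x)
  if (wavelength < min(x$wavelength) || wavelength > max(x$wavelength))
    stop("wavelength ", wavelength, " nm outside spectrum support")
  if (nrow(x) == 1L) return(x$value)
  stats::approx(x$wavelength, x$value, xout = wavelength, rule = 1)$y
}
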