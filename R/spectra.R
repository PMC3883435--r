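# UV-Vis spectrum handling: peak (lambda-max) detection at grid resolution,
# control-vs-treated peak shifts, interpolated absorbance at a fixed
# wavelength, and absorbance-vs-concentration calibration.

#' Construct a spectrum
#'
#' @param wavelengths Strictly increasing numeric grid, nm (>= 3 points).
#' @param absorbances Numeric absorbances, AU, same length.
#' @param sample_id Sample identifier.
#' @param analyte Analyte name (or NA).
#' @param concentration Analyte concentration, mM (or NA for controls it
#'   is conventionally 0).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, absorbances, sample_id = NA_character_,
                     analyte = NA_character_, concentration = NA_real_) {
  if (length(wavelengths) < 3L) {
    stop("a spectrum needs at least 3 grid points", call. = FALSE)
  }
  if (length(wavelengths) != length(absorbances)) {
    stop("'wavelengths' and 'absorbances' differ in length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  }
  structure(list(
    wavelengths = as.numeric(wavelengths),
    absorbances = as.numeric(absorbances),
    sample_id = as.character(sample_id),
    analyte = as.character(analyte),
    concentration = as.numeric(concentration)
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %s (%s, %g mM): %d points, %g-%g nm\n",
    x$sample_id, x$analyte, x$concentration, length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read spectra from a long-format CSV
#'
#' Expected columns: `sample_id,analyte,concentration_mM,wavelength_nm,absorbance`.
#' Rows are grouped by `sample_id` (one spectrum each) and sorted by
#' wavelength; a duplicated (sample, wavelength) pair is a data error.
#'
#' @param path CSV file path.
#' @return Named list of [spectrum()] objects, one per sample id.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("spectra file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "analyte", "concentration_mM", "wavelength_nm",
           "absorbance")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("spectra file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$wavelength_nm), ]
    if (anyDuplicated(g$wavelength_nm)) {
      stop(sprintf("sample '%s' has duplicated wavelength(s): %s",
                   g$sample_id[1],
                   paste(unique(g$wavelength_nm[duplicated(g$wavelength_nm)]),
                         collapse = ", ")), call. = FALSE)
    }
    spectrum(g$wavelength_nm, g$absorbance, sample_id = g$sample_id[1],
             analyte = g$analyte[1], concentration = g$concentration_mM[1])
  })
  out[unique(df$sample_id)]
}

#' Write spectra to a long-format CSV
#'
#' @param spectra List of [spectrum()] objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  rows <- dplyr::bind_rows(lapply(spectra, function(s) {
    data.frame(sample_id = s$sample_id, analyte = s$analyte,
               concentration_mM = s$concentration,
               wavelength_nm = s$wavelengths, absorbance = s$absorbances)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

window_mask <- function(s, window) {
  if (is.null(window)) return(rep(TRUE, length(s$wavelengths)))
  if (length(window) != 2L || window[1] > window[2]) {
    stop("'window' must be (lo, hi) with lo <= hi", call. = FALSE)
  }
  keep <- s$wavelengths >= window[1] & s$wavelengths <= window[2]
  if (!any(keep)) {
    stop(sprintf("window [%g, %g] nm does not overlap the %g-%g nm grid",
                 window[1], window[2], min(s$wavelengths),
                 max(s$wavelengths)), call. = FALSE)
  }
  keep
}

#' Wavelength of maximum absorbance
#'
#' Grid-resolution argmax of the absorbance within an optional wavelength
#' window — no smoothing, no sub-grid interpolation (peak shifts are
#' reported at grid resolution, matching integer-nm shift conventions).
#' Ties break to the lowest wavelength.
#'
#' @param s A [spectrum()].
#' @param window Optional `c(lo, hi)` in nm; must overlap the grid.
#' @return List of class `peak_result`: `lambda_max` (nm, on the grid) and
#'   `a_max` (AU, the stored absorbance there).
#' @export
find_lambda_max <- function(s, window = NULL) {
  stopifnot(inherits(s, "spectrum"))
  keep <- window_mask(s, window)
  wl <- s$wavelengths[keep]
  ab <- s$absorbances[keep]
  i <- which.max(ab)  # first maximum = lowest wavelength on ties
  structure(list(lambda_max = wl[i], a_max = ab[i]), class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak_result> lambda_max = %g nm, A = %g AU\n",
              x$lambda_max, x$a_max))
  invisible(x)
}

#' Peak shift between a control and a treated spectrum
#'
#' `delta_lambda = lambda_max(treated) - lambda_max(control)`; positive
#' values are red (bathochromic) shifts, negative values blue shifts.
#'
#' @param control,treated [spectrum()] objects.
#' @param window Optional `c(lo, hi)` nm window passed to
#'   [find_lambda_max()].
#' @return List of class `shift_result` with `delta_lambda` (nm) and the
#'   two peak results.
#' @examples
#' sc <- ketamine_spectrum_scenario(noise_sd = 0)
#' ctl <- generate_spectrum(sc, "ketamine", 0, seed = 1)
#' trt <- generate_spectrum(sc, "ketamine", 90, seed = 1)
#' peak_shift(ctl, trt, window = c(450, 600))  # +4 nm red shift
#' @export
peak_shift <- function(control, treated, window = NULL) {
  pc <- find_lambda_max(control, window)
  pt <- find_lambda_max(treated, window)
  structure(list(
    delta_lambda = pt$lambda_max - pc$lambda_max,
    control = pc, treated = pt
  ), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  dir <- if (x$delta_lambda > 0) "red" else if (x$delta_lambda < 0) "blue"
         else "no"
  cat(sprintf("<shift_result> %+g nm (%s shift): %g -> %g nm\n",
              x$delta_lambda, dir, x$control$lambda_max,
              x$treated$lambda_max))
  invisible(x)
}

#' Absorbance at a fixed wavelength
#'
#' Linear interpolation between the bracketing grid points; an exact grid
#' hit returns the stored value. Queries outside the grid span are an
#' error (no extrapolation).
#'
#' @param s A [spectrum()].
#' @param lambda Query wavelength, nm.
#' @return Absorbance in AU.
#' @export
absorbance_at <- function(s, lambda) {
  stopifnot(inherits(s, "spectrum"))
  if (lambda < min(s$wavelengths) || lambda > max(s$wavelengths)) {
    stop(sprintf("wavelength %g nm is outside the %g-%g nm grid span ",
                 lambda, min(s$wavelengths), max(s$wavelengths)),
         "(extrapolation is not supported)", call. = FALSE)
  }
  hit <- which(s$wavelengths == lambda)
  if (length(hit)) return(s$absorbances[hit[1]])
  stats::approx(s$wavelengths, s$absorbances, xout = lambda)$y
}

#' Point-wise average of replicate spectra
#'
#' Replicates must share an identical wavelength grid; averaging across
#' differing grids would silently regrid and is refused.
#'
#' @param spectra List of [spectrum()] objects on one common grid.
#' @return A [spectrum()] with the mean absorbance at each grid point.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(wl) || any(s$wavelengths != wl)) {
      stop("replicate spectra are on different wavelength grids; ",
           "regrid before averaging", call. = FALSE)
    }
  }
  ab <- rowMeans(vapply(spectra, function(s) s$absorbances,
                        numeric(length(wl))))
  spectrum(wl, ab,
           sample_id = paste0("mean_of_", length(spectra)),
           analyte = spectra[[1]]$analyte,
           concentration = spectra[[1]]$concentration)
}

#' Absorbance-vs-concentration standard curve
#'
#' Extracts the absorbance at `lambda` from every spectrum, averages the
#' replicates at each concentration, and fits the same unweighted linear
#' standard curve used for color differences ([fit_standard_curve()]).
#' For an absorbance quenched by analyte binding the slope and `r` are
#' negative.
#'
#' @param spectra List of [spectrum()] objects with `concentration` set;
#'   at least two distinct concentrations.
#' @param lambda Wavelength (nm) at which absorbance is read.
#' @return A `standard_curve` whose `mean_delta` column holds mean
#'   absorbance (AU).
#' @export
fit_absorbance_curve <- function(spectra, lambda) {
  stopifnot(length(spectra) >= 2L)
  raw <- data.frame(
    concentration = vapply(spectra, function(s) s$concentration, numeric(1)),
    delta = vapply(spectra, absorbance_at, numeric(1), lambda = lambda)
  )
  if (anyNA(raw$concentration)) {
    stop("every spectrum needs a concentration for calibration",
         call. = FALSE)
  }
  pts <- average_replicates(raw)
  fit_standard_curve(pts, slot = sprintf("A@%gnm", lambda))
}
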