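# Linear standard curves: replicate averaging, unweighted OLS on the
# per-concentration means, and inverse prediction of unknown concentrations
# with a first-order (delta-method) interval.

#' Average replicate differences into calibration points
#'
#' Collapses a replicate table (e.g. 3 plates x 3 assays = 9 differences
#' per concentration) into one calibration point per distinct
#' concentration: the mean signed difference, its sample standard
#' deviation (n - 1 denominator) and the replicate count.
#'
#' @param raw Data frame with a concentration column (`concentration_mM`
#'   or `concentration`) and a response column (`delta` or `absorbance`).
#'   Other columns (`plate`, `assay`, slot identifiers, ...) are ignored.
#' @return Tibble of calibration points: `concentration`, `mean_delta`,
#'   `sd_delta`, `n`, sorted by concentration.
#' @export
average_replicates <- function(raw) {
  raw <- as.data.frame(raw)
  if (nrow(raw) == 0L) stop("replicate table is empty", call. = FALSE)
  conc_col <- intersect(c("concentration_mM", "concentration"), names(raw))[1]
  val_col <- intersect(c("delta", "absorbance"), names(raw))[1]
  if (is.na(conc_col) || is.na(val_col)) {
    stop("replicate table needs a concentration column and a ",
         "'delta' (or 'absorbance') column", call. = FALSE)
  }
  conc <- raw[[conc_col]]
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  grp <- split(raw[[val_col]], conc)
  pts <- tibble::tibble(
    concentration = as.numeric(names(grp)),
    mean_delta = unname(vapply(grp, mean, numeric(1))),
    sd_delta = unname(vapply(grp, function(v) {
      if (length(v) > 1L) stats::sd(v) else 0
    }, numeric(1))),
    n = unname(vapply(grp, length, integer(1)))
  )
  pts[order(pts$concentration), ]
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of the mean response on concentration —
#' unweighted, on the per-concentration means, matching the protocol of
#' averaging replicate differences before plotting them against
#' concentration. The reported `r` is the signed Pearson correlation of
#' the (concentration, mean) pairs; for a decreasing response (e.g.
#' absorbance quenching) `r` is negative and `|r|` is the quantity
#' comparable to a quoted "R = 0.99".
#'
#' @param points Calibration points from [average_replicates()] (columns
#'   `concentration`, `mean_delta`; `sd_delta`/`n` carried through if
#'   present), with at least two distinct concentrations.
#' @param slot Optional (sensor, condition, channel) label for the fitted
#'   channel, carried into outputs.
#' @return An object of class `standard_curve`: `slope` (response units
#'   per mM), `intercept`, `r`, `points`, `slot`, and the residual
#'   standard error `sigma` with its degrees of freedom `df`.
#' @examples
#' pts <- tibble::tibble(concentration = c(10, 25, 50, 100),
#'                       mean_delta = 50 * c(10, 25, 50, 100))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, slot = NULL) {
  points <- as.data.frame(points)
  if (!all(c("concentration", "mean_delta") %in% names(points))) {
    stop("'points' needs columns 'concentration' and 'mean_delta'",
         call. = FALSE)
  }
  if (length(unique(points$concentration)) < 2L) {
    stop("standard curve needs at least 2 distinct concentrations ",
         "(degenerate design)", call. = FALSE)
  }
  fit <- stats::lm(mean_delta ~ concentration, data = points)
  df <- fit$df.residual
  sigma <- if (df >= 1L) sqrt(sum(stats::residuals(fit)^2) / df) else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)["concentration"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    # r is undefined for a perfectly flat response; report NA, not a warning
    r = if (stats::sd(points$mean_delta) == 0) NA_real_ else
      stats::cor(points$concentration, points$mean_delta),
    sigma = sigma,
    df = df,
    points = tibble::as_tibble(points),
    slot = slot
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> delta = %.6g * c + %.6g  (r = %.4f, %d points%s)\n",
    x$slope, x$intercept, x$r, nrow(x$points),
    if (is.null(x$slot)) "" else paste0(", slot ", paste(x$slot, collapse = "/"))))
  invisible(x)
}

degeneracy_tol <- function(curve) {
  1e-9 * max(1, diff(range(curve$points$mean_delta)))
}

#' Estimate a concentration from an observed response
#'
#' Inverts the standard curve: `c_hat = (delta_obs - intercept) / slope`.
#' The confidence interval comes from first-order propagation of the OLS
#' residual standard error through the inverse prediction formula
#' (classical calibration interval for one new observation):
#' `se(c_hat) = (sigma / |m|) * sqrt(1 + 1/n + (c_hat - mean(c))^2 / Sxx)`,
#' with a Student-t quantile on the fit's residual degrees of freedom.
#' With fewer than three calibration points (or a perfect fit) the
#' residual scale is zero and the interval collapses onto `c_hat`.
#'
#' @param curve A [fit_standard_curve()] result with non-degenerate slope.
#' @param delta_obs Observed response (color-sum units or AU).
#' @param confidence Coverage fraction, default 0.95.
#' @return An object of class `concentration_estimate`: `c_hat` (mM),
#'   `interval` (`low`, `high`), `confidence`.
#' @examples
#' pts <- tibble::tibble(concentration = c(10, 25, 50, 100),
#'                       mean_delta = 50 * c(10, 25, 50, 100))
#' estimate_concentration(fit_standard_curve(pts), delta_obs = 2500)
#' @export
estimate_concentration <- function(curve, delta_obs, confidence = 0.95) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  }
  if (abs(curve$slope) < degeneracy_tol(curve)) {
    stop("flat standard curve: |slope| below degeneracy tolerance, ",
         "concentration is not identifiable", call. = FALSE)
  }
  c_hat <- (delta_obs - curve$intercept) / curve$slope
  x <- curve$points$concentration
  sxx <- sum((x - mean(x))^2)
  if (curve$df >= 1L && is.finite(curve$sigma) && curve$sigma > 0) {
    se <- (curve$sigma / abs(curve$slope)) *
      sqrt(1 + 1 / length(x) + (c_hat - mean(x))^2 / sxx)
    half <- stats::qt((1 + confidence) / 2, df = curve$df) * se
  } else {
    half <- 0
  }
  structure(list(
    c_hat = c_hat,
    interval = c(low = c_hat - half, high = c_hat + half),
    confidence = confidence
  ), class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> %.4g mM  [%.4g, %.4g] at %d%%\n",
              x$c_hat, x$interval["low"], x$interval["high"],
              round(100 * x$confidence)))
  invisible(x)
}

#' Read a replicate difference table from CSV
#'
#' Expected columns: `concentration_mM,plate,assay,sensor,condition,channel,delta`
#' (extra columns pass through; only `concentration_mM` and `delta` are
#' required).
#'
#' @param path CSV file path.
#' @return Tibble of replicate rows.
#' @export
read_replicates <- function(path) {
  if (!file.exists(path)) stop("replicates file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration_mM", "delta") %in% names(df))) {
    stop("replicates file needs columns 'concentration_mM' and 'delta'",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Standard-curve JSON I/O
#'
#' Curves serialize as `{slot, slope, intercept, r, points: [...]}`.
#'
#' @param curve A `standard_curve`.
#' @param path JSON file path.
#' @return `write_curve()`: `path` invisibly; `read_curve()`: the curve.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "standard_curve"))
  jsonlite::write_json(list(
    slot = curve$slot, slope = curve$slope, intercept = curve$intercept,
    r = curve$r, sigma = curve$sigma, df = curve$df,
    points = as.data.frame(curve$points)
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE,
  null = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- c("slope", "intercept", "r", "points")
  missing_keys <- setdiff(req, names(j))
  if (length(missing_keys)) {
    stop("curve file is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  structure(list(
    slope = j$slope, intercept = j$intercept, r = j$r,
    sigma = j$sigma %||% NA_real_, df = j$df %||% 0L,
    points = tibble::as_tibble(j$points),
    slot = if (is.null(j$slot) || !length(j$slot)) NULL else j$slot
  ), class = "standard_curve")
}
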