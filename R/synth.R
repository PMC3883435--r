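# Seeded synthetic generators: plate scans whose analyte wells respond
# linearly in chosen channels, replicate difference tables, and Gaussian
# absorbance bands whose height and center move linearly with
# concentration. These give every pipeline stage a ground truth to be
# tested against without any instrument data.

#' Plate-scan scenario
#'
#' Defines how a synthetic plate responds to an analyte: a linear
#' color-sum response `delta = slope * concentration` for each responsive
#' (sensor, condition, channel) slot, a uniform baseline control color,
#' and i.i.d. Gaussian per-pixel noise.
#'
#' @param responses Data frame with columns `sensor`, `condition`,
#'   `channel` (`"R"/"G"/"B"`) and `slope` (color-sum units per mM).
#'   Slots not listed do not respond.
#' @param baseline Length-3 per-pixel control color `(R, G, B)`, within
#'   the channel range.
#' @param pixel_noise_sd Per-pixel additive Gaussian noise sd (channel
#'   units, >= 0).
#' @param concentrations Default concentration series, mM.
#' @param bit_depth Channel bit depth of rendered images (8 or 16).
#' @return An object of class `plate_scenario`.
#' @export
plate_scenario <- function(responses, baseline = c(180, 160, 140),
                           pixel_noise_sd = 0,
                           concentrations = c(10, 25, 50, 62.5, 80, 100),
                           bit_depth = 8L) {
  req <- c("sensor", "condition", "channel", "slope")
  missing_cols <- setdiff(req, names(responses))
  if (length(missing_cols)) {
    stop("'responses' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(responses$channel %in% CHANNELS)) {
    stop("'channel' must be one of R, G, B", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16",
                                       call. = FALSE)
  maxval <- 2^bit_depth - 1
  if (length(baseline) != 3L || any(baseline < 0) || any(baseline > maxval)) {
    stop(sprintf("'baseline' must be 3 channel values in [0, %d]", maxval),
         call. = FALSE)
  }
  if (pixel_noise_sd < 0) stop("'pixel_noise_sd' must be >= 0", call. = FALSE)
  structure(list(
    responses = tibble::as_tibble(responses[req]),
    baseline = as.numeric(baseline),
    pixel_noise_sd = as.numeric(pixel_noise_sd),
    concentrations = as.numeric(concentrations),
    bit_depth = as.integer(bit_depth)
  ), class = "plate_scenario")
}

#' @export
print.plate_scenario <- function(x, ...) {
  cat(sprintf(
    "<plate_scenario> %d responsive slot(s), baseline (%g, %g, %g), noise sd %g\n",
    nrow(x$responses), x$baseline[1], x$baseline[2], x$baseline[3],
    x$pixel_noise_sd))
  invisible(x)
}

#' Default ketamine plate scenario
#'
#' Emulates the sensing-array response to ketamine over the assayed
#' 10-100 mM series: the DC1 green channel responds at 50 color-sum units
#' per mM (the channel used for the headline standard curve), DC2 blue at
#' 45 and DC3 green at 30 units per mM — the other channels reported to
#' track concentration linearly. The slopes keep every slot's response
#' clear of the renderer's per-pixel rounding band around the significance
#' threshold at all assayed concentrations, so rendered digits equal the
#' ideal noiseless digits. Baseline control color (180, 160, 140),
#' noiseless by default.
#'
#' @param pixel_noise_sd Per-pixel noise sd, default 0.
#' @return A [plate_scenario()].
#' @export
ketamine_plate_scenario <- function(pixel_noise_sd = 0) {
  plate_scenario(
    responses = data.frame(
      sensor = c("DC1", "DC2", "DC3"),
      condition = 1L,
      channel = c("G", "B", "G"),
      slope = c(50, 45, 30)
    ),
    baseline = c(180, 160, 140),
    pixel_noise_sd = pixel_noise_sd,
    concentrations = c(10, 25, 50, 62.5, 80, 100)
  )
}

scenario_slope <- function(scenario, sensor, condition, channel) {
  r <- scenario$responses
  hit <- r$sensor == sensor & r$condition == condition & r$channel == channel
  if (any(hit)) sum(r$slope[hit]) else 0
}

#' Expected noiseless code of a scenario
#'
#' The code a plate rendered from `scenario` at `concentration` produces
#' when pixel noise is zero: digit 1 wherever
#' `|slope * concentration| >= threshold`. Useful for building code
#' libraries for synthetic identification experiments.
#'
#' @param scenario A [plate_scenario()].
#' @param layout A [plate_layout()] providing the slot order.
#' @param concentration Analyte concentration, mM.
#' @param config A [coding_config()].
#' @return A [binary_code()].
#' @export
scenario_expected_code <- function(scenario, layout, concentration,
                                   config = coding_config()) {
  slots <- code_slots(layout)
  slopes <- mapply(scenario_slope, slots$sensor, slots$condition,
                   slots$channel, MoreArgs = list(scenario = scenario))
  binary_code(digit_from_difference(slopes * concentration, config),
              ordering_id(layout))
}

#' Render a synthetic plate scan
#'
#' Control wells (and the background) are painted at the scenario's
#' baseline color. Each analyte well's responsive channels are shifted per
#' pixel by `round(slope * concentration / pixel_count)`, so the ROI total
#' difference approximates `slope * concentration` up to the rounding of
#' the per-pixel shift. Gaussian per-pixel noise is then added to the
#' whole image, rounded and clipped to the channel range. Fully
#' reproducible for a given seed.
#'
#' @param scenario A [plate_scenario()].
#' @param layout A [plate_layout()].
#' @param concentration Analyte concentration, mM.
#' @param seed Integer seed; all randomness flows through it (the global
#'   RNG state is untouched).
#' @return A [plate_image()].
#' @export
render_plate <- function(scenario, layout, concentration, seed) {
  stopifnot(inherits(scenario, "plate_scenario"),
            inherits(layout, "plate_layout"))
  maxval <- 2^scenario$bit_depth - 1
  pad <- ceiling(min(layout$pitch) / 2)
  width <- ceiling(layout$origin[1] + (layout$n_cols - 1) * layout$pitch[1]) +
    pad + 1
  height <- ceiling(layout$origin[2] + (layout$n_rows - 1) * layout$pitch[2]) +
    pad + 1
  px <- array(0, dim = c(height, width, 3L))
  for (k in 1:3) px[, , k] <- scenario$baseline[k]

  pixel_count <- nrow(roi_offsets(layout$roi))
  hw <- floor(min(layout$pitch) / 2) - 1  # painted patch half-width
  wells <- layout$wells
  for (i in which(wells$role == "analyte")) {
    ctr <- round(well_center(layout, wells$well[i]))
    xs <- (ctr[1] - hw):(ctr[1] + hw) + 1L
    ys <- (ctr[2] - hw):(ctr[2] + hw) + 1L
    for (k in 1:3) {
      m <- scenario_slope(scenario, wells$sensor[i], wells$condition[i],
                          CHANNELS[k])
      shift <- round(m * concentration / pixel_count)
      val <- scenario$baseline[k] - shift
      if (val < 0 || val > maxval) {
        stop(sprintf(
          "scenario error: shifted mean %g for well %s channel %s is outside [0, %d]",
          val, wells$well[i], CHANNELS[k], maxval), call. = FALSE)
      }
      px[ys, xs, k] <- val
    }
  }
  if (scenario$pixel_noise_sd > 0) {
    px <- withr::with_seed(seed, {
      px + stats::rnorm(length(px), 0, scenario$pixel_noise_sd)
    })
  }
  plate_image(pmin(pmax(round(px), 0), maxval), bit_depth = scenario$bit_depth)
}

#' Write a plate image to PNG or TIFF
#'
#' 8-bit images may go to either format; 16-bit images are written as
#' TIFF (16 bits per sample).
#'
#' @param img A [plate_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(img, path) {
  stopifnot(inherits(img, "plate_image"))
  norm <- img$pixels / (2^img$bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (img$bit_depth != 8L) {
      stop("16-bit images must be written as TIFF", call. = FALSE)
    }
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = img$bit_depth)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Generate a replicate difference table
#'
#' Draws `n_plates * n_assays` replicate differences per concentration and
#' responsive slot: `delta = slope * c + eps`, `eps ~ Normal(0,
#' sigma_delta)`. With the default 3 plates x 3 assays this reproduces the
#' nine-differences-per-point replication scheme of the assay protocol.
#'
#' @param scenario A [plate_scenario()].
#' @param n_plates,n_assays Replication structure (defaults 3 x 3).
#' @param seed Integer seed.
#' @param concentrations Concentration series, mM (defaults to the
#'   scenario's).
#' @param sigma_delta Noise sd of a single replicate difference, color-sum
#'   units. Default `pixel_noise_sd * sqrt(2 * pixel_count)` — the sd of a
#'   difference of two ROI sums of i.i.d. per-pixel noise.
#' @param pixel_count ROI pixel count used to derive `sigma_delta`;
#'   default the radius-10 disk (317 px).
#' @return Tibble with columns `concentration_mM`, `plate`, `assay`,
#'   `sensor`, `condition`, `channel`, `delta`.
#' @export
generate_difference_table <- function(scenario, n_plates = 3L, n_assays = 3L,
                                      seed,
                                      concentrations = scenario$concentrations,
                                      sigma_delta = NULL,
                                      pixel_count = NULL) {
  stopifnot(inherits(scenario, "plate_scenario"))
  if (n_plates < 1L || n_assays < 1L) {
    stop("'n_plates' and 'n_assays' must be >= 1", call. = FALSE)
  }
  if (is.null(sigma_delta)) {
    if (is.null(pixel_count)) {
      pixel_count <- nrow(roi_offsets(roi_spec("disk", 10)))
    }
    sigma_delta <- scenario$pixel_noise_sd * sqrt(2 * pixel_count)
  }
  resp <- scenario$responses
  grid <- expand.grid(
    assay = seq_len(n_assays), plate = seq_len(n_plates),
    slot = seq_len(nrow(resp)), concentration_mM = concentrations,
    KEEP.OUT.ATTRS = FALSE
  )
  eps <- if (sigma_delta > 0) {
    withr::with_seed(seed, stats::rnorm(nrow(grid), 0, sigma_delta))
  } else {
    numeric(nrow(grid))
  }
  tibble::tibble(
    concentration_mM = grid$concentration_mM,
    plate = grid$plate, assay = grid$assay,
    sensor = resp$sensor[grid$slot],
    condition = resp$condition[grid$slot],
    channel = resp$channel[grid$slot],
    delta = resp$slope[grid$slot] * grid$concentration_mM + eps
  )
}

#' Absorbance-spectrum scenario
#'
#' A single Gaussian absorbance band whose height and center wavelength
#' move linearly with analyte concentration:
#' `A(lambda) = (a0 + a_slope * c) * exp(-(lambda - (lambda0 +
#' lambda_slope * c))^2 / (2 * width^2)) + eps`, with i.i.d. Gaussian
#' noise `eps` on each grid point.
#'
#' @param lambda0 Band center at 0 mM, nm.
#' @param lambda_slope Center displacement, nm per mM (positive = red
#'   shift with concentration).
#' @param a0 Peak absorbance at 0 mM, AU.
#' @param a_slope Peak-absorbance change, AU per mM (negative =
#'   quenching).
#' @param width Gaussian band sd, nm (> 0).
#' @param noise_sd Per-point absorbance noise sd, AU (>= 0).
#' @param grid `c(lo, hi, step)` wavelength grid, nm.
#' @param concentrations Default concentration series, mM.
#' @return An object of class `spectrum_scenario`.
#' @export
spectrum_scenario <- function(lambda0 = 516, lambda_slope = 4 / 90,
                              a0 = 1.05, a_slope = -0.39 / 90,
                              width = 30, noise_sd = 0,
                              grid = c(400, 700, 1),
                              concentrations = c(5, 10, 20, 30, 45, 60, 80, 90)) {
  if (width <= 0) stop("'width' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (length(grid) != 3L || grid[3] <= 0 || grid[1] >= grid[2]) {
    stop("'grid' must be c(lo, hi, step) with lo < hi and step > 0",
         call. = FALSE)
  }
  structure(list(
    lambda0 = lambda0, lambda_slope = lambda_slope,
    a0 = a0, a_slope = a_slope, width = width, noise_sd = noise_sd,
    grid = as.numeric(grid), concentrations = as.numeric(concentrations)
  ), class = "spectrum_scenario")
}

#' @export
print.spectrum_scenario <- function(x, ...) {
  cat(sprintf(
    "<spectrum_scenario> band %g nm %+g nm/mM, peak %g AU %+g AU/mM, width %g nm, noise %g AU\n",
    x$lambda0, x$lambda_slope, x$a0, x$a_slope, x$width, x$noise_sd))
  invisible(x)
}

#' Default ketamine UV-Vis scenario
#'
#' Anchored to the printed endpoints of the DC1/ketamine titration: band
#' center 516 nm at 0 mM moving to 520 nm at 90 mM (+4/90 nm per mM), peak
#' absorbance 1.05 AU at 0 mM falling to 0.66 AU at 90 mM (-0.39/90 AU per
#' mM), linear in between. Band width 30 nm, 400-700 nm grid at 1 nm,
#' UV-Vis concentration series 5-90 mM.
#'
#' @param noise_sd Per-point absorbance noise sd, AU (default 0).
#' @return A [spectrum_scenario()].
#' @export
ketamine_spectrum_scenario <- function(noise_sd = 0) {
  spectrum_scenario(noise_sd = noise_sd)
}

# deterministic small-integer seed mix for (seed, concentration, replicate)
mix_seed <- function(seed, concentration, replicate) {
  as.integer((as.numeric(seed) * 1000003 + replicate * 7919 +
                round(concentration * 100) * 104729) %% 2147483647)
}

#' Generate a synthetic absorbance spectrum
#'
#' @param scenario A [spectrum_scenario()].
#' @param analyte Analyte name recorded in the metadata.
#' @param concentration Concentration, mM.
#' @param replicate Replicate index (distinct replicates get independent
#'   noise under the same `seed`).
#' @param seed Integer seed.
#' @return A [spectrum()].
#' @examples
#' sc <- ketamine_spectrum_scenario()
#' s <- generate_spectrum(sc, "ketamine", 90, seed = 1)
#' find_lambda_max(s, window = c(450, 600))  # 520 nm, 0.66 AU
#' @export
generate_spectrum <- function(scenario, analyte, concentration,
                              replicate = 1L, seed) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  wl <- seq(scenario$grid[1], scenario$grid[2], by = scenario$grid[3])
  center <- scenario$lambda0 + scenario$lambda_slope * concentration
  height <- scenario$a0 + scenario$a_slope * concentration
  ab <- height * exp(-(wl - center)^2 / (2 * scenario$width^2))
  if (scenario$noise_sd > 0) {
    ab <- ab + withr::with_seed(
      mix_seed(seed, concentration, replicate),
      stats::rnorm(length(wl), 0, scenario$noise_sd))
  }
  spectrum(wl, ab,
           sample_id = sprintf("%s_c%g_r%d", analyte, concentration,
                               as.integer(replicate)),
           analyte = analyte, concentration = concentration)
}
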