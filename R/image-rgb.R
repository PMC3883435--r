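# Reading plate scans and summing per-well RGB totals over each well's ROI.
# Re-implements the in-house image-analysis macro: the total red, green and
# blue value over a fixed set of pixels in each well.

#' Construct a plate image
#'
#' @param pixels Integer H x W x 3 array, channel order R, G, B, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16 (bits per channel).
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, bit_depth = 8L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("'bit_depth' must be 8 or 16, got ", bit_depth, call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("image has zero extent", call. = FALSE)
  maxval <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxval) {
    stop(sprintf("pixel values outside [0, %d] for bit depth %d",
                 maxval, bit_depth), call. = FALSE)
  }
  pixels <- array(as.integer(pixels), dim = dim(pixels))  # strip stray attrs
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth)),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %d x %d px, %d-bit RGB\n", d[2], d[1], x$bit_depth))
  invisible(x)
}

#' Read a plate scan from PNG or TIFF
#'
#' Accepts 8- or 16-bit RGB (or RGBA; the alpha channel is dropped with a
#' warning). Channel values are kept at native depth: a 16-bit scan yields
#' integer values in `[0, 65535]`. Grayscale images are rejected — channel
#' differencing needs all three channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")  # readTIFF attaches info directly
  } else {
    stop("unsupported image format '", ext, "' (expected PNG or TIFF)",
         call. = FALSE)
  }
  if (is.null(depth) || !depth %in% c(8, 16)) {
    stop("unsupported bit depth: ", depth %||% "unknown", call. = FALSE)
  }
  if (length(dim(img)) < 3L || dim(img)[3] < 3L) {
    stop("image is not RGB (grayscale or indexed input is not supported): ",
         path, call. = FALSE)
  }
  if (dim(img)[3] == 4L) {
    warning("dropping alpha channel of ", path, call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] != 3L) {
    stop(sprintf("image has %d channels; expected RGB or RGBA", dim(img)[3]),
         call. = FALSE)
  }
  # png/tiff return values normalized to [0,1]; recover native integers
  plate_image(round(img * (2^depth - 1)), bit_depth = as.integer(depth))
}

# Integer (dx, dy) offsets of the pixels belonging to an ROI centered at the
# origin. Disk rule: pixel center within Euclidean distance <= size; square
# rule: Chebyshev distance <= size. For non-integer well centers the offsets
# are recomputed against the fractional center in roi_pixels().
roi_offsets <- function(roi, frac = c(0, 0)) {
  r <- roi$size
  span <- seq.int(floor(-r + min(frac)) - 1, ceiling(r + max(frac)) + 1)
  grid <- expand.grid(dx = span, dy = span, KEEP.OUT.ATTRS = FALSE)
  keep <- if (roi$shape == "disk") {
    (grid$dx - frac[1])^2 + (grid$dy - frac[2])^2 <= r^2
  } else {
    pmax(abs(grid$dx - frac[1]), abs(grid$dy - frac[2])) <= r
  }
  as.matrix(grid[keep, , drop = FALSE])
}

# Absolute 0-based pixel coordinates of the ROI around a (possibly
# fractional) well center.
roi_pixels <- function(roi, center) {
  base <- floor(center)
  off <- roi_offsets(roi, frac = center - base)
  cbind(x = base[1] + off[, "dx"], y = base[2] + off[, "dy"])
}

#' Per-well total RGB color values
#'
#' For every mapped well of the layout, sums the red, green and blue channel
#' values over the well's ROI. These integer totals — not per-pixel means —
#' are the quantities the downstream threshold (default 1000) is calibrated
#' against.
#'
#' @param img A [plate_image()].
#' @param layout A [plate_layout()]; every well ROI must lie fully inside
#'   the image.
#' @param rescale_8bit If `TRUE` and the image is 16-bit, channel values are
#'   right-shifted by 8 bits (integer division by 256) before summing, so
#'   totals are on the 8-bit scale the default threshold assumes.
#' @return A tibble with one row per mapped well: `well`, `row`, `col`,
#'   `sensor`, `condition`, `role`, `pair`, `red_total`, `green_total`,
#'   `blue_total`, `pixel_count`.
#' @examples
#' lay <- default_layout()
#' img <- render_plate(ketamine_plate_scenario(), lay,
#'                     concentration = 50, seed = 1)
#' head(extract_well_totals(img, lay))
#' @export
extract_well_totals <- function(img, layout, rescale_8bit = FALSE) {
  stopifnot(inherits(img, "plate_image"), inherits(layout, "plate_layout"))
  d <- dim(img$pixels)
  px <- img$pixels
  if (rescale_8bit && img$bit_depth == 16L) {
    px <- px %/% 256L
  }
  wells <- layout$wells
  totals <- matrix(0, nrow(wells), 3L,
                   dimnames = list(NULL, c("red", "green", "blue")))
  counts <- integer(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    ctr <- well_center(layout, wells$well[i])
    pts <- roi_pixels(layout$roi, ctr)
    if (min(pts) < 0 || max(pts[, "x"]) >= d[2] || max(pts[, "y"]) >= d[1]) {
      stop(sprintf(
        "ROI of well '%s' exceeds the %d x %d image bounds", wells$well[i],
        d[2], d[1]), call. = FALSE)
    }
    counts[i] <- nrow(pts)
    for (k in 1:3) {
      # pixel (x, y) is px[y + 1, x + 1, k]
      totals[i, k] <- sum(px[cbind(pts[, "y"] + 1L, pts[, "x"] + 1L, k)])
    }
  }
  tibble::tibble(
    well = wells$well, row = wells$row, col = wells$col,
    sensor = wells$sensor, condition = wells$condition,
    role = wells$role, pair = wells$pair,
    red_total = as.numeric(totals[, "red"]),
    green_total = as.numeric(totals[, "green"]),
    blue_total = as.numeric(totals[, "blue"]),
    pixel_count = counts
  )
}

#' Write / read per-well totals as CSV
#'
#' Plain UTF-8 comma-separated file with the exact columns of
#' [extract_well_totals()].
#'
#' @param totals Tibble from [extract_well_totals()].
#' @param path CSV file path.
#' @return `write_well_totals()`: `path` invisibly; `read_well_totals()`:
#'   the totals tibble.
#' @export
write_well_totals <- function(totals, path) {
  utils::write.csv(as.data.frame(totals), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_totals
#' @export
read_well_totals <- function(path) {
  if (!file.exists(path)) stop("totals file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "row", "col", "sensor", "condition", "role", "pair",
           "red_total", "green_total", "blue_total", "pixel_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("totals file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[req])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
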