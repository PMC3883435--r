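# Plate layout: grid geometry, ROI definition, and the semantic map from
# wells to sensors, buffer conditions and control/analyte roles.

CHANNELS <- c("R", "G", "B")

#' Region-of-interest specification
#'
#' Describes the fixed region over which per-well channel totals are summed.
#' A `disk` ROI contains every pixel whose center lies within `size` pixels
#' (Euclidean) of the well center; a `square` ROI contains every pixel with
#' Chebyshev distance at most `size`. Pixel centers sit at integer
#' coordinates, 0-based, origin top-left, x rightward, y downward.
#'
#' @param shape `"disk"` or `"square"`.
#' @param size Radius (disk) or half-width (square) in pixels; must be > 0.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec("disk", 10)
#' @export
roi_spec <- function(shape = c("disk", "square"), size = 10) {
  shape <- match.arg(shape)
  if (!is.numeric(size) || length(size) != 1L || !is.finite(size) || size <= 0) {
    stop("roi 'size' must be a single positive number, got: ",
         deparse(size), call. = FALSE)
  }
  structure(list(shape = shape, size = as.numeric(size)), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s, size %g px\n", x$shape, x$size))
  invisible(x)
}

parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Z])([0-9]{1,2})$", well))
  bad <- vapply(m, function(g) length(g) == 0L, logical(1))
  if (any(bad)) {
    stop("malformed well address(es): ", paste(well[bad], collapse = ", "),
         " (expected e.g. 'A1')", call. = FALSE)
  }
  data.frame(
    well = well,
    row  = vapply(m, function(g) match(g[2], LETTERS), integer(1)),
    col  = vapply(m, function(g) as.integer(g[3]), integer(1)),
    stringsAsFactors = FALSE
  )
}

sensor_rank <- function(sensor_id) {
  m <- regmatches(sensor_id, regexec("^DC([0-9]+)$", sensor_id))
  bad <- vapply(m, function(g) length(g) == 0L, logical(1))
  if (any(bad)) {
    stop("sensor id(s) not of the form DC<n>: ",
         paste(unique(sensor_id[bad]), collapse = ", "), call. = FALSE)
  }
  vapply(m, function(g) as.integer(g[2]), integer(1))
}

#' Construct and validate a plate layout
#'
#' A layout couples the scan geometry (grid origin, pitch, ROI) with the
#' semantic well map: which sensor and buffer condition each well carries
#' and whether it is a control or an analyte well. Every analyte well must
#' be paired (via `pair`) with exactly one control well of the same sensor
#' and condition.
#'
#' @param n_rows,n_cols Grid dimensions (e.g. 8 and 12 for a 96-well plate).
#' @param origin Numeric length-2, pixel coordinates `(x, y)` of the center
#'   of well A1 (0-based, origin top-left).
#' @param pitch Numeric length-2, pixel spacing `(dx, dy)` between adjacent
#'   well centers. The ROI diameter must be smaller than the pitch.
#' @param roi A [roi_spec()].
#' @param wells Data frame with columns `well` ("A1" style), `sensor`
#'   (`"DC1"`..`"DC8"` style), `condition` (positive integer), `role`
#'   (`"control"` or `"analyte"`) and `pair` (pair identifier).
#' @return An object of class `plate_layout`.
#' @seealso [load_layout()], [well_center()], [code_slots()]
#' @examples
#' wells <- data.frame(
#'   well = c("A1", "A2"), sensor = "DC1", condition = 1L,
#'   role = c("control", "analyte"), pair = "P01"
#' )
#' lay <- plate_layout(8, 12, c(60, 60), c(40, 40), roi_spec("disk", 10), wells)
#' code_length(lay)  # 1 sensor x 1 condition x 3 channels = 3
#' @export
plate_layout <- function(n_rows, n_cols, origin, pitch, roi, wells) {
  if (!is.numeric(n_rows) || n_rows < 1 || !is.numeric(n_cols) || n_cols < 1) {
    stop("'n_rows' and 'n_cols' must be positive integers", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows > 26L) stop("'n_rows' may not exceed 26 (rows are letters A-Z)",
                         call. = FALSE)
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin))) {
    stop("'origin' must be numeric (x, y)", call. = FALSE)
  }
  if (!is.numeric(pitch) || length(pitch) != 2L || any(pitch <= 0)) {
    stop("'pitch' must be positive numeric (dx, dy)", call. = FALSE)
  }
  if (!inherits(roi, "roi_spec")) stop("'roi' must be a roi_spec", call. = FALSE)
  if (2 * roi$size >= min(pitch)) {
    stop(sprintf(
      "ROI diameter (%g px) must be smaller than the well pitch (%g px)",
      2 * roi$size, min(pitch)), call. = FALSE)
  }

  req <- c("well", "sensor", "condition", "role", "pair")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    stop("'wells' is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  addr <- parse_well(wells$well)
  if (anyDuplicated(wells$well)) {
    stop("duplicate well address(es): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
         call. = FALSE)
  }
  out_of_grid <- addr$row > n_rows | addr$col > n_cols | addr$col < 1L
  if (any(out_of_grid)) {
    stop("well(s) outside the declared grid: ",
         paste(wells$well[out_of_grid], collapse = ", "), call. = FALSE)
  }
  bad_role <- !wells$role %in% c("control", "analyte")
  if (any(bad_role)) {
    stop("'role' must be 'control' or 'analyte'; offending well(s): ",
         paste(wells$well[bad_role], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(wells$condition) || any(wells$condition < 1) ||
      any(wells$condition != as.integer(wells$condition))) {
    stop("'condition' must contain positive integers", call. = FALSE)
  }
  sensor_rank(wells$sensor)  # validates the DC<n> form

  wells <- tibble::tibble(
    well = wells$well, row = addr$row, col = addr$col,
    sensor = wells$sensor, condition = as.integer(wells$condition),
    role = wells$role, pair = as.character(wells$pair)
  )

  # pairing invariant: each pair id has exactly one control and one analyte
  # well, and both carry the same sensor and condition
  for (p in unique(wells$pair)) {
    grp <- wells[wells$pair == p, ]
    n_ctrl <- sum(grp$role == "control")
    n_anal <- sum(grp$role == "analyte")
    if (n_ctrl != 1L || n_anal != 1L) {
      stop(sprintf(
        "pair '%s' must have exactly one control and one analyte well; has %d control, %d analyte (wells: %s)",
        p, n_ctrl, n_anal, paste(grp$well, collapse = ", ")), call. = FALSE)
    }
    if (length(unique(grp$sensor)) != 1L || length(unique(grp$condition)) != 1L) {
      stop(sprintf(
        "pair '%s' mixes sensors or conditions (wells: %s)",
        p, paste(grp$well, collapse = ", ")), call. = FALSE)
    }
  }

  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    origin = as.numeric(origin), pitch = as.numeric(pitch),
    roi = roi, wells = wells
  ), class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %dx%d grid, origin (%g, %g), pitch (%g, %g)\n",
    x$n_rows, x$n_cols, x$origin[1], x$origin[2], x$pitch[1], x$pitch[2]))
  cat(sprintf("  ROI: %s, size %g px\n", x$roi$shape, x$roi$size))
  cat(sprintf("  %d mapped wells, %d sensors x %d conditions -> %d-digit codes\n",
              nrow(x$wells), length(layout_sensors(x)),
              length(layout_conditions(x)), code_length(x)))
  invisible(x)
}

layout_sensors <- function(layout) {
  s <- unique(layout$wells$sensor)
  s[order(sensor_rank(s))]
}

layout_conditions <- function(layout) {
  sort(unique(layout$wells$condition))
}

#' Canonical code digit slots of a layout
#'
#' The digits of an identification code are ordered canonically: sensors
#' ascending (DC1 before DC2, ...), then buffer conditions ascending, then
#' channels in R, G, B order. `code_slots()` enumerates the slots in that
#' order; `code_length()` is their count (`n_sensors * n_conditions * 3`);
#' `ordering_id()` is a human-readable string identifying the convention,
#' stored alongside every code so that codes from incompatible layouts are
#' never compared digit-by-digit.
#'
#' @param layout A [plate_layout()].
#' @return `code_slots()`: a tibble with columns `slot` (1-based position),
#'   `sensor`, `condition`, `channel`.
#' @export
code_slots <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  grid <- expand.grid(
    channel = CHANNELS,
    condition = layout_conditions(layout),
    sensor = layout_sensors(layout),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("sensor", "condition", "channel")]
  tibble::tibble(
    slot = seq_len(nrow(grid)),
    sensor = grid$sensor,
    condition = as.integer(grid$condition),
    channel = grid$channel
  )
}

#' @rdname code_slots
#' @export
code_length <- function(layout) {
  3L * length(layout_sensors(layout)) * length(layout_conditions(layout))
}

#' @rdname code_slots
#' @export
ordering_id <- function(layout) {
  paste0("sensors:", paste(layout_sensors(layout), collapse = ","),
         "|conditions:", paste(layout_conditions(layout), collapse = ","),
         "|channels:R,G,B")
}

#' Pixel coordinates of a well center
#'
#' @param layout A [plate_layout()].
#' @param well Well address string such as `"B3"`.
#' @return Named numeric vector `c(x, y)`, 0-based pixel coordinates
#'   (x rightward, y downward).
#' @examples
#' lay <- default_layout()
#' well_center(lay, "A1")
#' @export
well_center <- function(layout, well) {
  stopifnot(inherits(layout, "plate_layout"))
  addr <- parse_well(well)
  if (addr$row > layout$n_rows || addr$col > layout$n_cols) {
    stop(sprintf("well '%s' lies outside the %dx%d grid",
                 well, layout$n_rows, layout$n_cols), call. = FALSE)
  }
  c(x = layout$origin[1] + (addr$col - 1L) * layout$pitch[1],
    y = layout$origin[2] + (addr$row - 1L) * layout$pitch[2])
}

#' Read a plate layout from its JSON description
#'
#' The layout file is JSON with keys `n_rows`, `n_cols`, `origin` (`[x, y]`),
#' `pitch` (`[dx, dy]`), `roi` (`{"shape": "disk"|"square", "size": px}`) and
#' `wells`, a list of `{"well", "sensor", "condition", "role", "pair"}`
#' records. See `system.file("extdata", "layout_default.json",
#' package = "chipcode")` for a validating example.
#'
#' @param path Path to the JSON layout file.
#' @return A validated [plate_layout()].
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- c("n_rows", "n_cols", "origin", "pitch", "roi", "wells")
  missing_keys <- setdiff(req, names(spec))
  if (length(missing_keys)) {
    stop("layout file is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (!all(c("shape", "size") %in% names(spec$roi))) {
    stop("layout 'roi' must have keys 'shape' and 'size'", call. = FALSE)
  }
  plate_layout(
    n_rows = spec$n_rows, n_cols = spec$n_cols,
    origin = spec$origin, pitch = spec$pitch,
    roi = roi_spec(spec$roi$shape, spec$roi$size),
    wells = spec$wells
  )
}

#' Write a plate layout to JSON
#'
#' Round-trips with [load_layout()]: the written file parses back to an
#' equal layout.
#'
#' @param layout A [plate_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  spec <- list(
    n_rows = layout$n_rows, n_cols = layout$n_cols,
    origin = layout$origin, pitch = layout$pitch,
    roi = list(shape = layout$roi$shape, size = layout$roi$size),
    wells = as.data.frame(
      layout$wells[, c("well", "sensor", "condition", "role", "pair")])
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' The shipped default plate layout
#'
#' Eight sensors (DC1-DC8, one per plate row A-H) under two buffer
#' conditions, each condition as a control/analyte well pair (columns 1-4),
#' on a standard 8 x 12 grid: 32 mapped wells and 8 x 2 x 3 = 48 code
#' digits. Geometry: origin (60, 60), pitch 40 px, disk ROI of radius 10 px.
#'
#' @return A [plate_layout()].
#' @examples
#' code_length(default_layout())
#' @export
default_layout <- function() {
  load_layout(system.file("extdata", "layout_default.json",
                          package = "chipcode", mustWork = TRUE))
}
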