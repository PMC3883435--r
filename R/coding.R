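# Control-vs-analyte channel differencing, threshold coding, code assembly,
# color-change counting, and Hamming-distance identification against a
# code library.

#' Coding configuration
#'
#' The single tunable of the digit assignment: the significance threshold on
#' the absolute control-minus-analyte channel difference, in color-sum
#' units. The default of 1000 is calibrated for totals summed from 8-bit
#' channel values (see the `rescale_8bit` argument of
#' [extract_well_totals()] for 16-bit scans).
#'
#' @param threshold Positive number, color-sum units.
#' @return An object of class `coding_config`.
#' @export
coding_config <- function(threshold = 1000) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0) {
    stop("'threshold' must be a single positive number", call. = FALSE)
  }
  structure(list(threshold = as.numeric(threshold)), class = "coding_config")
}

#' Control-minus-analyte channel differences
#'
#' For every control/analyte well pair and every channel, computes the
#' signed difference `delta = control_total - analyte_total`. The sign is
#' preserved (calibration fits use it); only the digit assignment takes the
#' magnitude.
#'
#' @param totals Per-well totals tibble from [extract_well_totals()] (or
#'   [read_well_totals()]).
#' @param layout The [plate_layout()] the totals were extracted under; used
#'   to check that every pair has both roles present.
#' @return Tibble with columns `pair`, `sensor`, `condition`, `channel`
#'   (`"R"`, `"G"`, `"B"`), `delta`.
#' @export
compute_differences <- function(totals, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  need <- layout$wells$well
  absent <- setdiff(need, totals$well)
  if (length(absent)) {
    stop("totals are missing mapped well(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cols <- c(R = "red_total", G = "green_total", B = "blue_total")
  out <- lapply(unique(layout$wells$pair), function(p) {
    grp <- layout$wells[layout$wells$pair == p, ]
    ctrl <- totals[totals$well == grp$well[grp$role == "control"], ]
    anal <- totals[totals$well == grp$well[grp$role == "analyte"], ]
    if (nrow(ctrl) != 1L || nrow(anal) != 1L) {
      stop("pair '", p, "' lacks a control or analyte row in the totals",
           call. = FALSE)
    }
    tibble::tibble(
      pair = p, sensor = grp$sensor[1], condition = grp$condition[1],
      channel = CHANNELS,
      delta = unname(vapply(cols[CHANNELS],
                            function(cl) ctrl[[cl]] - anal[[cl]], numeric(1)))
    )
  })
  dplyr::bind_rows(out)
}

#' Binary digit from a channel difference
#'
#' A channel records a color change (digit 1) when the magnitude of its
#' control-minus-analyte difference reaches the significance threshold.
#' The comparison is inclusive: `|delta| >= threshold` gives 1, so a
#' difference exactly at the printed threshold counts as a change.
#'
#' @param delta Signed channel difference(s), color-sum units (vectorized).
#' @param config A [coding_config()].
#' @return Integer vector of 0/1 digits.
#' @examples
#' digit_from_difference(c(0, 999, 1000, -1500), coding_config(1000))
#' @export
digit_from_difference <- function(delta, config = coding_config()) {
  stopifnot(inherits(config, "coding_config"))
  as.integer(abs(delta) >= config$threshold)
}

#' Binary identification code
#'
#' An ordered string of 0/1 digits, one per (sensor, condition, channel)
#' slot in the canonical order of [code_slots()], tagged with the
#' `ordering_id` of the layout that defines that order.
#'
#' @param digits Character string over `{0,1}` (or an integer 0/1 vector).
#' @param ordering Ordering identifier string (see [ordering_id()]).
#' @return An object of class `binary_code`.
#' @export
binary_code <- function(digits, ordering) {
  if (is.numeric(digits)) digits <- paste(as.integer(digits), collapse = "")
  if (!is.character(digits) || length(digits) != 1L ||
      grepl("[^01]", digits) || nchar(digits) == 0L) {
    stop("'digits' must be a non-empty string over {0,1}", call. = FALSE)
  }
  structure(list(digits = digits, ordering_id = as.character(ordering)),
            class = "binary_code")
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %s (%d digits, %d changes)\n",
              x$digits, nchar(x$digits), count_color_changes(x)))
  invisible(x)
}

#' @export
format.binary_code <- function(x, ...) x$digits

code_digits <- function(code) {
  as.integer(strsplit(code$digits, "")[[1]])
}

#' Assemble per-slot digits into an identification code
#'
#' @param digits Tibble with columns `sensor`, `condition`, `channel`,
#'   `digit` — exactly one 0/1 digit per canonical slot of the layout.
#' @param layout The [plate_layout()] defining the slot order.
#' @return A [binary_code()] of length [code_length()] (48 for the default
#'   8-sensor, 2-condition layout).
#' @export
assemble_code <- function(digits, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  slots <- code_slots(layout)
  key <- function(s, co, ch) paste(s, co, ch, sep = "\r")
  have <- key(digits$sensor, digits$condition, digits$channel)
  if (anyDuplicated(have)) {
    dup <- have[duplicated(have)][1]
    stop("duplicate digit for slot ", gsub("\r", "/", dup), call. = FALSE)
  }
  idx <- match(key(slots$sensor, slots$condition, slots$channel), have)
  if (anyNA(idx)) {
    miss <- slots[is.na(idx), ]
    stop("missing digit for slot(s): ",
         paste(sprintf("%s/cond%d/%s", miss$sensor, miss$condition,
                       miss$channel), collapse = ", "), call. = FALSE)
  }
  d <- as.integer(digits$digit[idx])
  if (any(!d %in% c(0L, 1L))) stop("digits must be 0 or 1", call. = FALSE)
  binary_code(d, ordering_id(layout))
}

#' Number of color changes in a code
#'
#' The number of 1 digits — the quantity that grows with analyte
#' concentration in a monotone-response assay.
#'
#' @param code A [binary_code()].
#' @return Integer count of 1s.
#' @export
count_color_changes <- function(code) {
  stopifnot(inherits(code, "binary_code"))
  sum(code_digits(code))
}

#' Identification code for one analyzed plate
#'
#' Convenience pipeline: totals -> differences -> threshold digits ->
#' assembled code.
#'
#' @param totals Per-well totals tibble ([extract_well_totals()]).
#' @param layout A [plate_layout()].
#' @param config A [coding_config()].
#' @return A [binary_code()].
#' @export
plate_code <- function(totals, layout, config = coding_config()) {
  diffs <- compute_differences(totals, layout)
  diffs$digit <- digit_from_difference(diffs$delta, config)
  assemble_code(diffs, layout)
}

#' Code library construction and JSON I/O
#'
#' A code library holds the known fingerprints unknowns are identified
#' against: one entry per (analyte, concentration) with its binary code.
#' All entries must share one code length and one ordering convention.
#' Libraries serialize as a JSON list of
#' `{"analyte", "concentration_mM", "code", "ordering_id"}` records.
#'
#' @param analyte Character vector of analyte names.
#' @param code List of [binary_code()] objects (or character digit strings
#'   if `ordering` is supplied).
#' @param concentration_mM Numeric vector (NA where the entry is not tied
#'   to a concentration).
#' @param ordering Ordering id applied to plain-string `code` entries.
#' @return An object of class `code_library`.
#' @export
code_library <- function(analyte, code, concentration_mM = NA_real_,
                         ordering = NULL) {
  if (is.character(code)) {
    if (is.null(ordering)) {
      stop("'ordering' is required when codes are given as strings",
           call. = FALSE)
    }
    code <- lapply(code, binary_code, ordering = ordering)
  }
  stopifnot(all(vapply(code, inherits, logical(1), "binary_code")))
  if (length(code) == 0L) stop("library must have at least one entry",
                               call. = FALSE)
  lens <- vapply(code, function(c) nchar(c$digits), integer(1))
  ords <- vapply(code, function(c) c$ordering_id, character(1))
  if (length(unique(lens)) != 1L || length(unique(ords)) != 1L) {
    stop("all library codes must share one length and ordering_id",
         call. = FALSE)
  }
  entries <- tibble::tibble(
    analyte = as.character(analyte),
    concentration_mM = as.numeric(rep_len(concentration_mM, length(code))),
    code = vapply(code, function(c) c$digits, character(1))
  )
  structure(list(entries = entries, ordering_id = ords[1],
                 code_length = lens[1]), class = "code_library")
}

#' @export
print.code_library <- function(x, ...) {
  cat(sprintf("<code_library> %d entries, %d-digit codes\n",
              nrow(x$entries), x$code_length))
  invisible(x)
}

#' @rdname code_library
#' @param path JSON file path.
#' @export
write_code_library <- function(lib, path) {
  stopifnot(inherits(lib, "code_library"))
  df <- as.data.frame(lib$entries)
  df$ordering_id <- lib$ordering_id
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname code_library
#' @param lib A `code_library`.
#' @export
read_code_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- c("analyte", "code", "ordering_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("library file is missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$ordering_id)) != 1L) {
    stop("library mixes ordering_id values", call. = FALSE)
  }
  conc <- if ("concentration_mM" %in% names(df)) df$concentration_mM else NA_real_
  code_library(df$analyte, as.character(df$code),
               concentration_mM = conc, ordering = df$ordering_id[1])
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Identify a code against a library
#'
#' Nearest-neighbor identification under Hamming distance. All entries at
#' the minimal distance are returned; ties are reported, never silently
#' broken.
#'
#' @param code A [binary_code()].
#' @param lib A [code_library()] with codes of the same length and
#'   ordering convention.
#' @return An object of class `match_result`: list with `best_matches`
#'   (tibble of tied entries) and `distance` (minimal Hamming distance).
#' @examples
#' lay <- default_layout()
#' lib <- code_library(c("A", "B"), c("0000", "1111"), ordering = "toy")
#' match_code(binary_code("0001", "toy"), lib)
#' @export
match_code <- function(code, lib) {
  stopifnot(inherits(code, "binary_code"), inherits(lib, "code_library"))
  if (nrow(lib$entries) == 0L) stop("code library is empty", call. = FALSE)
  if (nchar(code$digits) != lib$code_length) {
    stop(sprintf("code length %d does not match library code length %d",
                 nchar(code$digits), lib$code_length), call. = FALSE)
  }
  if (code$ordering_id != lib$ordering_id) {
    stop(sprintf(
      "code ordering '%s' is incompatible with library ordering '%s'",
      code$ordering_id, lib$ordering_id), call. = FALSE)
  }
  d <- vapply(lib$entries$code, hamming, integer(1), a = code$digits,
              USE.NAMES = FALSE)
  dmin <- min(d)
  structure(list(
    best_matches = lib$entries[d == dmin, , drop = FALSE],
    distance = as.integer(dmin)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> distance %d, %d tied match(es): %s\n",
              x$distance, nrow(x$best_matches),
              paste(x$best_matches$analyte, collapse = ", ")))
  invisible(x)
}

#' Write channel differences as CSV
#'
#' Columns `pair,sensor,condition,channel,delta`.
#'
#' @param diffs Tibble from [compute_differences()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_differences <- function(diffs, path) {
  utils::write.csv(
    as.data.frame(diffs[, c("pair", "sensor", "condition", "channel", "delta")]),
    path, row.names = FALSE)
  invisible(path)
}
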