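# Verification of binary reads against fixed-precision CSV exports.
# The procedure: values read from the binary file are rounded to the CSV's
# precision (6 decimals for waveform rows, 4 for text timestamps), f32
# values are promoted to f64, and each pair is compared by checking the
# absolute difference against the f64 machine epsilon. Texts are compared
# exactly. A raw (unrounded) mode quantifies the information lost by the
# CSV's fixed precision instead.

#' Epsilon equality of 64-bit floats
#'
#' `TRUE` exactly when the absolute difference of the two values is at most
#' the f64 machine epsilon (`.Machine$double.eps`, about 2.22e-16). `NaN`
#' or `NA` inputs compare unequal, as do two infinities.
#'
#' @param a,b numeric vectors (recycled to a common length).
#' @return logical vector.
#' @export
#' @examples
#' float_equal(0.5, 0.5)
#' float_equal(0.5, 0.5 + 1e-10)
#' float_equal(0.1 + 0.2, 0.3)
float_equal <- function(a, b) {
  d <- abs(as.double(a) - as.double(b))
  !is.na(d) & d <= .Machine$double.eps
}

#' Round to a fixed decimal precision, as an f64
#'
#' Rounds half-to-even at `digits` decimal places and returns the nearest
#' representable f64 of the decimal result — exactly the value obtained by
#' printing at that precision and parsing back, and hence exactly what the
#' CSV dialect stores.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return double vector.
#' @export
round_fixed <- function(x, digits) {
  as.numeric(sprintf(paste0("%.", digits, "f"), round(x, digits)))
}

parse_dialect_csv <- function(csv, type = c("waveform", "text"), header = FALSE) {
  type <- match.arg(type)
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (header && length(lines) > 0L) lines <- lines[-1]
  if (length(lines) == 0L)
    return(if (type == "waveform")
      list(timestamp = double(), value = double())
    else list(timestamp = double(), text = character()))

  comma <- regexpr(",", lines, fixed = TRUE)
  if (any(comma < 0L))
    dps_abort("csv_parse_error",
              sprintf("row %d has no separator", which(comma < 0L)[1]))
  ts_str <- substr(lines, 1L, comma - 1L)
  rest <- substr(lines, comma + 1L, nchar(lines))
  timestamp <- suppressWarnings(as.numeric(ts_str))
  if (anyNA(timestamp))
    dps_abort("csv_parse_error",
              sprintf("row %d has a non-numeric timestamp", which(is.na(timestamp))[1]))

  if (type == "waveform") {
    value <- suppressWarnings(as.numeric(rest))
    if (anyNA(value))
      dps_abort("csv_parse_error",
                sprintf("row %d has a non-numeric value", which(is.na(value))[1]))
    list(timestamp = timestamp, value = value)
  } else {
    quoted <- startsWith(rest, '"')
    if (any(quoted)) {
      bad <- quoted & !grepl('^"(?:[^"]|"")*"$', rest)
      if (any(bad))
        dps_abort("csv_parse_error",
                  sprintf("row %d has an unterminated quoted text", which(bad)[1]))
      rest[quoted] <- gsub('""', '"', sub('"$', "", sub('^"', "", rest[quoted])))
    }
    list(timestamp = timestamp, text = rest)
  }
}

new_comparison <- function(n_compared, n_different, max_abs_difference,
                           text_mismatches, mode, stream) {
  structure(
    list(n_compared = as.double(n_compared),
         n_different = as.double(n_different),
         max_abs_difference = as.double(max_abs_difference),
         text_mismatches = as.double(text_mismatches),
         mode = mode, stream = stream),
    class = "dps_comparison")
}

#' Compare a stream against a CSV export
#'
#' Row-aligned (strictly positional) comparison of the values read from the
#' binary file with the rows of a CSV export of the same stream. In
#' `"rounded"` mode — the verification procedure proper — binary values are
#' first rounded to the CSV precision (6 decimals for waveform timestamp
#' and value columns, 4 for text timestamps) with [round_fixed()], so a
#' stream compared against its own faithful export shows zero differences.
#' In `"raw"` mode the unrounded binary values are compared instead, which
#' measures the precision lost by the CSV export itself; for 6-decimal
#' waveform rows this is bounded by half of the last printed digit plus
#' representation error, i.e. about 5e-7, well under 1e-5.
#'
#' Every floating-point pair is compared with [float_equal()]; texts are
#' compared exactly and tallied separately.
#'
#' @param file a `dps_file`.
#' @param stream_path ToC path of the stream to compare.
#' @param csv CSV text (a single string, or a vector of lines) in the
#'   export dialect.
#' @param mode `"rounded"` (the verification procedure) or `"raw"`.
#' @param header does the CSV start with a header line?
#' @return a `dps_comparison`: `n_compared` floating-point comparisons, of
#'   which `n_different` differed; `max_abs_difference` over the unequal
#'   pairs (0 when none); `text_mismatches` for text streams.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' csv <- generate_csv_reference(ses$file, "Continuous Recording")
#' compare_stream_to_csv(ses$file, "Continuous Recording", csv)
compare_stream_to_csv <- function(file, stream_path, csv,
                                  mode = c("rounded", "raw"), header = FALSE) {
  mode <- match.arg(mode)
  s <- dps_resolve(file, stream_path)
  if (!inherits(s, "dps_stream"))
    abort_kind_mismatch(sprintf("ToC entry \"%s\" is a folder, not a stream", s$name))
  csv <- paste(csv, collapse = "\n")

  if (s$stream_type == "waveform") {
    slab <- assemble_waveform(file, s)
    parsed <- parse_dialect_csv(csv, "waveform", header = header)
    if (length(parsed$timestamp) != nrow(slab))
      dps_abort("row_count_mismatch",
                sprintf("stream has %d samples but CSV has %d rows",
                        nrow(slab), length(parsed$timestamp)))
    bt <- slab$time          # f64 timestamps
    bv <- slab$amplitude     # f32 values, promoted to f64 on read
    if (mode == "rounded") {
      bt <- round_fixed(bt, 6L)
      bv <- round_fixed(bv, 6L)
    }
    eq <- c(float_equal(bt, parsed$timestamp), float_equal(bv, parsed$value))
    diffs <- abs(c(bt - parsed$timestamp, bv - parsed$value))
    new_comparison(
      n_compared = length(eq), n_different = sum(!eq),
      max_abs_difference = if (any(!eq)) max(diffs[!eq]) else 0,
      text_mismatches = 0, mode = mode, stream = path_label(stream_path))
  } else {
    slab <- assemble_text(file, s)
    parsed <- parse_dialect_csv(csv, "text", header = header)
    if (length(parsed$timestamp) != nrow(slab))
      dps_abort("row_count_mismatch",
                sprintf("stream has %d text pages but CSV has %d rows",
                        nrow(slab), length(parsed$timestamp)))
    bt <- slab$timestamp_b   # the timestamp the dialect prints
    if (mode == "rounded") bt <- round_fixed(bt, 4L)
    eq <- float_equal(bt, parsed$timestamp)
    diffs <- abs(bt - parsed$timestamp)
    new_comparison(
      n_compared = length(eq), n_different = sum(!eq),
      max_abs_difference = if (any(!eq)) max(diffs[!eq]) else 0,
      text_mismatches = sum(slab$text != parsed$text),
      mode = mode, stream = path_label(stream_path))
  }
}

#' @export
print.dps_comparison <- function(x, ...) {
  cat(sprintf("<dps_comparison> stream \"%s\" (%s mode)\n", x$stream, x$mode))
  cat(sprintf("  %s values compared, %s differed, max |difference| = %g\n",
              format(x$n_compared, big.mark = ","),
              format(x$n_different, big.mark = ","), x$max_abs_difference))
  if (x$text_mismatches > 0)
    cat(sprintf("  %s text mismatches\n", format(x$text_mismatches, big.mark = ",")))
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x a `dps_comparison`.
#' @param ... unused.
#' @return a tibble with one row per report field.
#' @export
#' @method tidy dps_comparison
tidy.dps_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = c("n_compared", "n_different", "max_abs_difference", "text_mismatches"),
    value = c(x$n_compared, x$n_different, x$max_abs_difference, x$text_mismatches))
}

#' One-row summary of a comparison report
#'
#' @param x a `dps_comparison`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
#' @method glance dps_comparison
glance.dps_comparison <- function(x, ...) {
  tibble::tibble(
    stream = x$stream, mode = x$mode,
    n_compared = x$n_compared, n_different = x$n_different,
    max_abs_difference = x$max_abs_difference,
    text_mismatches = x$text_mismatches,
    identical = x$n_different == 0 && x$text_mismatches == 0)
}
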