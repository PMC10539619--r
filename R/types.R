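# Domain model of a recording file: a flat store of data pages plus a
# hierarchical table of contents (ToC) of folders and streams, a fixed-size
# header and a version footer. Pages come in two kinds: waveform pages
# (f32 amplitudes with f64 timestamps, or a single first timestamp plus a
# regular sampling interval) and text pages (a string plus two f64
# timestamps; equal timestamps mean a comment, distinct timestamps mean a
# sorted spike whose second timestamp is the automatically recognized spike
# time).

HEADER_LENGTH <- 64L
MAGIC <- charToRaw("DPSY")
PLOT_CONFIG_LENGTH <- 32L

#' Construct a waveform data page
#'
#' A waveform page holds a chunk of continuously recorded signal: amplitudes
#' as 32-bit floats and timestamps (seconds) as 64-bit floats. Regularly
#' sampled chunks store only the first timestamp together with the sampling
#' `interval`; irregular chunks store one timestamp per sample.
#'
#' Amplitudes are coerced to the nearest f32 value on construction (see
#' [as_f32()]) so that in-memory pages are bit-identical to their on-disk
#' representation.
#'
#' @param id file-unique page id (unsigned 32-bit integer).
#' @param amplitudes numeric vector of signal values, length >= 1.
#' @param timestamps numeric vector of seconds. For a regular page, a single
#'   first timestamp; otherwise one strictly increasing value per amplitude.
#' @param interval regular sampling interval in seconds, or `NULL` for an
#'   irregularly sampled page.
#' @param reference_id optional id of a related page (e.g. a spike template),
#'   or `NULL`.
#' @return an object of class `dps_waveform_page`.
#' @export
#' @examples
#' dps_waveform_page(1, amplitudes = rnorm(100), timestamps = 0, interval = 1e-4)
dps_waveform_page <- function(id, amplitudes, timestamps, interval = NULL,
                              reference_id = NULL) {
  page <- structure(
    list(id = as.double(id), kind = "waveform",
         reference_id = if (is.null(reference_id)) NULL else as.double(reference_id),
         amplitudes = as_f32(amplitudes),
         timestamps = as.double(timestamps),
         interval = if (is.null(interval)) NULL else as.double(interval)),
    class = c("dps_waveform_page", "dps_page"))
  validate_page(page)
  page
}

#' Construct a text data page
#'
#' Text pages store comments entered during the recording as well as sorted
#' spikes. `timestamp_a` is the primary timestamp; for a comment,
#' `timestamp_b` repeats it exactly, while for a sorted spike `timestamp_b`
#' is the automatically recognized spike time (and differs from
#' `timestamp_a`).
#'
#' @param id file-unique page id.
#' @param text the text content (Latin-1 representable); may be empty.
#' @param timestamp_a primary timestamp in seconds, >= 0.
#' @param timestamp_b secondary timestamp in seconds; equal to `timestamp_a`
#'   for comments (defaults to it), the recognized spike time for spikes.
#' @param reference_id optional id of a related page, or `NULL`.
#' @return an object of class `dps_text_page`.
#' @export
#' @examples
#' dps_text_page(2, "heat stimulus", 12.5)              # a comment
#' dps_text_page(3, "Track 1", 3.0001, 3.0)             # a sorted spike
dps_text_page <- function(id, text, timestamp_a, timestamp_b = timestamp_a,
                          reference_id = NULL) {
  page <- structure(
    list(id = as.double(id), kind = "text",
         reference_id = if (is.null(reference_id)) NULL else as.double(reference_id),
         text = as.character(text),
         timestamp_a = as.double(timestamp_a),
         timestamp_b = as.double(timestamp_b)),
    class = c("dps_text_page", "dps_page"))
  validate_page(page)
  page
}

#' Is a text page a comment (rather than a sorted spike)?
#'
#' A text page is a comment exactly when its two timestamps are equal; it is
#' a sorted spike when they differ.
#'
#' @param page a `dps_text_page`.
#' @return `TRUE` for a comment, `FALSE` for a sorted spike.
#' @export
is_comment <- function(page) {
  stopifnot(inherits(page, "dps_text_page"))
  identical(page$timestamp_a, page$timestamp_b)
}

#' Construct a table-of-contents folder
#'
#' @param id entry id, unique among ToC entries (a namespace unrelated to
#'   page ids).
#' @param name non-empty display name.
#' @param children list of `dps_folder` / `dps_stream` objects; order is
#'   preserved on round-trip.
#' @return an object of class `dps_folder`.
#' @export
dps_folder <- function(id, name, children = list()) {
  entry <- structure(
    list(id = as.double(id), name = as.character(name), children = children),
    class = c("dps_folder", "dps_toc_entry"))
  validate_entry(entry)
  entry
}

#' Construct a table-of-contents stream
#'
#' A stream names an ordered set of data pages (by id) that together form
#' one logical waveform or text stream, plus an opaque plot-configuration
#' block used by the acquisition GUI.
#'
#' @param id entry id, unique among ToC entries.
#' @param name non-empty display name.
#' @param stream_type `"waveform"` or `"text"`; every referenced page must
#'   have the matching kind.
#' @param page_ids ordered vector of page ids belonging to the stream.
#' @param plot_config opaque 32-byte raw block (defaults to zeros).
#' @return an object of class `dps_stream`.
#' @export
dps_stream <- function(id, name, stream_type = c("waveform", "text"),
                       page_ids = double(), plot_config = raw(PLOT_CONFIG_LENGTH)) {
  stream_type <- match.arg(stream_type)
  entry <- structure(
    list(id = as.double(id), name = as.character(name),
         stream_type = stream_type, page_ids = as.double(page_ids),
         plot_config = plot_config),
    class = c("dps_stream", "dps_toc_entry"))
  validate_entry(entry)
  entry
}

#' Construct an in-memory recording file
#'
#' Assembles the four parts of the format: a fixed 64-byte header (magic tag
#' plus padding), the flat page store in recording order, the ToC tree and
#' the version footer. All structural invariants are checked; use
#' [write_dps()] to serialize and [read_dps()] to parse.
#'
#' @param pages list of data pages ([dps_waveform_page()] /
#'   [dps_text_page()]) in the order they occurred during the recording.
#' @param toc root folder of the table of contents.
#' @param footer version string of the producing program (non-empty).
#' @param header_raw optional 64-byte raw header block; the magic tag and
#'   the ToC offset pointer are always (re)written by the serializer.
#' @return an object of class `dps_file`.
#' @export
dps_file <- function(pages = list(), toc = dps_folder(0, "Root"),
                     footer = "dapsysr synthetic writer",
                     header_raw = NULL) {
  if (is.null(header_raw)) {
    header_raw <- raw(HEADER_LENGTH)
    header_raw[1:4] <- MAGIC
  }
  file <- structure(
    list(header = list(magic = MAGIC, raw = header_raw),
         pages = pages, toc = toc, footer = as.character(footer)),
    class = "dps_file")
  names(file$pages) <- vapply(pages, function(p) format_id(p$id), character(1))
  validate_dps_file(file)
  file
}

format_id <- function(id) format(id, scientific = FALSE, trim = TRUE)

# ---- validators ------------------------------------------------------------

validate_page <- function(page) {
  if (is.na(page$id) || page$id < 0 || page$id >= 4294967296 || page$id != floor(page$id))
    abort_invariant("page id must be an unsigned 32-bit integer")
  if (!is.null(page$reference_id) &&
      (page$reference_id < 0 || page$reference_id >= U32_ABSENT))
    abort_invariant("reference_id must be an unsigned 32-bit integer below the absent sentinel")
  if (inherits(page, "dps_waveform_page")) {
    n <- length(page$amplitudes)
    if (n < 1L) abort_invariant("waveform page must hold at least one amplitude")
    if (!is_f32_clean(page$amplitudes))
      abort_invariant("waveform amplitudes must be exactly representable as 32-bit floats")
    if (is.null(page$interval)) {
      if (length(page$timestamps) != n) abort_length_mismatch(n, length(page$timestamps))
      if (n > 1L && any(diff(page$timestamps) <= 0))
        abort_invariant("irregular waveform timestamps must be strictly increasing")
    } else {
      if (length(page$timestamps) != 1L)
        abort_invariant("regular waveform page must store exactly one (first) timestamp")
      if (!is.finite(page$interval) || page$interval <= 0)
        abort_invariant("regular sampling interval must be positive")
    }
  } else {
    if (length(page$text) != 1L || is.na(page$text))
      abort_invariant("text page must hold a single non-NA string")
    if (!is.finite(page$timestamp_a) || page$timestamp_a < 0)
      abort_invariant("text page timestamp_a must be finite and >= 0")
    if (!is.finite(page$timestamp_b))
      abort_invariant("text page timestamp_b must be finite")
  }
  invisible(page)
}

validate_entry <- function(entry) {
  if (is.na(entry$id) || entry$id < 0 || entry$id >= 4294967296)
    abort_invariant("ToC entry id must be an unsigned 32-bit integer")
  if (!nzchar(entry$name)) abort_invariant("ToC entry name must be non-empty")
  if (inherits(entry, "dps_folder")) {
    ok <- vapply(entry$children, inherits, logical(1), what = "dps_toc_entry")
    if (!all(ok)) abort_invariant("folder children must be ToC entries")
  } else {
    if (!is.raw(entry$plot_config) || length(entry$plot_config) != PLOT_CONFIG_LENGTH)
      abort_invariant(sprintf("plot_config must be a raw vector of %d bytes", PLOT_CONFIG_LENGTH))
    if (anyNA(entry$page_ids) || any(entry$page_ids < 0) || any(entry$page_ids >= 4294967296))
      abort_invariant("stream page ids must be unsigned 32-bit integers")
  }
  invisible(entry)
}

toc_entries <- function(entry) {
  # depth-first flatten of a ToC tree, root included
  if (inherits(entry, "dps_folder"))
    c(list(entry), unlist(lapply(entry$children, toc_entries), recursive = FALSE))
  else list(entry)
}

toc_streams <- function(entry) {
  Filter(function(e) inherits(e, "dps_stream"), toc_entries(entry))
}

#' Validate all structural invariants of a recording file
#'
#' Checks page-id uniqueness, per-page invariants, ToC entry-id uniqueness,
#' that every page referenced by a stream (or by a page's `reference_id`)
#' exists, and that referenced page kinds agree with the stream type. Called
#' by both [read_dps()] and [write_dps()] so invalid structures can be
#' neither produced nor serialized.
#'
#' @param file a `dps_file`.
#' @return the file, invisibly; errors otherwise.
#' @export
validate_dps_file <- function(file) {
  stopifnot(inherits(file, "dps_file"))
  if (!is.raw(file$header$raw) || length(file$header$raw) != HEADER_LENGTH)
    abort_invariant(sprintf("header must be exactly %d bytes", HEADER_LENGTH))
  if (length(file$footer) != 1L || is.na(file$footer) || !nzchar(file$footer))
    abort_invariant("footer version string must be non-empty")
  if (!inherits(file$toc, "dps_folder"))
    abort_invariant("ToC root must be a folder")

  ids <- vapply(file$pages, function(p) p$id, double(1))
  if (anyDuplicated(ids)) abort_invariant("page ids must be unique within a file")
  for (p in file$pages) validate_page(p)
  for (p in file$pages) {
    if (!is.null(p$reference_id) && !(p$reference_id %in% ids))
      abort_dangling_page_ref(p$reference_id)
  }

  entries <- toc_entries(file$toc)
  eids <- vapply(entries, function(e) e$id, double(1))
  if (anyDuplicated(eids)) abort_invariant("ToC entry ids must be unique")
  for (e in entries) validate_entry(e)

  kind_of <- stats::setNames(vapply(file$pages, function(p) p$kind, character(1)),
                             vapply(ids, format_id, character(1)))
  for (s in toc_streams(file$toc)) {
    for (pid in s$page_ids) {
      k <- unname(kind_of[format_id(pid)])
      if (is.na(k)) abort_dangling_page_ref(pid, stream = s$name)
      if (!identical(k, s$stream_type))
        abort_kind_mismatch(sprintf(
          "stream \"%s\" has type %s but references a %s page (id %s)",
          s$name, s$stream_type, k, format_id(pid)))
    }
  }
  invisible(file)
}

# ---- print methods ---------------------------------------------------------

#' @export
print.dps_file <- function(x, ...) {
  kinds <- vapply(x$pages, function(p) p$kind, character(1))
  cat(sprintf("<dps_file> %d pages (%d waveform, %d text)\n",
              length(x$pages), sum(kinds == "waveform"), sum(kinds == "text")))
  cat(sprintf("footer: %s\n", x$footer))
  print_toc_tree(x$toc, x, indent = "")
  invisible(x)
}

print_toc_tree <- function(entry, file, indent) {
  if (inherits(entry, "dps_folder")) {
    cat(sprintf("%s+ %s/\n", indent, entry$name))
    for (ch in entry$children) print_toc_tree(ch, file, paste0(indent, "  "))
  } else {
    cat(sprintf("%s- %s  [%s stream, %d pages]\n",
                indent, entry$name, entry$stream_type, length(entry$page_ids)))
  }
  invisible(NULL)
}

#' @export
print.dps_page <- function(x, ...) {
  if (inherits(x, "dps_waveform_page")) {
    cat(sprintf("<waveform page %s> %d samples, %s\n", format_id(x$id),
                length(x$amplitudes),
                if (is.null(x$interval)) "irregularly sampled"
                else sprintf("regular dt = %g s from t0 = %g s", x$interval, x$timestamps[1])))
  } else {
    cat(sprintf("<text page %s> \"%s\" at %.4f s (%s)\n", format_id(x$id), x$text,
                x$timestamp_a, if (is_comment(x)) "comment" else
                  sprintf("sorted spike, recognized %.6f s", x$timestamp_b)))
  }
  invisible(x)
}
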