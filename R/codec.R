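# Bit-exact reader and writer for the reference dialect. The byte-level
# layout is documented in docs/format.md at the repository root; that
# document is normative for the writer. Summary: 64-byte header ("DPSY"
# magic + u64 pointer to the ToC), flat page section, recursive ToC section,
# footer string, all little-endian, strings length-prefixed Latin-1.

TAG_WAVEFORM <- 0x01
TAG_TEXT <- 0x02
TAG_FOLDER <- 0x01
TAG_STREAM <- 0x02

#' Read a recording file
#'
#' Parses the four sections of a reference-dialect file — header, data
#' pages, table of contents, footer — strictly and fail-fast: a file that
#' ends inside any structure, carries an unknown page-kind tag, or whose
#' streams reference absent pages raises a typed error rather than
#' returning a partial structure.
#'
#' @param source path to a file, or a raw vector holding its bytes.
#' @return a [dps_file()] object.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' bytes <- write_dps(ses$file)
#' f <- read_dps(bytes)
read_dps <- function(source) {
  bytes <- if (is.raw(source)) source else read_file_bytes(source)

  if (length(bytes) < HEADER_LENGTH) abort_truncated("the fixed-length header", at = length(bytes))
  if (!identical(bytes[1:4], MAGIC)) abort_bad_magic(bytes[1:4])
  header_raw <- bytes[1:HEADER_LENGTH]
  toc_offset <- r_u64(new_cursor(bytes[5:12]), what = "the ToC offset pointer")
  # the ToC pointer is dialect plumbing managed by the serializer, not header
  # content; clear it in the model so read(write(f)) is field-identical to f
  header_raw[5:12] <- raw(8L)
  if (toc_offset < HEADER_LENGTH || toc_offset > length(bytes))
    abort_truncated("the page section (ToC pointer outside the file)", at = HEADER_LENGTH)

  cur <- new_cursor(bytes)
  cur$pos <- HEADER_LENGTH + 1L

  pages <- list()
  while (cursor_offset(cur) < toc_offset) {
    page <- parse_page(cur)
    if (cursor_offset(cur) > toc_offset)
      abort_truncated("the page section (last page overruns the ToC)", at = cursor_offset(cur))
    pages[[length(pages) + 1L]] <- page
  }

  toc <- parse_toc_entry(cur)
  if (!inherits(toc, "dps_folder"))
    abort_invariant("ToC root entry must be a folder")
  footer <- r_str(cur, what = "the footer version string")
  if (cursor_remaining(cur) > 0L)
    abort_invariant(sprintf("%d trailing bytes after the footer", cursor_remaining(cur)))

  dps_file(pages = pages, toc = toc, footer = footer, header_raw = header_raw)
}

read_file_bytes <- function(path) {
  if (!file.exists(path)) dps_abort("io_failure", sprintf("no such file: %s", path))
  n <- file.info(path)$size
  readBin(path, raw(), n = n)
}

parse_page <- function(cur) {
  offset <- cursor_offset(cur)
  id <- r_u32(cur, what = "a page id")
  tag <- r_u8(cur, what = "a page kind tag")
  ref <- r_u32(cur, what = "a page reference id")
  ref <- if (ref == U32_ABSENT) NULL else ref
  if (tag == TAG_WAVEFORM) parse_waveform_page(cur, id, ref)
  else if (tag == TAG_TEXT) parse_text_page(cur, id, ref)
  else abort_unknown_page_kind(tag, offset = offset)
}

#' @rdname read_dps
#' @details `parse_waveform_page()` and `parse_text_page()` decode a single
#' page body from a cursor positioned just past the common page header; they
#' are exported for testing and for building alternative dialect readers.
#' @param cur an internal byte cursor (see source).
#' @param id,ref decoded page id and optional reference id.
#' @export
parse_waveform_page <- function(cur, id, ref = NULL) {
  flag <- r_u8(cur, what = "the regular-sampling flag")
  if (!flag %in% c(0L, 1L))
    abort_invariant(sprintf("invalid regular-sampling flag 0x%02x", flag))
  n <- r_u32(cur, what = "the amplitude count")
  amplitudes <- r_f32(cur, n = n, what = "the amplitude array")
  if (flag == 1L) {
    t0 <- r_f64(cur, what = "the first timestamp")
    dt <- r_f64(cur, what = "the sampling interval")
    dps_waveform_page(id, amplitudes, timestamps = t0, interval = dt, reference_id = ref)
  } else {
    m <- r_u32(cur, what = "the timestamp count")
    timestamps <- r_f64(cur, n = m, what = "the timestamp array")
    if (m != n) abort_length_mismatch(n, m)
    dps_waveform_page(id, amplitudes, timestamps = timestamps, reference_id = ref)
  }
}

#' @rdname read_dps
#' @export
parse_text_page <- function(cur, id, ref = NULL) {
  text <- r_str(cur, what = "the text content")
  ts <- r_f64(cur, n = 2L, what = "the text-page timestamps")
  dps_text_page(id, text, timestamp_a = ts[1], timestamp_b = ts[2], reference_id = ref)
}

parse_toc_entry <- function(cur) {
  id <- r_u32(cur, what = "a ToC entry id")
  name <- r_str(cur, what = "a ToC entry name")
  type <- r_u8(cur, what = "a ToC entry type tag")
  if (type == TAG_FOLDER) {
    n <- r_u32(cur, what = "a folder child count")
    children <- vector("list", n)
    for (i in seq_len(n)) children[[i]] <- parse_toc_entry(cur)
    dps_folder(id, name, children)
  } else if (type == TAG_STREAM) {
    stype <- r_u8(cur, what = "a stream type tag")
    if (!stype %in% c(TAG_WAVEFORM, TAG_TEXT))
      abort_invariant(sprintf("invalid stream type tag 0x%02x", stype))
    n <- r_u32(cur, what = "a stream page count")
    page_ids <- r_u32(cur, n = n, what = "a stream page-id array")
    plot_config <- take(cur, PLOT_CONFIG_LENGTH, "a plot-config block")
    dps_stream(id, name,
               stream_type = if (stype == TAG_WAVEFORM) "waveform" else "text",
               page_ids = page_ids, plot_config = plot_config)
  } else {
    abort_invariant(sprintf("unknown ToC entry type tag 0x%02x", type))
  }
}

#' Serialize a recording file
#'
#' Inverse of [read_dps()]: emits reference-dialect bytes that parse back to
#' an equal structure. Serialization is deterministic, so
#' `write_dps(read_dps(write_dps(f)))` is byte-identical to `write_dps(f)`.
#' All structural invariants are validated before any byte is produced.
#'
#' @param file a [dps_file()].
#' @param path optional output path; when `NULL` the bytes are returned.
#' @return the raw byte vector, invisibly when written to `path`.
#' @export
write_dps <- function(file, path = NULL) {
  validate_dps_file(file)

  page_chunks <- lapply(file$pages, serialize_page)
  page_bytes <- unlist(page_chunks, use.names = FALSE)
  if (is.null(page_bytes)) page_bytes <- raw(0)

  header <- file$header$raw
  header[1:4] <- MAGIC
  toc_offset <- HEADER_LENGTH + length(page_bytes)
  header[5:12] <- w_u64(toc_offset)

  bytes <- c(header, page_bytes, serialize_toc_entry(file$toc), w_str(file$footer))
  if (is.null(path)) return(bytes)
  writeBin(bytes, path)
  invisible(bytes)
}

serialize_page <- function(page) {
  ref <- if (is.null(page$reference_id)) U32_ABSENT else page$reference_id
  head <- c(w_u32(page$id),
            w_u8(if (page$kind == "waveform") TAG_WAVEFORM else TAG_TEXT),
            w_u32(ref))
  if (page$kind == "waveform") {
    if (!is.null(page$interval)) {
      c(head, w_u8(1L), w_u32(length(page$amplitudes)), w_f32(page$amplitudes),
        w_f64(page$timestamps[1]), w_f64(page$interval))
    } else {
      c(head, w_u8(0L), w_u32(length(page$amplitudes)), w_f32(page$amplitudes),
        w_u32(length(page$timestamps)), w_f64(page$timestamps))
    }
  } else {
    c(head, w_str(page$text), w_f64(c(page$timestamp_a, page$timestamp_b)))
  }
}

serialize_toc_entry <- function(entry) {
  head <- c(w_u32(entry$id), w_str(entry$name))
  if (inherits(entry, "dps_folder")) {
    kids <- lapply(entry$children, serialize_toc_entry)
    c(head, w_u8(TAG_FOLDER), w_u32(length(entry$children)),
      unlist(kids, use.names = FALSE))
  } else {
    c(head, w_u8(TAG_STREAM),
      w_u8(if (entry$stream_type == "waveform") TAG_WAVEFORM else TAG_TEXT),
      w_u32(length(entry$page_ids)), w_u32(entry$page_ids), entry$plot_config)
  }
}
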