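# Navigation of the table of contents and assembly of per-stream data into
# tidy tibbles.

#' Resolve a path in the table of contents
#'
#' Walks the ToC tree by display name, one segment per level, matching
#' case-insensitively (names are not trimmed). An empty path resolves to the
#' root folder itself.
#'
#' @param x a `dps_file` or a `dps_folder` to start from.
#' @param path character vector of names: folders first, then the target
#'   entry. A single string with no separator is a length-1 path.
#' @return the matching `dps_folder` or `dps_stream`.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' dps_resolve(ses$file, "Continuous Recording")
#' dps_resolve(ses$file, c("Tracks", "Track 1"))
dps_resolve <- function(x, path = character()) {
  root <- if (inherits(x, "dps_file")) x$toc else x
  stopifnot(inherits(root, "dps_toc_entry"))
  path <- as.character(path)
  node <- root
  for (i in seq_along(path)) {
    if (!inherits(node, "dps_folder")) abort_not_found(path[seq_len(i)])
    child_names <- vapply(node$children, function(e) e$name, character(1))
    hit <- which(tolower(child_names) == tolower(path[i]))
    if (length(hit) == 0L) abort_not_found(path[seq_len(i)])
    if (length(hit) > 1L)
      dps_abort("ambiguous_path",
                sprintf("path segment \"%s\" matches %d sibling entries", path[i], length(hit)))
    node <- node$children[[hit]]
  }
  node
}

#' Expand the timestamps of a regularly sampled waveform page
#'
#' A regular page stores only its first timestamp `t0` and the sampling
#' interval `dt`; the full timestamp vector is `t0 + k * dt` for
#' `k = 0, ..., n - 1` where `n` is the number of amplitudes. The closed
#' form (rather than iterative accumulation) is used so no drift accrues
#' over long pages; successive differences stay within 1 ulp of `dt`.
#'
#' @param page a regular `dps_waveform_page`.
#' @return double vector of `length(page$amplitudes)` timestamps, strictly
#'   increasing.
#' @export
dps_expand_timestamps <- function(page) {
  stopifnot(inherits(page, "dps_waveform_page"))
  if (is.null(page$interval))
    dps_abort("not_regular", "page is irregularly sampled: no interval to expand")
  page$timestamps[1] + (seq_len(length(page$amplitudes)) - 1) * page$interval
}

page_times <- function(page) {
  if (is.null(page$interval)) page$timestamps else dps_expand_timestamps(page)
}

resolve_stream <- function(file, stream, type) {
  s <- if (inherits(stream, "dps_stream")) stream else dps_resolve(file, stream)
  if (!inherits(s, "dps_stream"))
    abort_kind_mismatch(sprintf("ToC entry \"%s\" is a folder, not a stream", s$name))
  if (!identical(s$stream_type, type))
    abort_kind_mismatch(sprintf("stream \"%s\" has type %s, expected %s",
                                s$name, s$stream_type, type))
  s
}

stream_pages <- function(file, stream) {
  lapply(stream$page_ids, function(pid) {
    page <- file$pages[[format_id(pid)]]
    if (is.null(page)) abort_dangling_page_ref(pid, stream = stream$name)
    page
  })
}

#' Assemble a waveform stream into one tidy table
#'
#' Concatenates all pages of a waveform stream, in the stream's page order,
#' into a single tibble with one row per sample. Regular pages are expanded
#' via [dps_expand_timestamps()]. The starting row of each source page is
#' recorded in the `page_boundaries` attribute (1-based row indices, first
#' element 1 when the stream is non-empty), preserving the discontinuous
#' page segmentation of the file.
#'
#' Pages written in recording order yield non-decreasing timestamps; pages
#' that overlap or run backwards are tolerated with a warning, since page
#' order in foreign files is an observation, not a guarantee.
#'
#' @param file a `dps_file`.
#' @param stream a `dps_stream` of type waveform, or a path accepted by
#'   [dps_resolve()].
#' @return a tibble with columns `time` (f64 seconds), `amplitude`
#'   (f32-valued doubles) and `page_id`, plus attribute `page_boundaries`.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' slab <- assemble_waveform(ses$file, "Continuous Recording")
#' head(slab)
assemble_waveform <- function(file, stream) {
  s <- resolve_stream(file, stream, "waveform")
  pages <- stream_pages(file, s)
  times <- lapply(pages, page_times)
  amps <- lapply(pages, function(p) p$amplitudes)
  lens <- vapply(amps, length, integer(1))
  out <- tibble::tibble(
    time = unlist(times, use.names = FALSE) %||% double(),
    amplitude = unlist(amps, use.names = FALSE) %||% double(),
    page_id = rep(vapply(pages, function(p) p$id, double(1)), times = lens))
  if (nrow(out) > 1L && any(diff(out$time) < 0))
    warning("assembled waveform timestamps are not non-decreasing; ",
            "source pages are not in recording order", call. = FALSE)
  attr(out, "page_boundaries") <-
    if (length(lens) == 0L) integer() else cumsum(c(1L, lens[-length(lens)]))
  out
}

#' Assemble a text stream into one tidy table
#'
#' One row per text page, in the stream's page order, with the
#' comment/spike disambiguation applied: a page is a comment exactly when
#' its two timestamps are equal, otherwise a sorted spike whose
#' `timestamp_b` is the automatically recognized spike time.
#'
#' @inheritParams assemble_waveform
#' @param stream a `dps_stream` of type text, or a path for [dps_resolve()].
#' @return a tibble with columns `text`, `timestamp_a`, `timestamp_b`,
#'   `is_comment` and `page_id`.
#' @export
assemble_text <- function(file, stream) {
  s <- resolve_stream(file, stream, "text")
  pages <- stream_pages(file, s)
  tibble::tibble(
    text = vapply(pages, function(p) p$text, character(1)),
    timestamp_a = vapply(pages, function(p) p$timestamp_a, double(1)),
    timestamp_b = vapply(pages, function(p) p$timestamp_b, double(1)),
    is_comment = vapply(pages, is_comment, logical(1)),
    page_id = vapply(pages, function(p) p$id, double(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
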