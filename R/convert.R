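# Conversion of a file into a generic recording model: continuous traces,
# event series (comments) and sorted-spike series. There is no universal
# converter for every ToC layout an experiment may produce, so the mapping
# from ToC paths to model components is an explicit configuration object;
# the default matches the session layout produced by generate_session().

#' Configure the file-to-recording converter
#'
#' Names the ToC paths to convert. Each waveform stream becomes one or more
#' continuous traces: consecutive regular pages are merged into a single
#' trace when their sampling intervals are bitwise equal and the next
#' page's first timestamp lands within `merge_gap_tolerance * dt` of the
#' expected next sample time; a larger gap (e.g. a pause around a comment)
#' starts a new trace. Comment streams become event series (comments only);
#' each text stream under a track folder becomes one sorted-spike series
#' (non-comments only).
#'
#' @param continuous_paths list of ToC paths of waveform streams.
#' @param comment_paths list of ToC paths of comment text streams.
#' @param track_folder_paths list of ToC paths of folders whose child text
#'   streams hold sorted spikes.
#' @param merge_gap_tolerance page-merge tolerance as a fraction of the
#'   sampling interval, in (0, 1).
#' @return an object of class `dps_converter_config`.
#' @export
converter_config <- function(continuous_paths = list("Continuous Recording"),
                             comment_paths = list("Comments"),
                             track_folder_paths = list("Tracks"),
                             merge_gap_tolerance = 0.5) {
  if (!is.numeric(merge_gap_tolerance) || length(merge_gap_tolerance) != 1L ||
      merge_gap_tolerance <= 0 || merge_gap_tolerance >= 1)
    abort_invariant("merge_gap_tolerance must lie in (0, 1)")
  structure(
    list(continuous_paths = lapply(continuous_paths, as.character),
         comment_paths = lapply(comment_paths, as.character),
         track_folder_paths = lapply(track_folder_paths, as.character),
         merge_gap_tolerance = merge_gap_tolerance),
    class = "dps_converter_config")
}

path_label <- function(path) paste(path, collapse = "/")

#' Convert a recording file to the generic recording model
#'
#' @param file a `dps_file`.
#' @param config a [converter_config()]; the default matches the layout of
#'   [generate_session()] fixtures.
#' @return an object of class `dps_recording`: a list with `traces` (each a
#'   list with `name`, `start_time_s`, `sampling_interval_s` or `times_s`,
#'   and `samples`), `events` (tibbles with `time`, `label`), `spikes`
#'   (tibbles with `entered_time`, `recognized_time` and a `track_name`
#'   attribute-column), and `provenance` (source footer + converter name).
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.1, seed = 3))
#' rec <- dps_convert(ses$file)
#' glance(rec)
dps_convert <- function(file, config = converter_config()) {
  stopifnot(inherits(file, "dps_file"), inherits(config, "dps_converter_config"))

  traces <- list()
  for (path in config$continuous_paths) {
    s <- resolve_stream(file, path, "waveform")
    traces <- c(traces, waveform_stream_to_traces(
      file, s, path_label(path), config$merge_gap_tolerance))
  }

  events <- lapply(config$comment_paths, function(path) {
    slab <- assemble_text(file, resolve_stream(file, path, "text"))
    slab <- slab[slab$is_comment, ]
    tibble::tibble(name = path_label(path), time = slab$timestamp_a, label = slab$text)
  })

  spikes <- list()
  for (path in config$track_folder_paths) {
    folder <- dps_resolve(file, path)
    if (!inherits(folder, "dps_folder"))
      abort_kind_mismatch(sprintf("ToC entry \"%s\" is not a folder", path_label(path)))
    for (child in folder$children) {
      if (!inherits(child, "dps_stream") || child$stream_type != "text") next
      slab <- assemble_text(file, child)
      slab <- slab[!slab$is_comment, ]
      spikes <- c(spikes, list(tibble::tibble(
        track_name = child$name,
        entered_time = slab$timestamp_a,
        recognized_time = slab$timestamp_b)))
    }
  }

  structure(
    list(traces = traces, events = events, spikes = spikes,
         provenance = paste0(file$footer, " | dapsysr microneurography converter")),
    class = "dps_recording")
}

waveform_stream_to_traces <- function(file, stream, label, tolerance) {
  pages <- stream_pages(file, stream)
  traces <- list()
  current <- NULL

  flush <- function() {
    if (!is.null(current)) traces[[length(traces) + 1L]] <<- current
    current <<- NULL
  }

  for (page in pages) {
    if (is.null(page$interval)) {
      # irregular pages are never merged
      flush()
      traces[[length(traces) + 1L]] <- list(
        name = label, start_time_s = page$timestamps[1],
        sampling_interval_s = NULL, times_s = page$timestamps,
        samples = page$amplitudes)
      next
    }
    t0 <- page$timestamps[1]
    if (!is.null(current) && !is.null(current$sampling_interval_s) &&
        identical(current$sampling_interval_s, page$interval)) {
      expected <- current$start_time_s +
        length(current$samples) * current$sampling_interval_s
      if (abs(t0 - expected) <= tolerance * page$interval) {
        current$samples <- c(current$samples, page$amplitudes)
        next
      }
    }
    flush()
    current <- list(name = label, start_time_s = t0,
                    sampling_interval_s = page$interval, times_s = NULL,
                    samples = page$amplitudes)
  }
  flush()

  if (length(traces) > 1L)
    for (k in seq_along(traces))
      traces[[k]]$name <- sprintf("%s #%d", label, k)
  traces
}

#' @export
print.dps_recording <- function(x, ...) {
  cat(sprintf("<dps_recording> %d trace(s), %d event series, %d spike series\n",
              length(x$traces), length(x$events), length(x$spikes)))
  for (tr in x$traces) {
    cat(sprintf("  trace \"%s\": %d samples, %s\n", tr$name, length(tr$samples),
                if (is.null(tr$sampling_interval_s)) "irregular"
                else sprintf("dt = %g s from %g s", tr$sampling_interval_s, tr$start_time_s)))
  }
  for (ev in x$events)
    cat(sprintf("  events \"%s\": %d comments\n", ev$name[1] %||% "", nrow(ev)))
  for (sp in x$spikes)
    cat(sprintf("  spikes \"%s\": %d sorted spikes\n", sp$track_name[1] %||% "", nrow(sp)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' Tidy a recording model into one row per component
#'
#' @param x a `dps_recording`.
#' @param ... unused.
#' @return a tibble with columns `component`, `name`, `n`, `start_time`,
#'   `end_time`.
#' @export
#' @method tidy dps_recording
tidy.dps_recording <- function(x, ...) {
  rows <- list()
  for (tr in x$traces) {
    tt <- if (is.null(tr$sampling_interval_s)) tr$times_s else
      tr$start_time_s + (length(tr$samples) - 1) * tr$sampling_interval_s
    rows <- c(rows, list(tibble::tibble(
      component = "trace", name = tr$name, n = length(tr$samples),
      start_time = tr$start_time_s, end_time = max(tt))))
  }
  for (ev in x$events)
    rows <- c(rows, list(tibble::tibble(
      component = "events", name = ev$name[1] %||% NA_character_, n = nrow(ev),
      start_time = suppressWarnings(min(ev$time)),
      end_time = suppressWarnings(max(ev$time)))))
  for (sp in x$spikes)
    rows <- c(rows, list(tibble::tibble(
      component = "spikes", name = sp$track_name[1] %||% NA_character_, n = nrow(sp),
      start_time = suppressWarnings(min(sp$recognized_time)),
      end_time = suppressWarnings(max(sp$recognized_time)))))
  if (length(rows) == 0L)
    return(tibble::tibble(component = character(), name = character(),
                          n = integer(), start_time = double(), end_time = double()))
  dplyr::bind_rows(rows)
}

#' One-row summary of a recording model
#'
#' @param x a `dps_recording`.
#' @param ... unused.
#' @return a one-row tibble with component counts and total sample count.
#' @export
#' @method glance dps_recording
glance.dps_recording <- function(x, ...) {
  tibble::tibble(
    n_traces = length(x$traces),
    n_event_series = length(x$events),
    n_spike_series = length(x$spikes),
    total_samples = sum(vapply(x$traces, function(tr) length(tr$samples), double(1))),
    total_events = sum(vapply(x$events, nrow, integer(1))),
    total_spikes = sum(vapply(x$spikes, nrow, integer(1))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
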