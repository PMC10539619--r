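# Deterministic generator of synthetic microneurography-like sessions.
# Emulates the structure produced by the acquisition program: one regularly
# sampled continuous waveform stream split across pages (splitting at every
# comment, because the program closes the current waveform page when a
# comment is entered, writes the text page, and starts a new waveform
# page), a comment text stream, and per-track sorted-spike text streams
# whose pages reference a small spike-template waveform page.

#' Describe a synthetic recording session
#'
#' Parameters of the session the generator emulates. Defaults describe a
#' short but structurally complete microneurography recording: 100 s of a
#' single continuous channel sampled at 10 kHz, a handful of experimenter
#' comments, and two sorted-spike tracks.
#'
#' @param duration_s recording duration in seconds (> 0).
#' @param sample_rate_hz sampling rate of the continuous channel in Hz (> 0).
#' @param n_comments number of comments entered during the recording; each
#'   comment falls into its own sampling interval, so it must be smaller
#'   than the total sample count.
#' @param n_spike_tracks number of sorted-spike tracks (template classes).
#' @param spikes_per_track number of sorted spikes per track.
#' @param page_target_samples maximum samples per waveform page; pages are
#'   additionally split at every comment time.
#' @param seed master seed; the same seed always yields a byte-identical
#'   file.
#' @return an object of class `dps_session_spec`.
#' @export
session_spec <- function(duration_s = 100, sample_rate_hz = 10000,
                         n_comments = 4, n_spike_tracks = 2,
                         spikes_per_track = 25,
                         page_target_samples = 100000, seed = 1) {
  spec <- structure(
    list(duration_s = as.double(duration_s),
         sample_rate_hz = as.double(sample_rate_hz),
         n_comments = as.integer(n_comments),
         n_spike_tracks = as.integer(n_spike_tracks),
         spikes_per_track = as.integer(spikes_per_track),
         page_target_samples = as.integer(page_target_samples),
         seed = as.integer(seed)),
    class = "dps_session_spec")
  with(spec, {
    if (!is.finite(duration_s) || duration_s <= 0)
      dps_abort("invalid_spec", "duration_s must be positive")
    if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
      dps_abort("invalid_spec", "sample_rate_hz must be positive")
    if (is.na(page_target_samples) || page_target_samples < 1L)
      dps_abort("invalid_spec", "page_target_samples must be >= 1")
    if (is.na(n_comments) || n_comments < 0L ||
        is.na(n_spike_tracks) || n_spike_tracks < 0L ||
        is.na(spikes_per_track) || spikes_per_track < 0L)
      dps_abort("invalid_spec", "counts must be >= 0")
    if (is.na(seed)) dps_abort("invalid_spec", "seed must be an integer")
  })
  total <- round(spec$duration_s * spec$sample_rate_hz)
  if (total < 1L) dps_abort("invalid_spec", "session too short: no samples")
  if (spec$n_comments >= total)
    dps_abort("invalid_spec", "more comments than sampling intervals")
  spec
}

# Counter-based substream seeding: every random component draws under its
# own derived seed, so adding or reordering components never silently
# changes the values of the others.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed %% 1000003L) * 2017 + counter * 104729) %% 2147483647)
}

with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, counter))
  expr
}

spike_template_shape <- function(sample_rate_hz) {
  # biphasic transient ~1.5 ms wide, the classic extracellular spike shape
  half <- max(1L, as.integer(round(0.00075 * sample_rate_hz)))
  k <- seq(-half, half)
  list(offsets = k, values = as_f32(-k / half * exp(-(k / (half / 2))^2 / 2) * 0.6))
}

#' Generate a synthetic recording session
#'
#' Builds a complete, valid in-memory recording file together with the
#' ground truth used by tests. The continuous channel is a seeded noisy
#' sinusoid with biphasic spike-shaped transients added at the recognized
#' spike times, split into regular waveform pages of at most
#' `page_target_samples` samples and additionally at every comment time:
#' the split a comment induces takes precedence over the size target, so a
#' session with `n` comments and a large size target yields exactly `n + 1`
#' continuous-stream pages. Comment times are drawn uniformly over the
#' recording and redrawn (deterministically) until each falls into its own
#' interior sampling interval, since a comment cannot be entered twice
#' within one sample tick. Sorted-spike text pages store the entered time
#' in `timestamp_a` and the recognized time (one sample interval earlier)
#' in `timestamp_b`, and reference their track's spike-template page. The
#' flat page store is ordered by page start time; template pages, which
#' belong to no stream, come last.
#'
#' The ToC mirrors a typical session: a root folder holding the
#' "Continuous Recording" waveform stream, the "Comments" text stream and a
#' "Tracks" folder with one text stream per track.
#'
#' @param spec a [session_spec()].
#' @return a list with elements `file` (a [dps_file()]) and `truth`, a list
#'   holding `total_samples`, `comment_times`, `spikes` (tibble with
#'   `track`, `entered_time`, `recognized_time`), `page_count_by_kind`,
#'   `continuous_pages` (page count of the continuous stream) and
#'   `samples_per_page`.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.1, n_comments = 2, seed = 7))
#' ses$file
#' ses$truth$page_count_by_kind
generate_session <- function(spec) {
  stopifnot(inherits(spec, "dps_session_spec"))
  dt <- 1 / spec$sample_rate_hz
  total <- as.integer(round(spec$duration_s * spec$sample_rate_hz))

  comment_times <- with_substream(spec$seed, 1L, {
    for (attempt in 1:1000) {
      ct <- sort(stats::runif(spec$n_comments, 0, spec$duration_s))
      cells <- ceiling(ct * spec$sample_rate_hz)
      if (!anyDuplicated(cells) && all(cells > 0 & cells < total)) break
    }
    ct
  })
  comment_labels <- paste0("comment ", seq_len(spec$n_comments), ": ",
                           rep_len(c("heat stimulus", "cold stimulus", "brush",
                                     "electrical pulse", "rest"), spec$n_comments))

  spikes <- lapply(seq_len(spec$n_spike_tracks), function(track) {
    rec <- with_substream(spec$seed, 10L + track,
      sort(stats::runif(spec$spikes_per_track, dt, max(dt, spec$duration_s - dt))))
    tibble::tibble(track = track, entered_time = rec + dt, recognized_time = rec)
  })
  spikes <- if (length(spikes)) dplyr::bind_rows(spikes) else
    tibble::tibble(track = integer(), entered_time = double(), recognized_time = double())

  amplitudes <- with_substream(spec$seed, 2L, {
    t <- (seq_len(total) - 1) * dt
    0.08 * sin(2 * pi * 1.5 * t) + stats::rnorm(total, sd = 0.02)
  })
  template <- spike_template_shape(spec$sample_rate_hz)
  for (i in seq_len(nrow(spikes))) {
    centre <- as.integer(round(spikes$recognized_time[i] * spec$sample_rate_hz)) + 1L
    idx <- centre + template$offsets
    ok <- idx >= 1L & idx <= total
    amplitudes[idx[ok]] <- amplitudes[idx[ok]] + template$values[ok]
  }
  amplitudes <- as_f32(amplitudes)

  # page breaks: comment-induced splits first, then the size target within
  # each inter-comment chunk
  breaks <- sort(unique(pmin(pmax(ceiling(comment_times * spec$sample_rate_hz), 0), total)))
  breaks <- breaks[breaks > 0 & breaks < total]
  edges <- c(0, breaks, total)
  starts <- integer(0)
  ends <- integer(0)
  for (j in seq_len(length(edges) - 1L)) {
    cuts <- seq(edges[j], edges[j + 1L], by = spec$page_target_samples)
    if (cuts[length(cuts)] != edges[j + 1L]) cuts <- c(cuts, edges[j + 1L])
    starts <- c(starts, cuts[-length(cuts)])
    ends <- c(ends, cuts[-1])
  }

  wave_pages <- lapply(seq_along(starts), function(j)
    dps_waveform_page(0, amplitudes[seq.int(starts[j] + 1L, ends[j])],
                      timestamps = starts[j] * dt, interval = dt))
  comment_pages <- lapply(seq_len(spec$n_comments), function(i)
    dps_text_page(0, comment_labels[i], comment_times[i]))
  spike_pages <- lapply(seq_len(nrow(spikes)), function(i)
    dps_text_page(0, paste0("Track ", spikes$track[i]),
                  timestamp_a = spikes$entered_time[i],
                  timestamp_b = spikes$recognized_time[i]))

  # flat page store ordered by page start time (waveform t0, text
  # timestamp_a); sequential ids assigned in that order
  all_pages <- c(wave_pages, comment_pages, spike_pages)
  all_times <- c(starts * dt, comment_times, spikes$entered_time)
  all_pages <- all_pages[order(all_times)]
  for (j in seq_along(all_pages)) all_pages[[j]]$id <- as.double(j)

  template_ids <- double(0)
  if (spec$n_spike_tracks > 0L) {
    template_pages <- lapply(seq_len(spec$n_spike_tracks), function(track)
      dps_waveform_page(length(all_pages) + track, template$values,
                        timestamps = 0, interval = dt))
    template_ids <- vapply(template_pages, function(p) p$id, double(1))
    for (j in seq_along(all_pages)) {
      p <- all_pages[[j]]
      if (inherits(p, "dps_text_page") && !is_comment(p))
        all_pages[[j]]$reference_id <-
          template_ids[as.integer(sub("^Track ", "", p$text))]
    }
    all_pages <- c(all_pages, template_pages)
  }

  id_of <- function(pages) vapply(pages, function(p) p$id, double(1))
  wave_ids <- sort(id_of(Filter(function(p)
    inherits(p, "dps_waveform_page") && !(p$id %in% template_ids), all_pages)))
  comment_ids <- sort(id_of(Filter(function(p)
    inherits(p, "dps_text_page") && is_comment(p), all_pages)))
  track_ids <- lapply(seq_len(spec$n_spike_tracks), function(track)
    sort(id_of(Filter(function(p)
      inherits(p, "dps_text_page") && !is_comment(p) &&
        identical(p$text, paste0("Track ", track)), all_pages))))

  root <- dps_folder(1, "Root", list(
    dps_stream(2, "Continuous Recording", "waveform", wave_ids),
    dps_stream(3, "Comments", "text", comment_ids),
    dps_folder(4, "Tracks",
               lapply(seq_len(spec$n_spike_tracks), function(track)
                 dps_stream(4 + track, paste0("Track ", track), "text",
                            track_ids[[track]])))))

  file <- dps_file(pages = all_pages, toc = root,
                   footer = "Dapsys 8.0 build 7291 S/N 0001 [synthetic]")

  kinds <- vapply(all_pages, function(p) p$kind, character(1))
  truth <- list(
    total_samples = total,
    comment_times = comment_times,
    spikes = spikes,
    page_count_by_kind = c(waveform = sum(kinds == "waveform"),
                           text = sum(kinds == "text")),
    continuous_pages = length(wave_ids),
    samples_per_page = as.integer(ends - starts))

  list(file = file, truth = truth)
}

#' Render a stream as reference CSV text
#'
#' Independent reference implementation of the CSV dialect (6 decimals for
#' waveform timestamp/value rows, 4 decimals for text timestamps, decimal
#' round-half-even, RFC 4180 quoting of texts containing separators), used
#' as the expectation against which the exporter and the verification
#' comparator are tested. Returns the CSV as a single string rather than
#' writing a file.
#'
#' @param file a `dps_file`.
#' @param stream_path path for [dps_resolve()].
#' @param header prepend a column-name header line.
#' @return a character scalar: CSV lines separated (and terminated) by
#'   `"\n"`.
#' @export
generate_csv_reference <- function(file, stream_path, header = FALSE) {
  s <- dps_resolve(file, stream_path)
  if (!inherits(s, "dps_stream"))
    abort_kind_mismatch(sprintf("ToC entry \"%s\" is a folder, not a stream", s$name))
  pages <- stream_pages(file, s)
  if (s$stream_type == "waveform") {
    lines <- unlist(lapply(pages, function(page) {
      tt <- page_times(page)
      paste0(sprintf("%.6f", round(tt, 6)), ",",
             sprintf("%.6f", round(page$amplitudes, 6)))
    }), use.names = FALSE)
    head_line <- "timestamp,value"
  } else {
    lines <- vapply(pages, function(page) {
      txt <- page$text
      if (grepl('[",\n]', txt)) txt <- paste0('"', gsub('"', '""', txt), '"')
      paste0(sprintf("%.4f", round(page$timestamp_b, 4)), ",", txt)
    }, character(1))
    head_line <- "timestamp,text"
  }
  if (header) lines <- c(head_line, lines)
  if (length(lines) == 0L) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}
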