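# Fixture builders used across the suite. Everything is generated in code;
# no binary files are stored.

# A small hand-built file exercising every structural feature: regular and
# irregular waveform pages, comment and sorted-spike text pages, a nested
# folder, a page referenced by another page, and a page in no stream.
tiny_file <- function() {
  pages <- list(
    dps_waveform_page(1, amplitudes = c(0.5, -0.25, 0.125), timestamps = 0,
                      interval = 0.001),
    dps_waveform_page(2, amplitudes = c(1, 2, 3), timestamps = c(0.1, 0.2, 0.3)),
    dps_text_page(3, "heat stimulus", 12.5),
    dps_text_page(4, "Track 1", 3.0001, 3.0, reference_id = 6),
    dps_text_page(5, "", 0.0),
    dps_waveform_page(6, amplitudes = as_f32(sin(1:8)), timestamps = 0,
                      interval = 0.0005))
  toc <- dps_folder(10, "Root", list(
    dps_stream(11, "Continuous Recording", "waveform", c(1, 2)),
    dps_stream(12, "Comments", "text", c(3, 5)),
    dps_folder(13, "Tracks", list(
      dps_stream(14, "Track 1", "text", 4)))))
  dps_file(pages = pages, toc = toc, footer = "Dapsys 7.52 S/N 1234")
}

# Randomized valid file: arbitrary page counts, mixed regular/irregular
# pages, ToC depth up to 4. Deterministic in `seed`. Built independently of
# generate_session() so round-trip properties cover structures the session
# generator never produces.
random_file <- function(seed, max_pages = 30) {
  set.seed(seed)
  n_pages <- sample(0:max_pages, 1)
  ids <- if (n_pages > 0) sort(sample.int(999999L, n_pages)) else integer(0)
  texts <- c("comment", "Track 1", "a,b", "he said \"now\"", "µV signal", "")

  pages <- lapply(seq_len(n_pages), function(i) {
    if (stats::runif(1) < 0.5) {
      n <- sample(1:25, 1)
      amps <- as_f32(stats::rnorm(n))
      if (stats::runif(1) < 0.5) {
        dps_waveform_page(ids[i], amps, timestamps = stats::runif(1, 0, 10),
                          interval = stats::runif(1, 1e-5, 1e-2))
      } else {
        ts <- sort(stats::runif(n, 0, 100))
        while (any(diff(ts) <= 0)) ts <- sort(stats::runif(n, 0, 100))
        dps_waveform_page(ids[i], amps, timestamps = ts)
      }
    } else {
      ta <- stats::runif(1, 0, 100)
      if (stats::runif(1) < 0.5) dps_text_page(ids[i], sample(texts, 1), ta)
      else dps_text_page(ids[i], sample(texts, 1), ta, ta - 1e-4)
    }
  })

  kind_of <- vapply(pages, function(p) p$kind, character(1))
  pool <- list(waveform = ids[kind_of == "waveform"], text = ids[kind_of == "text"])

  entry_id <- 0L
  next_entry <- function() {
    entry_id <<- entry_id + 1L
    entry_id
  }
  make_folder <- function(depth, name) {
    n_children <- sample(0:3, 1)
    children <- lapply(seq_len(n_children), function(k) {
      if (depth < 4 && stats::runif(1) < 0.35) {
        make_folder(depth + 1L, sprintf("folder %d-%d", depth, k))
      } else {
        kind <- sample(c("waveform", "text"), 1)
        avail <- pool[[kind]]
        take_n <- if (length(avail) == 0) 0 else sample(0:length(avail), 1)
        taken <- if (take_n > 0) avail[sample.int(length(avail), take_n)] else double(0)
        pool[[kind]] <<- setdiff(pool[[kind]], taken)
        dps_stream(next_entry(), sprintf("%s stream %d-%d", kind, depth, k),
                   kind, taken,
                   plot_config = as.raw(sample(0:255, 32, replace = TRUE)))
      }
    })
    dps_folder(next_entry(), name, children)
  }
  root <- make_folder(0L, "Root")
  dps_file(pages = pages, toc = root,
           footer = sprintf("Dapsys 8.%d S/N %04d", sample(0:9, 1), seed %% 10000))
}

# Bytes of a single serialized page, for hand-corrupting in codec tests.
page_bytes <- function(page) dapsysr:::serialize_page(page)
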