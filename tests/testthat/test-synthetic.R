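# Session generator: structure, determinism, ground truth, reference CSV.

test_that("a session without comments or tracks is a single page", {
  ses <- generate_session(session_spec(duration_s = 1.0, sample_rate_hz = 10000,
                                       n_comments = 0, n_spike_tracks = 0,
                                       spikes_per_track = 0,
                                       page_target_samples = 10000, seed = 7))
  expect_identical(ses$truth$page_count_by_kind, c(waveform = 1L, text = 0L))
  expect_identical(length(ses$file$pages[[1]]$amplitudes), 10000L)
  expect_identical(ses$truth$total_samples, 10000L)
})

test_that("each comment splits the continuous stream: n comments, n+1 pages", {
  ses <- generate_session(session_spec(duration_s = 1, sample_rate_hz = 5000,
                                       n_comments = 3, n_spike_tracks = 0,
                                       spikes_per_track = 0,
                                       page_target_samples = 1000000, seed = 3))
  expect_identical(ses$truth$continuous_pages, 4L)
  kinds <- table(vapply(ses$file$pages, function(p) p$kind, character(1)))
  expect_identical(as.integer(kinds[["text"]]), 3L)
  # split positions follow the comment times: data up to the comment goes in
  # the earlier page
  slab <- assemble_waveform(ses$file, "Continuous Recording")
  bounds <- attr(slab, "page_boundaries")[-1]
  expect_identical(as.integer(bounds - 1L),
                   as.integer(ceiling(ses$truth$comment_times * 5000)))
})

test_that("generation is deterministic in the seed", {
  spec <- session_spec(duration_s = 0.5, sample_rate_hz = 2000, seed = 42)
  a <- write_dps(generate_session(spec)$file)
  b <- write_dps(generate_session(spec)$file)
  expect_identical(a, b)

  other <- generate_session(session_spec(duration_s = 0.5, sample_rate_hz = 2000,
                                         seed = 43))
  expect_false(identical(write_dps(other$file), a))
  # different seeds change the amplitudes themselves
  amp_42 <- assemble_waveform(generate_session(spec)$file, "Continuous Recording")$amplitude
  amp_43 <- assemble_waveform(other$file, "Continuous Recording")$amplitude
  expect_false(identical(amp_42[1:10], amp_43[1:10]))
})

test_that("every generated file passes the strict reader and ground truth matches", {
  set.seed(99)
  for (k in 1:25) {
    spec <- session_spec(
      duration_s = stats::runif(1, 0.05, 0.6),
      sample_rate_hz = sample(c(1000, 2000, 5000), 1),
      n_comments = sample(0:5, 1),
      n_spike_tracks = sample(0:3, 1),
      spikes_per_track = sample(0:10, 1),
      page_target_samples = sample(c(100, 500, 1e6), 1),
      seed = k)
    ses <- generate_session(spec)
    back <- read_dps(write_dps(ses$file))
    expect_identical(back, ses$file, label = sprintf("sweep %d", k))

    slab <- assemble_waveform(ses$file, "Continuous Recording")
    expect_identical(nrow(slab), ses$truth$total_samples, label = sprintf("sweep %d", k))

    comments <- assemble_text(ses$file, "Comments")
    expect_equal(comments$timestamp_a, ses$truth$comment_times)
    expect_true(all(comments$is_comment))
  }
})

test_that("spike pages carry entered and recognized times and a template reference", {
  ses <- generate_session(session_spec(duration_s = 0.5, sample_rate_hz = 2000,
                                       n_spike_tracks = 2, spikes_per_track = 6,
                                       seed = 12))
  spikes <- assemble_text(ses$file, c("Tracks", "Track 2"))
  truth <- ses$truth$spikes[ses$truth$spikes$track == 2, ]
  expect_equal(spikes$timestamp_a, truth$entered_time)
  expect_equal(spikes$timestamp_b, truth$recognized_time)
  expect_true(all(spikes$timestamp_a != spikes$timestamp_b))

  # the referenced template page exists, is a waveform, and sits in no stream
  ref <- ses$file$pages[[as.character(spikes$page_id[1])]]$reference_id
  expect_false(is.null(ref))
  template <- ses$file$pages[[as.character(ref)]]
  expect_s3_class(template, "dps_waveform_page")
  streamed <- unlist(lapply(dapsysr:::toc_streams(ses$file$toc), function(s) s$page_ids))
  expect_false(ref %in% streamed)
})

test_that("invalid session specs are rejected", {
  expect_error(session_spec(duration_s = 0), class = "dapsysr_invalid_spec")
  expect_error(session_spec(sample_rate_hz = -1), class = "dapsysr_invalid_spec")
  expect_error(session_spec(page_target_samples = 0), class = "dapsysr_invalid_spec")
  expect_error(session_spec(n_comments = -1), class = "dapsysr_invalid_spec")
  expect_error(session_spec(duration_s = 0.001, sample_rate_hz = 1000, n_comments = 5),
               class = "dapsysr_invalid_spec")
})

test_that("the reference CSV renderer applies the dialect precision rules", {
  pages <- list(
    dps_waveform_page(1, amplitudes = as_f32(0.1234567), timestamps = 0.1,
                      interval = 1),
    dps_text_page(2, "touch", 2.75),
    dps_text_page(3, "cold", 0.33335))
  f <- dps_file(pages = pages, toc = dps_folder(4, "Root", list(
    dps_stream(5, "W", "waveform", 1),
    dps_stream(6, "T", "text", c(2, 3)),
    dps_stream(7, "E", "text"))))

  expect_identical(generate_csv_reference(f, "W"), "0.100000,0.123457\n")
  expect_identical(generate_csv_reference(f, "T"), "2.7500,touch\n0.3334,cold\n")
  expect_identical(generate_csv_reference(f, "E"), "")
  expect_identical(generate_csv_reference(f, "E", header = TRUE), "timestamp,text\n")
  expect_error(generate_csv_reference(f, "missing"), class = "dapsysr_not_found")
})
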