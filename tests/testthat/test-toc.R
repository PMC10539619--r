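# ToC navigation and stream assembly.

test_that("paths resolve case-insensitively to unique entries", {
  f <- tiny_file()

  s <- dps_resolve(f, "Continuous Recording")
  expect_s3_class(s, "dps_stream")
  expect_identical(s$stream_type, "waveform")

  expect_identical(dps_resolve(f, "continuous recording")$id, s$id)
  expect_identical(dps_resolve(f, character()), f$toc)
  expect_identical(dps_resolve(f, c("tracks", "TRACK 1"))$name, "Track 1")

  expect_error(dps_resolve(f, "Nope"), class = "dapsysr_not_found")
  expect_error(dps_resolve(f, c("Continuous Recording", "deeper")),
               class = "dapsysr_not_found")

  dup <- dps_folder(1, "Root", list(dps_stream(2, "A", "text"),
                                    dps_stream(3, "a", "text")))
  expect_error(dps_resolve(dup, "A"), class = "dapsysr_ambiguous_path")
})

test_that("regular timestamp expansion uses the closed form", {
  p <- dps_waveform_page(1, rep(0, 3), 0, interval = 0.001)
  expect_identical(dps_expand_timestamps(p), c(0, 0.001, 0.002))

  single <- dps_waveform_page(2, 0, 5.0, interval = 0.25)
  expect_identical(dps_expand_timestamps(single), 5.0)

  # long page: last element must equal the loop-free closed form bitwise
  n <- 10000
  long <- dps_waveform_page(3, rep(0, n), 1.0, interval = 1e-4)
  tt <- dps_expand_timestamps(long)
  expect_identical(tt[n], 1.0 + (n - 1) * 1e-4)
  expect_true(all(diff(tt) > 0))
  # successive differences deviate from the interval by at most 1 ulp at
  # the timestamp's magnitude
  ulp <- 2^(ceiling(log2(max(tt))) - 52)
  expect_lte(max(abs(diff(tt) - 1e-4)), ulp)

  irregular <- dps_waveform_page(4, c(1, 2), c(0.1, 0.2))
  expect_error(dps_expand_timestamps(irregular), class = "dapsysr_not_regular")
})

test_that("waveform assembly concatenates pages in order with boundaries", {
  pages <- list(dps_waveform_page(1, c(1, 2, 3), 0, interval = 0.001),
                dps_waveform_page(2, c(4, 5, 6), 0.003, interval = 0.001))
  f <- dps_file(pages = pages,
                toc = dps_folder(3, "Root", list(dps_stream(4, "W", "waveform", c(1, 2)))))
  slab <- assemble_waveform(f, "W")
  expect_identical(nrow(slab), 6L)
  expect_identical(slab$time, c(0, 0.001, 0.002, 0.003, 0.004, 0.005))
  expect_identical(slab$amplitude, c(1, 2, 3, 4, 5, 6))
  expect_identical(attr(slab, "page_boundaries"), c(1L, 4L))
  expect_identical(slab$page_id, rep(c(1, 2), each = 3))

  emptyf <- dps_file(pages = list(),
                     toc = dps_folder(1, "Root", list(dps_stream(2, "W", "waveform"))))
  empty <- assemble_waveform(emptyf, "W")
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "page_boundaries"), integer())

  expect_error(assemble_waveform(f, c()), class = "dapsysr_kind_mismatch")
})

test_that("assembled slab length matches generator bookkeeping", {
  ses <- generate_session(session_spec(duration_s = 0.8, sample_rate_hz = 5000,
                                       n_comments = 3, page_target_samples = 1000,
                                       seed = 11))
  slab <- assemble_waveform(ses$file, "Continuous Recording")
  expect_identical(nrow(slab), ses$truth$total_samples)
  expect_identical(as.integer(diff(c(attr(slab, "page_boundaries"), nrow(slab) + 1L))),
                   ses$truth$samples_per_page)
  expect_true(all(diff(slab$time) >= 0))
})

test_that("text assembly aligns arrays and applies the comment rule", {
  pages <- list(dps_text_page(1, "A", 1.0, 1.0),
                dps_text_page(2, "T1", 2.5, 2.4999))
  f <- dps_file(pages = pages,
                toc = dps_folder(3, "Root", list(dps_stream(4, "T", "text", c(1, 2)))))
  slab <- assemble_text(f, "T")
  expect_identical(slab$is_comment, c(TRUE, FALSE))
  expect_identical(slab$text, c("A", "T1"))
  expect_identical(slab$timestamp_b, c(1.0, 2.4999))

  emptyf <- dps_file(pages = list(),
                     toc = dps_folder(1, "Root", list(dps_stream(2, "T", "text"))))
  empty <- assemble_text(emptyf, "T")
  expect_identical(nrow(empty), 0L)

  ses <- generate_session(session_spec(duration_s = 1, sample_rate_hz = 2000,
                                       n_spike_tracks = 1, spikes_per_track = 50,
                                       seed = 5))
  spikes <- assemble_text(ses$file, c("Tracks", "Track 1"))
  expect_identical(nrow(spikes), 50L)
  expect_false(any(spikes$is_comment))
})

test_that("out-of-order pages assemble with a warning, not an error", {
  pages <- list(dps_waveform_page(1, c(1, 2), 1.0, interval = 0.001),
                dps_waveform_page(2, c(3, 4), 0.0, interval = 0.001))
  f <- dps_file(pages = pages,
                toc = dps_folder(3, "Root", list(dps_stream(4, "W", "waveform", c(1, 2)))))
  expect_warning(slab <- assemble_waveform(f, "W"), "recording order")
  expect_identical(nrow(slab), 4L)
})
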