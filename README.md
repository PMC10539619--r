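# dapsysr

Open access to DAPSYS-style binary electrophysiology recordings from R.

DAPSYS ("Data Acquisition Processor System") is a proprietary
neurophysiological acquisition program used, among other places, in
microneurography — recordings of single peripheral-nerve-fiber activity in
awake humans. Its native binary format locks the data to the vendor
software, whose only built-in escape hatch is a manual, fixed-precision
CSV export that inflates files roughly fourfold and costs precision.
`dapsysr` implements the format's logical model as an open codec, so
recordings can be read, validated, converted to a generic recording model,
exported to NIX-structured HDF5 or dialect CSV, and verified — entirely
without the original software. A deterministic synthetic-session generator
makes every layer testable without access to real (typically
patient-restricted) recordings.

## The file model

A recording file has four parts, all little-endian:

1. **Header** — fixed 64 bytes; only a magic tag and a section pointer are
   interpreted.
2. **Data pages** — the flat store: discontinuous chunks of data, each
   with a file-unique `u32` id. *Waveform pages* hold f32 amplitudes with
   f64 timestamps (regularly sampled pages store just the first timestamp
   `t0` plus the interval `dt`; the full vector is `t0 + k·dt`). *Text
   pages* hold a string and two f64 timestamps: equal timestamps mean a
   comment, distinct timestamps a sorted spike whose second timestamp is
   the automatically recognized spike time.
3. **Table of contents** — the folder/stream hierarchy shown in the
   acquisition GUI; streams list the page ids that belong to them.
4. **Footer** — the program version/serial string.

When a comment is entered during a recording, the current waveform page is
closed, the text page appended, and a new waveform page begun — so *n*
comments split a continuous stream into *n + 1* pages. The exact byte
layout of the reference dialect is documented in
[`docs/format.md`](docs/format.md).

The verification comparator reproduces the format-level check used when a
binary reader is validated against the vendor's CSV export: binary values
are rounded to the CSV precision (6 decimals for waveform rows, 4 for text
timestamps), f32 values promoted to f64, and each pair compared by
`|a − b| ≤ ε` with ε the f64 machine epsilon. A raw (unrounded) mode
instead measures the information the CSV export itself loses, which for
6-decimal rows is bounded by half of the last printed digit, 5·10⁻⁷ —
comfortably inside the 10⁻⁵ scale of the printed precision.

## Worked example

```r
library(dapsysr)

ses <- generate_session(session_spec(duration_s = 10, sample_rate_hz = 10000,
                                     n_comments = 3, n_spike_tracks = 2,
                                     spikes_per_track = 15, seed = 42))
ses$file
#> <dps_file> 39 pages (6 waveform, 33 text)
#> footer: Dapsys 8.0 build 7291 S/N 0001 [synthetic]
#> + Root/
#>   - Continuous Recording  [waveform stream, 4 pages]
#>   - Comments  [text stream, 3 pages]
#>   + Tracks/
#>     - Track 1  [text stream, 15 pages]
#>     - Track 2  [text stream, 15 pages]
```

Three comments split the 10-s continuous stream into four pages (plus two
spike-template pages among the six waveform pages). Convert and summarise:

```r
rec <- dps_convert(ses$file)
glance(rec)
#> # A tibble: 1 × 6
#>   n_traces n_event_series n_spike_series total_samples total_events total_spikes
#>      <int>          <int>          <int>         <dbl>        <int>        <int>
#> 1        1              1              2        100000            3           30
```

The comment-split pages are gapless, so they merge back into one 100 000-
sample trace. Export to the fixed-precision CSV dialect and verify the
binary values against it:

```r
csv <- tempfile(fileext = ".csv")
export_csv(ses$file, "Continuous Recording", csv)
readLines(csv, n = 2)
#> [1] "0.000000,0.017657"  "0.000100,-0.009508"

compare_stream_to_csv(ses$file, "Continuous Recording", readLines(csv), mode = "raw")
#> <dps_comparison> stream "Continuous Recording" (raw mode)
#>   2e+05 values compared, 115,572 differed, max |difference| = 4.99998e-07

compare_stream_to_csv(ses$file, "Continuous Recording", readLines(csv), mode = "rounded")
#> <dps_comparison> stream "Continuous Recording" (rounded mode)
#>   2e+05 values compared, 0 differed, max |difference| = 0
```

In raw mode more than half of the 200 000 values differ from the CSV — but
never by more than 5·10⁻⁷, exactly the 6-decimal rounding bound; in
rounded mode (the verification procedure proper) the read is perfect.
`export_nix_h5(rec, "session.nix.h5")` writes the same model to
NIX-structured HDF5 at source precision, and `autoplot(rec)` draws the
traces with comment/spike rugs.

A command-line shim is installed as `exec/dapsys-tool` (subcommands
`inspect`, `export`, `verify`, `generate`).

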