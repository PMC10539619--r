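---
title: "The recording format, the verification procedure, and the choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The recording format, the verification procedure, and the choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapsysr)
```

## The problem

Microneurography records the activity of single peripheral nerve fibers in
awake humans. Sessions acquired with the DAPSYS system are stored in a
proprietary binary format; the vendor software exports only fixed-precision
CSV, file by file, which inflates sizes roughly fourfold and rounds every
value to a fixed number of decimals. `dapsysr` implements the format's
logical model directly — reader, writer, converter, exporters and a
rounding-aware verification comparator — so the data outlive the original
software.

This vignette explains the model the package implements, the numerical
choices it makes, and what its synthetic test data do and do not
demonstrate.

## The file model and its reference dialect

A file has four sections: a fixed 64-byte header, a flat store of *data
pages*, a hierarchical *table of contents* (ToC), and a footer holding the
producing program's version string. Pages are either waveform pages (f32
amplitudes, f64 second timestamps) or text pages (a string plus two f64
timestamps). Two rules carry most of the format's semantics:

* **Regular sampling.** A regularly sampled waveform page stores only its
  first timestamp `t0` and the sampling interval `dt`; the timestamp
  vector is implied as `t0 + k·dt`.
* **Comment/spike disambiguation.** A text page is a *comment* exactly
  when its two timestamps are bitwise equal; otherwise it is a *sorted
  spike* and the second timestamp is the automatically recognized spike
  time.

The logical model does not pin down byte offsets, tag values, endianness
or string encodings. The package therefore defines one concrete *reference
dialect* (normative description in `docs/format.md`): little-endian
throughout (the acquisition software runs on x86 Windows), length-prefixed
Latin-1 strings, a `u8` regular-sampling flag, `0xFFFFFFFF` as the absent
sentinel for optional page references, and a `u64` pointer at header
offset 4 locating the ToC. The codec is layered — model types on one side,
dialect serialization on the other — so a second dialect matching some
other byte layout could be added without touching any consumer of the
model. Parsing is strict and fail-fast with typed errors: truncation,
unknown tags, dangling page references and kind mismatches all abort the
parse rather than yield a partial structure, because a partially read
recording is worse than a refused one.

## Timestamp expansion

Regular timestamps are expanded with the closed form `t0 + k·dt`, not by
iterative accumulation, so no rounding drift accrues across a page:

```{r}
page <- dps_waveform_page(1, rep(0, 10000), timestamps = 1.0, interval = 1e-4)
tt <- dps_expand_timestamps(page)
identical(tt[10000], 1.0 + 9999 * 1e-4)
max(abs(diff(tt) - 1e-4))
```

The residual jitter in successive differences is 1 ulp at the timestamp's
magnitude — unavoidable in f64 — and this choice matters downstream: the
CSV comparator compares these expanded timestamps against their printed
form, and accumulation drift would show up there as spurious differences.

## The CSV dialect and decimal rounding

The export dialect prints waveform rows as `timestamp,value` with both
columns at exactly 6 decimal places, and text rows as `timestamp,text`
with 4 decimal places; separators are commas, line endings `"\n"`, and
texts are quoted per RFC 4180 only when needed. Which of a sorted spike's
two timestamps the CSV prints is not observable from the format rules
alone; the dialect prints the *effective event time* — the recognized
spike time — since that is the scientifically meaningful value of a spike
row (for comments the two timestamps coincide anyway).

Rounding is decimal round-half-even. This is implemented as
`sprintf(round(x, p))` rather than bare `sprintf`, a deliberate
distinction: `sprintf("%.4f", 0.33335)` prints `0.3333`, because the
nearest double to 0.33335 lies just below it, while `round(0.33335, 4)`
resolves the intended decimal tie to the even digit, giving `0.3334`. The
comparator's rounding helper goes one step further and uses the
print-then-parse composition:

```{r}
round_fixed(0.33335, 4)
```

i.e. "rounded to `p` decimals, represented as the nearest f64" — exactly
what parsing the CSV yields. Empirically, R's `round(x, 6)` alone can land
1 ulp away from the double that its printed form re-parses to (about 1 in
4000 uniform values), which would break the guarantee that a stream
compared against its own faithful export shows zero differences; the
composition closes that gap.

## The verification comparator

The comparator is strictly positional: row *k* of the CSV is compared to
sample *k* of the assembled stream. In **rounded** mode — the verification
procedure proper — binary values are first rounded to the CSV's precision
and each pair is compared by `|a − b| ≤ ε` with ε the f64 machine epsilon
(`.Machine$double.eps`); texts are compared exactly and tallied
separately. In **raw** mode the unrounded binary values are compared
instead, which measures what the CSV export itself loses: for 6-decimal
rows at most half of the last printed digit, 5·10⁻⁷. The report carries
the number of values compared, the number differing, and the maximum
absolute difference over the differing pairs.

## The converter and trace merging

The ToC layout of a session depends on the experimental setup, so there is
no universal conversion; a `converter_config()` names which streams become
continuous traces, which comments, and which folders hold spike tracks.
One genuine design choice: pages of a waveform stream are discontinuous
chunks of one recording, so consecutive regular pages are *merged* into a
single trace when their intervals match bitwise and the next page starts
within `merge_gap_tolerance · dt` (default 0.5, chosen as the natural
half-sample criterion: a gap below half an interval cannot hide a missing
sample) of the expected next sample time. Comment-induced splits are
gapless and merge back; genuine pauses start a new trace. The alternative
— one trace per page — would push reassembly onto every consumer.

## NIX/HDF5 export

The recording model serializes to one HDF5 file following the NIX data
model's layout conventions: root attributes (`format`, `version`), a
`data` group with one block, `data_arrays` with typed dimension
descriptors (`sample` dimensions with `sampling_interval`/`offset` for
regular traces, `range` with explicit ticks for irregular ones, `set` for
events and spikes), and a metadata section holding the source footer.
Trace samples are stored as f32 — the source precision — which keeps the
exported file within a few percent of the binary's size. Entity ids are
content-derived hashes and timestamp attributes are fixed, so identical
models produce byte-identical files. Event labels and spike entered-times
are stored as companion datasets inside their array's group; this is a
documented convention of this package, pragmatic rather than a claim of
full NIX-library compatibility.

## What the synthetic generator emulates — and what it does not

`generate_session()` emulates the *structure* of a microneurography
session: a regularly sampled continuous channel split into pages at every
comment (so *n* comments yield *n + 1* continuous pages) and at a page
size target; comment pages interleaved at their times; per-track
sorted-spike pages whose recognized time precedes the entered time by one
sampling interval and which reference a spike-template waveform page; and
the session ToC (continuous stream, comments stream, tracks folder).
Amplitudes are a seeded noisy sinusoid (0.08 amplitude at 1.5 Hz, Gaussian
noise σ = 0.02) with ~1.5 ms biphasic transients at spike times — chosen
so QC tooling sees plausible morphology. The statistical details are a
fixture choice, not a modelling claim.

Defaults describe the study-scale conditions: 100 s at 10 kHz (10⁶
samples), 4 comments, 2 tracks × 25 spikes, 10⁵-sample page target.
Comment times are drawn uniformly and redrawn until each falls into its
own interior sampling interval — a comment cannot physically be entered
twice within one 0.1 ms tick — which keeps the split-count rule exact.
Randomness is counter-seeded per component (comment times, spike times,
noise), so adding a component never silently changes another's values,
and the same seed always yields a byte-identical file.

What passing tests on these fixtures shows: the codec, assembly,
conversion, export and comparison logic are correct for the documented
dialect and for the structural rules above. What it cannot show: that the
reference dialect matches the true on-disk byte layout of vendor files
(not publicly documented — byte offsets, tag values and the plot-config
fields were never printed), or that real sessions respect page ordering
and naming discipline. The reader therefore tolerates out-of-order pages
with a warning, treats duplicate sibling names as an error at resolve
time rather than parse time, and isolates every dialect assumption behind
the codec layer.

## Problem sizes and numerical tolerances used by the test suite

The suite exercises round-trips on 200+ randomized files (up to ~30 pages,
ToC depth ≤ 4), full-scale precision and size checks on the 10⁶-sample
default session, and sweeps of the comment-split rule for 0–20 comments.
Numerical assertions use exact (`identical()`) comparison wherever the
design guarantees bitwise stability — codec round-trips, f32 coercion,
rounded-mode self-comparison — and explicit analytic bounds elsewhere
(5·10⁻⁷ + ε for 6-decimal loss, 1 ulp for timestamp jitter). No tolerance
is looser than the quantity's analytic bound.

## Known limitations

* The reference dialect is a faithful realization of the format's logical
  model, not a byte-level clone of vendor files; reading a real vendor
  file would require adding a second dialect behind the codec layer.
* Files are read fully into memory; there is no streaming or chunked
  export for recordings larger than RAM.
* NIX export targets structural compatibility with generic HDF5/NIX
  tooling; NWB export and in-place editing are out of scope.
* Text encoding is Latin-1 by dialect decision; scripts outside it cannot
  be serialized.
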