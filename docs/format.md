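# Reference binary dialect

This document is normative for `write_dps()` and describes the exact byte
layout the codec produces and parses. It realizes the logical model of the
DAPSYS-style format — fixed header, flat page store, hierarchical table of
contents (ToC), version footer — as one concrete dialect. The codec is
layered (logical model vs. dialect), so a second dialect matching some
other byte layout can be added without touching the model types.

Conventions:

* All multi-byte integers and floats are **little-endian**.
* `u8`, `u32`, `u64`: unsigned integers of 1, 4, 8 bytes.
* `f32`, `f64`: IEEE 754 binary32 / binary64.
* `str`: a `u32` byte count followed by that many bytes of **Latin-1**
  text. No terminator. Embedded NUL bytes are invalid.
* All timestamps are seconds; amplitudes are in the recorded signal units.

## File layout

| section | contents |
|---------|----------|
| header  | fixed 64 bytes (below) |
| pages   | data pages, back to back, in recording order |
| ToC     | one recursively serialized root folder entry |
| footer  | `str`: program version + serial number |

Nothing may follow the footer; trailing bytes are a parse error.

## Header (64 bytes)

| offset | type | value |
|--------|------|-------|
| 0      | 4 bytes | magic `"DPSY"` (`44 50 53 59`) |
| 4      | u64  | absolute byte offset of the ToC section |
| 12     | 52 bytes | padding, written as zeros, ignored on read |

Only the magic and the ToC pointer are interpreted; header content is
otherwise not required to read the file.

## Data pages

Every page starts with a common header:

| field | type | notes |
|-------|------|-------|
| id    | u32  | unique within the file |
| kind  | u8   | `0x01` waveform, `0x02` text; anything else is an error |
| reference_id | u32 | optional related page; `0xFFFFFFFF` = absent |

### Waveform page body (`kind = 0x01`)

| field | type | notes |
|-------|------|-------|
| regular | u8 | `0x01` regularly sampled, `0x00` irregular |
| n | u32 | amplitude count, >= 1 |
| amplitudes | n × f32 | |
| *if regular:* t0 | f64 | first timestamp |
| *if regular:* dt | f64 | sampling interval, > 0 |
| *if irregular:* m | u32 | timestamp count; must equal n |
| *if irregular:* timestamps | m × f64 | strictly increasing |

### Text page body (`kind = 0x02`)

| field | type | notes |
|-------|------|-------|
| text | str | may be empty |
| timestamp_a | f64 | primary timestamp, >= 0 |
| timestamp_b | f64 | equals `timestamp_a` for a comment; the
automatically recognized spike time for a sorted spike |

## ToC entries

Entries serialize recursively, depth first:

| field | type | notes |
|-------|------|-------|
| id   | u32 | unique among ToC entries (a namespace unrelated to page ids) |
| name | str | non-empty display name |
| entry_type | u8 | `0x01` folder, `0x02` stream |

Folder body: `u32` child count, then each child entry in order.

Stream body:

| field | type | notes |
|-------|------|-------|
| stream_type | u8 | `0x01` waveform, `0x02` text |
| n | u32 | page count |
| page_ids | n × u32 | ordered; every id must exist and match the stream type |
| plot_config | 32 bytes | opaque GUI plot configuration |

The root entry must be a folder.

## CSV dialect

The fixed-precision CSV dialect used by `export_csv()` and understood by
the verification comparator:

* waveform streams: `timestamp,value` rows, both columns printed at
  exactly 6 decimal places;
* text streams: `timestamp,text` rows, the timestamp at exactly 4 decimal
  places. The printed timestamp is the effective event time
  (`timestamp_b`): the comment time for comments, the recognized spike
  time for sorted spikes;
* rounding is decimal round-half-even;
* comma separator, `"\n"` line endings, no header row unless requested;
* texts are double-quoted per RFC 4180 only when they contain a comma,
  quote or newline.
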