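# The fixed-precision CSV dialect. Waveform rows print timestamp and value
# at exactly 6 decimal places; text rows print the event timestamp at
# exactly 4 decimal places followed by the text. Rounding is decimal
# round-half-even: values are first rounded to the target precision with
# round() (which rounds the intended decimal, not the binary artefact of
# the nearest double) and then printed with a fixed number of digits.

fmt_fixed <- function(x, digits) sprintf(paste0("%.", digits, "f"), round(x, digits))

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_lines_for_stream <- function(file, stream_path, header = FALSE) {
  s <- dps_resolve(file, stream_path)
  if (!inherits(s, "dps_stream"))
    abort_kind_mismatch(sprintf("ToC entry \"%s\" is a folder, not a stream", s$name))
  if (s$stream_type == "waveform") {
    slab <- assemble_waveform(file, s)
    lines <- paste0(fmt_fixed(slab$time, 6L), ",", fmt_fixed(slab$amplitude, 6L))
    if (header) lines <- c("timestamp,value", lines)
  } else {
    slab <- assemble_text(file, s)
    lines <- paste0(fmt_fixed(slab$timestamp_b, 4L), ",", csv_quote(slab$text))
    if (header) lines <- c("timestamp,text", lines)
  }
  lines
}

#' Export one stream to fixed-precision CSV
#'
#' Writes the stream in the CSV dialect of the acquisition program's own
#' export: waveform streams as `timestamp,value` rows with both columns at
#' 6 decimal places; text streams as `timestamp,text` rows with the event
#' timestamp (the recognized spike time for sorted spikes, the comment time
#' for comments) at 4 decimal places. Rows appear in assembled stream
#' order, lines end with `"\n"`, and texts are double-quoted per RFC 4180
#' only when they contain a separator, quote or newline. No header row is
#' written unless requested.
#'
#' Rounding to the fixed precision loses information: re-parsing an
#' exported waveform CSV can deviate from the source values by up to half
#' of the last printed decimal (5e-7 for 6 decimals).
#'
#' @param file a `dps_file`.
#' @param stream_path ToC path of the stream (see [dps_resolve()]).
#' @param path output file path.
#' @param header write a column-name header line first.
#' @return `path`, invisibly.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' csv <- tempfile(fileext = ".csv")
#' export_csv(ses$file, "Continuous Recording", csv)
#' readLines(csv, n = 2)
export_csv <- function(file, stream_path, path, header = FALSE) {
  lines <- csv_lines_for_stream(file, stream_path, header = header)
  con <- base::file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
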