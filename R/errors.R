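# Typed error conditions. Every error raised by the package carries the class
# "dapsysr_error" plus one specific subclass so callers (and the CLI) can
# dispatch on the failure kind rather than on message text.

dps_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("dapsysr_", class), "dapsysr_error"), ...)
}

abort_truncated <- function(what, at = NULL) {
  msg <- sprintf("truncated file: input ended inside %s", what)
  if (!is.null(at)) msg <- sprintf("%s (byte offset %d)", msg, at)
  dps_abort("truncated_file", msg)
}

abort_bad_magic <- function(found) {
  dps_abort("bad_magic",
            sprintf("not a recognized recording file: magic bytes %s (expected \"DPSY\")",
                    paste(sprintf("%02x", as.integer(found)), collapse = " ")))
}

abort_unknown_page_kind <- function(tag, offset = NULL) {
  dps_abort("unknown_page_kind",
            sprintf("unknown page kind tag 0x%02x%s", tag,
                    if (is.null(offset)) "" else sprintf(" at byte offset %d", offset)))
}

abort_dangling_page_ref <- function(id, stream = NULL) {
  dps_abort("dangling_page_ref",
            sprintf("stream%s references page id %s which does not exist in the file",
                    if (is.null(stream)) "" else sprintf(" \"%s\"", stream),
                    format(id, scientific = FALSE)))
}

abort_invariant <- function(message) dps_abort("invariant_violation", message)

abort_length_mismatch <- function(n_amp, n_ts) {
  dps_abort("length_mismatch",
            sprintf("irregular waveform page has %d amplitudes but %d timestamps", n_amp, n_ts))
}

abort_kind_mismatch <- function(message) dps_abort("kind_mismatch", message)

abort_not_found <- function(path) {
  dps_abort("not_found", sprintf("no table-of-contents entry matches path \"%s\"",
                                 paste(path, collapse = "/")))
}
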