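# Low-level binary primitives for the reference dialect. All multi-byte
# values are little-endian (the originating acquisition software runs on
# x86 Windows). Unsigned 32-bit integers are represented in R as doubles,
# which hold every value in [0, 2^32) exactly.

U32_ABSENT <- 4294967295  # 0xFFFFFFFF sentinel: optional id not present

#' Coerce doubles to the nearest 32-bit float value
#'
#' Waveform amplitudes are stored on disk as IEEE 754 single precision.
#' `as_f32()` rounds a double vector through a 4-byte representation so the
#' in-memory values are exactly what a write/read cycle would produce;
#' round-trip tests can then compare bitwise.
#'
#' @param x numeric vector.
#' @return double vector whose elements are all exactly representable as f32.
#' @export
#' @examples
#' as_f32(0.1234567)
as_f32 <- function(x) {
  if (length(x) == 0L) return(double(0))
  readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
          "double", size = 4L, n = length(x), endian = "little")
}

is_f32_clean <- function(x) length(x) == 0L || identical(as_f32(x), as.double(x))

# ---- writers: each returns a raw vector ------------------------------------

w_u8 <- function(x) as.raw(x)

w_u32 <- function(v) {
  v <- as.double(v)
  if (any(is.na(v)) || any(v < 0) || any(v >= 4294967296) || any(v != floor(v)))
    abort_invariant("u32 field out of range [0, 2^32)")
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

w_u64 <- function(v) {
  # values in practice are file offsets, far below 2^53
  v <- as.double(v)
  lo <- v %% 4294967296
  hi <- v %/% 4294967296
  c(w_u32(lo), w_u32(hi))
}

w_f32 <- function(x) writeBin(as.double(x), raw(), size = 4L, endian = "little")
w_f64 <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

w_str <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    abort_invariant("string field must be a single non-NA character value")
  latin <- iconv(enc2utf8(s), from = "UTF-8", to = "latin1")
  if (is.na(latin))
    dps_abort("encoding_error",
              sprintf("string not representable in Latin-1: \"%s\"", s))
  bytes <- charToRaw(latin)
  c(w_u32(length(bytes)), bytes)
}

# ---- cursor over a raw vector ----------------------------------------------

new_cursor <- function(bytes) {
  cur <- new.env(parent = emptyenv())
  cur$bytes <- bytes
  cur$pos <- 1L       # 1-based index of next unread byte
  cur
}

cursor_offset <- function(cur) cur$pos - 1L          # 0-based file offset
cursor_remaining <- function(cur) length(cur$bytes) - cur$pos + 1L

take <- function(cur, n, what) {
  n <- as.integer(n)
  if (cursor_remaining(cur) < n) abort_truncated(what, at = cursor_offset(cur))
  out <- cur$bytes[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + n
  out
}

r_u8 <- function(cur, what = "a byte field") as.integer(take(cur, 1L, what))

r_u32 <- function(cur, n = 1L, what = "a u32 field") {
  x <- readBin(take(cur, 4L * n, what), "integer", n = n, size = 4L, endian = "little")
  x <- as.double(x)
  neg <- x < 0
  x[neg] <- x[neg] + 4294967296
  x
}

r_u64 <- function(cur, what = "a u64 field") {
  lo <- r_u32(cur, what = what)
  hi <- r_u32(cur, what = what)
  hi * 4294967296 + lo
}

r_f32 <- function(cur, n = 1L, what = "an f32 array") {
  readBin(take(cur, 4L * n, what), "double", n = n, size = 4L, endian = "little")
}

r_f64 <- function(cur, n = 1L, what = "an f64 array") {
  readBin(take(cur, 8L * n, what), "double", n = n, size = 8L, endian = "little")
}

r_str <- function(cur, what = "a string field") {
  len <- r_u32(cur, what = what)
  bytes <- take(cur, len, what)
  if (any(bytes == as.raw(0L)))
    dps_abort("encoding_error", "string field contains an embedded NUL byte")
  s <- rawToChar(bytes)
  Encoding(s) <- "latin1"
  enc2utf8(s)
}
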