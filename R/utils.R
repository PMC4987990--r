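# Shared low-level helpers: structured error conditions and little-endian
# binary packing. All multi-octet integers in BAM/BAI/BGZF are little-endian.

bamkit_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bamkit_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# unsigned 16-bit little-endian
u16_raw <- function(x) {
  as.raw(c(x %% 256L, x %/% 256L))
}

read_u16 <- function(r, at) {
  as.integer(r[at]) + 256L * as.integer(r[at + 1L])
}

# unsigned/signed 32-bit little-endian from a numeric (double) value.
# Values up to 2^32-1 are accepted; negatives are two's-complemented.
u32_raw <- function(x) {
  x <- as.numeric(x)
  x <- ifelse(x < 0, x + 4294967296, x)
  b <- rbind(x %% 256,
             x %/% 256 %% 256,
             x %/% 65536 %% 256,
             x %/% 16777216 %% 256)
  as.raw(as.vector(b))
}

# vectorized unsigned 32-bit read: `at` are 1-based offsets of the low octet
read_u32 <- function(r, at) {
  as.numeric(r[at]) +
    256 * as.numeric(r[at + 1L]) +
    65536 * as.numeric(r[at + 2L]) +
    16777216 * as.numeric(r[at + 3L])
}

read_i32 <- function(r, at) {
  v <- read_u32(r, at)
  ifelse(v >= 2147483648, v - 4294967296, v)
}

i32_raw <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# 64-bit unsigned as double (exact below 2^53, ample for virtual offsets of
# any file this package produces)
read_u64d <- function(r, at) {
  read_u32(r, at) + 4294967296 * read_u32(r, at + 4L)
}

u64d_raw <- function(x) {
  lo <- x %% 4294967296
  hi <- x %/% 4294967296
  b <- rbind(lo %% 256, lo %/% 256 %% 256, lo %/% 65536 %% 256,
             lo %/% 16777216 %% 256,
             hi %% 256, hi %/% 256 %% 256, hi %/% 65536 %% 256,
             hi %/% 16777216 %% 256)
  as.raw(as.vector(b))
}

# strtoi without the 2^31 limit (flags etc. stay well below it, positions too)
int_or_stop <- function(x, what, line = NULL) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v) != is.na(x))) {
    where <- if (is.null(line)) "" else sprintf(" at line %d", line)
    bamkit_stop(sprintf("malformed %s%s", what, where), "bamkit_parse_error")
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
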