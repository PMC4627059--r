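#' Bit-vector utilities
#'
#' Genomes and profile fields are represented as plain integer vectors over
#' {0, 1}. These helpers convert between the vector form and character
#' strings such as `"01111110"`, and provide the XOR / popcount primitives
#' that the binding and rate machinery is built on.
#'
#' @param x A character scalar over `0`/`1`, or an integer bit vector.
#' @return `bits()` returns an integer vector; `bitstr()` a character scalar.
#' @examples
#' bits("0101")
#' bitstr(c(1L, 0L, 1L))
#' @export
bits <- function(x) {
  if (is.numeric(x)) {
    v <- as.integer(x)
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(x)) return(integer(0))
    v <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  }
  if (anyNA(v) || any(v < 0L | v > 1L)) stop("bits must be 0 or 1")
  v
}

#' @rdname bits
#' @export
bitstr <- function(x) paste(as.integer(x), collapse = "")

#' @rdname bits
#' @param a,b Equal-length bit vectors.
#' @export
bit_xor <- function(a, b) {
  if (length(a) != length(b)) stop("bit_xor: length mismatch")
  as.integer(xor(a == 1L, b == 1L))
}

#' @rdname bits
#' @export
popcount <- function(x) sum(as.integer(x))

# Big-endian unsigned integer value of a bit field (first bit = MSB).
# Fields are at most 20 bits wide so double precision is exact.
bits_to_uint <- function(x) {
  if (length(x) == 0L) stop("empty bit field")
  sum(as.numeric(x) * 2^((length(x) - 1L):0L))
}

# Inverse of bits_to_uint for a given width (big-endian).
uint_to_bits <- function(v, width) {
  stopifnot(v >= 0, v < 2^width)
  out <- integer(width)
  for (i in width:1) {
    out[i] <- as.integer(v %% 2)
    v <- v %/% 2
  }
  out
}
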