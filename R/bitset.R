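#' Packed vertex bitsets
#'
#' Start-vertex sets and compatibility sets are stored as raw vectors of
#' `ceiling(n/8)` bytes, with bit `v` (0-based) in byte `v %/% 8` at bit
#' position `v %% 8` — the same layout `packBits()` uses, and the layout of
#' the serialized index.
#'
#' @param indices 0-based vertex indices.
#' @param n number of vertices the bitset covers.
#' @param bits a raw vector bitset.
#' @return `bitsetFromIndices()` a raw vector; `bitsetIndices()` an integer
#'   vector of 0-based set bits; `bitsetPopcount()` the number of set bits.
#' @examples
#' b <- bitsetFromIndices(c(0L, 9L), 10)
#' bitsetIndices(b)
#' bitsetPopcount(b)
#' @name bitset
NULL

#' @rdname bitset
#' @export
bitsetFromIndices <- function(indices, n) {
  l <- logical(8L * ((as.integer(n) + 7L) %/% 8L))
  if (length(indices)) l[as.integer(indices) + 1L] <- TRUE
  packBits(l, "raw")
}

#' @rdname bitset
#' @export
bitsetIndices <- function(bits) {
  which(rawToBits(bits) == as.raw(1L)) - 1L
}

#' @rdname bitset
#' @export
bitsetPopcount <- function(bits) {
  sum(rawToBits(bits) == as.raw(1L))
}

emptyBitset <- function(n) raw((as.integer(n) + 7L) %/% 8L)

bitsetAny <- function(bits) any(bits != as.raw(0L))
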