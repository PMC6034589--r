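# Deterministic string hashing for the mock binding predictor.
#
# A Lehmer-style multiplicative recurrence over the byte sequence, carried out
# in double precision below 2^53 so results are identical across platforms and
# sessions. Strings are padded to a fixed 128-byte frame before folding so the
# value of one string never depends on which other strings share the call.

.HASH_MOD <- 2147483647      # 2^31 - 1 (Mersenne prime)
.HASH_MULT <- 48271          # minimal-standard Lehmer multiplier
.HASH_FRAME <- 128L

#' Deterministic uniform variates from strings
#'
#' Maps each input string to a reproducible value in `[0, 1)`. Used by the
#' mock binding predictor so that predictions are a pure function of
#' (sequence, allele, seed) without touching R's global RNG state.
#'
#' @param x character vector; each element must be at most 128 bytes.
#' @return numeric vector in `[0, 1)`, same length as `x`.
#' @keywords internal
#' @noRd
hash_unit <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(numeric(0))
  n <- length(x)
  ints <- lapply(x, utf8ToInt)
  lens <- lengths(ints)
  if (any(lens > .HASH_FRAME)) {
    stop("hash_unit(): input longer than ", .HASH_FRAME, " bytes")
  }
  mat <- vapply(ints, function(v) {
    c(v + 1, rep.int(0, .HASH_FRAME - length(v)))
  }, numeric(.HASH_FRAME))
  if (n == 1L) mat <- matrix(mat, ncol = 1L)
  h <- rep.int(17, n)
  for (i in seq_len(.HASH_FRAME)) {
    h <- (h * .HASH_MULT + mat[i, ]) %% .HASH_MOD
  }
  # extra scrambling rounds decorrelate near-identical inputs
  h <- (h * .HASH_MULT + 12345) %% .HASH_MOD
  h <- (h * .HASH_MULT + 67890) %% .HASH_MOD
  h / .HASH_MOD
}
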