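# State coding: a state is an N-bit vector; its integer code places region 1
# at the least-significant bit, so code = sum_i bits[i] * 2^(i-1).

.checkBits <- function(bits) {
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L))
    stop("state entries must be 0 or 1", call. = FALSE)
  if (length(bits) > .MAX_ENUM_N)
    stop(sprintf("at most %d regions supported for state encoding",
                 .MAX_ENUM_N), call. = FALSE)
  invisible(TRUE)
}

#' Encode a binary state vector as an integer code
#'
#' Region 1 maps to the least-significant bit: \code{encodeState(c(1, 0))}
#' is 1 and \code{encodeState(c(0, 1))} is 2.
#'
#' @param bits binary vector (entries 0/1), length at most 20.
#' @return non-negative integer code in [0, 2^N).
#' @seealso [decodeState()]
#' @export
encodeState <- function(bits) {
  bits <- as.integer(bits)
  .checkBits(bits)
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' Decode an integer state code into a binary vector
#'
#' @param code non-negative integer in [0, 2^N).
#' @param nRegions number of regions N.
#' @return integer vector of N bits (region 1 first).
#' @export
decodeState <- function(code, nRegions) {
  code <- as.integer(code)
  nRegions <- as.integer(nRegions)
  if (code < 0L || code >= 2^nRegions)
    stop("code out of range for given nRegions", call. = FALSE)
  as.integer(bitwAnd(bitwShiftR(code, seq_len(nRegions) - 1L), 1L))
}

#' Complement (flip every bit of) a binary state
#'
#' The complementary state inverts each region's activity; it appears in the
#' landscape analysis because near-flip-symmetric systems carry local minima
#' in complementary pairs.
#'
#' @param bits binary vector.
#' @return binary vector with every bit flipped.
#' @export
complementState <- function(bits) {
  bits <- as.integer(bits)
  .checkBits(bits)
  1L - bits
}

# complement on codes, vectorized
.complementCode <- function(code, nRegions) {
  as.integer(2^nRegions - 1 - code)
}

#' Hamming distance between two binary states
#'
#' @param a,b binary vectors of equal length.
#' @return integer count of differing positions.
#' @export
hammingDistance <- function(a, b) {
  if (length(a) != length(b))
    stop("states must have equal length", call. = FALSE)
  sum(as.integer(a) != as.integer(b))
}

.hammingCodes <- function(codeA, codeB) {
  x <- bitwXor(as.integer(codeA), as.integer(codeB))
  n <- 0L
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# Full state-space bit matrix: 2^N x N, row k+1 = decodeState(k, N).
.stateSpace <- function(nRegions) {
  if (nRegions > .MAX_ENUM_N)
    stop(sprintf("full enumeration limited to N <= %d (got N = %d)",
                 .MAX_ENUM_N, nRegions), call. = FALSE)
  codes <- 0:(2^nRegions - 1)
  vapply(seq_len(nRegions),
         function(i) as.double(bitwAnd(bitwShiftR(codes, i - 1L), 1L)),
         numeric(2^nRegions))
}

# render bits as a human-readable string, region 1 leftmost
.bitString <- function(code, nRegions) {
  vapply(code, function(k)
    paste(decodeState(k, nRegions), collapse = ""), character(1))
}

#' Binarize a continuous multivariate series
#'
#' Values strictly above the threshold become 1 (active); values at or below
#' it become 0 (deactive). Zero is the conventional threshold for signals
#' that have been mean-centered (e.g. after global-signal regression).
#'
#' @param continuous T x N numeric matrix or data.frame.
#' @param threshold scalar threshold (default 0). Ties map to 0.
#' @return A \linkS4class{StateSeries}.
#' @export
binarizeSeries <- function(continuous, threshold = 0) {
  x <- as.matrix(continuous)
  if (!is.numeric(x)) stop("input must be numeric", call. = FALSE)
  if (any(is.na(x))) stop("input contains missing values", call. = FALSE)
  b <- (x > threshold) + 0L
  dimnames(b) <- dimnames(x)
  StateSeries(b)
}

# Evaluate an expression with a temporary RNG state; restores (or removes)
# .Random.seed afterwards so callers' RNG streams are untouched.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
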