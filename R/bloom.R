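#' Bloom-filter false-positive rate
#'
#' Probability that a non-member query reports present, for a filter with r
#' bits per inserted element and k hash functions:
#' \deqn{F = (1 - e^{-k/r})^k.}
#' At the real-valued optimum k = r ln 2 this reduces to
#' F = (0.6185...)^r.
#'
#' @param r bits per inserted element (m/n), positive.
#' @param k number of hash functions (need not be integer; the real-valued
#'   optimum is sometimes of interest).
#' @return The false-positive probability.
#' @examples
#' bloomFPR(8, 5)            # about 0.0217, i.e. slightly above 2%
#' bloomFPR(8, 8 * log(2))   # (0.6185)^8 at the real-valued optimum
#' @export
bloomFPR <- function(r, k) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(k < 1)) stop("k must be >= 1")
  (1 - exp(-k / r))^k
}

#' Optimal number of hash functions
#'
#' The integer number of hash functions used by default for a filter with r
#' bits per element: floor(r ln 2), clamped to at least 1.  With the package
#' default r = 8 this gives k = 5.
#'
#' @param r bits per inserted element, positive.
#' @return Integer k >= 1.
#' @examples
#' optimalK(8)   # 5
#' optimalK(1)   # 1 (clamped)
#' @export
optimalK <- function(r) {
  if (any(r <= 0)) stop("r must be positive")
  pmax(1L, as.integer(floor(r * log(2))))
}

#' Canonical form of b-mers
#'
#' Returns the lexicographically smaller of each b-mer and its reverse
#' complement, making filter membership strand-symmetric.  b-mers containing
#' characters outside A/C/G/T come back as NA and are skipped by all callers.
#'
#' @param s character vector of b-mers.
#' @param b optional expected length; if supplied, any element of a
#'   different length is an error.
#' @return Character vector of canonical b-mers (NA where invalid).
#' @examples
#' canonicalBmer(c("ACGT", "TTTT"))  # "ACGT", "AAAA"
#' @export
canonicalBmer <- function(s, b = NULL) {
  s <- toupper(as.character(s))
  if (!is.null(b) && any(nchar(s) != b, na.rm = TRUE))
    stop("b-mer length must be exactly ", b)
  canonical_bmer_cpp(s)
}

#' Reverse complement of character sequences
#'
#' Thin character-vector convenience around the C-level complement used by
#' the dispatch and mapping code; for XStringSet objects use
#' \code{Biostrings::reverseComplement}.
#'
#' @param s character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcompChar <- function(s) revcomp_cpp(toupper(as.character(s)))

#' Hash positions of a key
#'
#' The k bit positions a key maps to, from a double-hashing scheme: two
#' independent seeded 64-bit hashes g1, g2 give position_i = (g1 + i g2)
#' mod m for i = 0..k-1.
#'
#' @param key a single character string.
#' @param k number of hash functions.
#' @param m filter size in bits.
#' @param seed base seed of the hash family.
#' @return Numeric vector of k positions in [0, m).
#' @examples
#' hashPositions("ACGTACGT", k = 5, m = 1e6, seed = 1L)
#' @export
hashPositions <- function(key, k, m, seed = 1L) {
  hash_positions_cpp(as.character(key), as.integer(k), as.numeric(m),
                     as.integer(seed))
}

#' @rdname bfInsert
#' @export
setGeneric("bfInsert", function(x, keys) standardGeneric("bfInsert"))

#' @rdname bfContains
#' @export
setGeneric("bfContains", function(x, keys) standardGeneric("bfContains"))

#' Insert keys into a Bloom filter
#'
#' Sets the k hashed bit positions of each key.  Keys are inserted verbatim
#' (no canonicalisation); \code{\link{buildFilter}} and the dispatch stage
#' canonicalise b-mers before touching the filter.  NA keys are skipped.
#'
#' @param x a \code{BloomFilter}.
#' @param keys character vector of keys.
#' @return A new \code{BloomFilter} with the bits set and
#'   \code{nInserted} advanced.
#' @examples
#' f <- BloomFilter(m = 128, k = 3)
#' f <- bfInsert(f, "ACGTACGT")
#' bfContains(f, "ACGTACGT")  # TRUE: no false negatives
#' @aliases bfInsert,BloomFilter-method
#' @name bfInsert
#' @export
setMethod("bfInsert", "BloomFilter", function(x, keys) {
  keys <- as.character(keys)
  x@bits <- bf_insert_keys_cpp(x@bits, x@m, x@k, x@seed, keys)
  x@nInserted <- x@nInserted + sum(!is.na(keys))
  x
})

#' Query a Bloom filter
#'
#' TRUE iff all k hashed bits of the key are set.  A key that was inserted
#' always reports TRUE; a key that was not may report TRUE with probability
#' about \code{\link{bloomFPR}}(m/n, k).
#'
#' @param x a \code{BloomFilter}.
#' @param keys character vector of keys.
#' @return Logical vector (NA where the key is NA).
#' @aliases bfContains,BloomFilter-method
#' @name bfContains
#' @export
setMethod("bfContains", "BloomFilter", function(x, keys) {
  bf_contains_keys_cpp(x@bits, x@m, x@k, x@seed, as.character(keys))
})

#' Build a Bloom filter over a partition's b-mers
#'
#' Scans every length-b window (stride 1) of every target, skips windows
#' containing N, canonicalises the rest and inserts them.  The bit-array
#' size is m = r x (number of valid b-mer positions), so r is the
#' bits-per-insert ratio of Eq.-style FPR predictions; k defaults to
#' \code{\link{optimalK}}(r).
#'
#' @param targets a DNAStringSet or named character vector of target
#'   sequences.
#' @param b b-mer length.
#' @param r bits per inserted element; default 8.
#' @param k number of hash functions; default \code{optimalK(r)}.
#' @param seed base hash seed; all filters queried together must share it.
#' @return A \code{BloomFilter}.
#' @examples
#' tg <- Biostrings::DNAStringSet(c(t1 = "ACGTACGTACGT"))
#' f <- buildFilter(tg, b = 4)
#' bfContains(f, canonicalBmer("ACGT"))  # TRUE
#' @export
buildFilter <- function(targets, b, r = 8, k = optimalK(r), seed = 1L) {
  seqs <- asSeqChar(targets)
  b <- as.integer(b)
  if (b < 1L) stop("b must be >= 1")
  n <- count_valid_bmers_cpp(seqs, b)
  if (n == 0) {
    warning("no valid b-mers of length ", b, " in targets; filter is empty")
    n <- 1
  }
  m <- max(1, round(r * n))
  built <- bf_build_cpp(seqs, b, m, as.integer(k), as.integer(seed))
  new("BloomFilter", bits = built$bits, m = m, k = as.integer(k),
      b = b, seed = as.integer(seed), nInserted = built$nInserted)
}

#' Write / read a Bloom filter file
#'
#' Compact binary format: an 8-byte magic/version, the filter parameters
#' (m, k, b, seed, nInserted), then the raw bit array.  Round-trips exactly.
#'
#' @param x a \code{BloomFilter}.
#' @param path file path (convention: \code{part_<p>.bf}).
#' @return \code{writeBloomFilter} returns \code{path} invisibly;
#'   \code{readBloomFilter} returns the \code{BloomFilter}.
#' @export
writeBloomFilter <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BLMFILT1"), con)
  writeBin(c(x@m, x@nInserted), con, size = 8)
  writeBin(c(x@k, x@b, x@seed), con, size = 4)
  writeBin(x@bits, con)
  invisible(path)
}

#' @rdname writeBloomFilter
#' @export
readBloomFilter <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, "BLMFILT1"))
    stop("not a Bloom filter file: ", path)
  dbl <- readBin(con, "double", 2, size = 8)
  ints <- readBin(con, "integer", 3, size = 4)
  bits <- readBin(con, "raw", ceiling(dbl[1] / 8))
  new("BloomFilter", bits = bits, m = dbl[1], k = ints[1], b = ints[2],
      seed = ints[3], nInserted = dbl[2])
}

# Coerce targets to a plain uppercase character vector, names preserved.
asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(toupper(as.character(x)), names(x))
  } else {
    setNames(toupper(as.character(x)), names(x))
  }
}
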