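#' Choose the dispatch b-mer length
#'
#' The dispatch guarantee (no read with a true exact match of length >= l is
#' ever missed) requires b <= l, where l is the minimum seed or exact-match
#' length of the aligner in use.  By default b = l, the largest valid value
#' (largest filters' specificity); a smaller b may be supplied explicitly.
#'
#' @param l minimum aligner seed / exact-match length, >= 1.
#' @param b optional override; must satisfy b <= l.
#' @return The b to use.
#' @examples
#' chooseB(20)          # 20
#' chooseB(20, b = 16)  # 16
#' @export
chooseB <- function(l, b = NULL) {
  l <- as.integer(l)
  if (is.na(l) || l < 1L) stop("l must be an integer >= 1")
  if (is.null(b)) return(l)
  b <- as.integer(b)
  if (is.na(b) || b < 1L) stop("b must be an integer >= 1")
  if (b > l)
    stop("b (", b, ") must not exceed the minimum aligner seed length l (",
         l, ")")
  b
}

#' Dispatch reads against partition Bloom filters
#'
#' Scans every b-mer (stride 1, N-containing windows skipped) of every read
#' in canonical form against each partition's filter and records the
#' partitions with at least one hit.  Reads shorter than b, or with no hit
#' in any partition, get an empty destination set (i.e. are discarded).
#' Because the filters have no false negatives, a read exactly matching
#' >= b bases of either strand of a partition's targets is always routed
#' there; false-positive hits only route extra copies.
#'
#' @param reads a DNAStringSet, QualityScaledDNAStringSet or named character
#'   vector of read sequences.
#' @param filters list of \code{\link{BloomFilter-class}} objects, one per
#'   partition, all built with the same b and seed.
#' @return A \code{\link{DispatchTable-class}}.
#' @examples
#' tg <- Biostrings::DNAStringSet(c(t = "ACGTACGTACGTACGTACGT"))
#' f <- buildFilter(tg, b = 8)
#' dt <- dispatchReads(c(r1 = "ACGTACGTACGT", r2 = "TTTTTTTTTTTT"), list(f))
#' discardedReads(dt)  # r2
#' @export
dispatchReads <- function(reads, filters) {
  seqs <- asSeqChar(reads)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("read", seq_along(seqs))
  if (!length(filters) || !all(vapply(filters, methods::is, logical(1),
                                      "BloomFilter")))
    stop("filters must be a non-empty list of BloomFilter objects")
  bs <- vapply(filters, bmerLength, integer(1))
  if (length(unique(bs)) != 1L || anyNA(bs))
    stop("all filters must share one b-mer length; got: ",
         paste(bs, collapse = ", "))
  seeds <- vapply(filters, function(f) f@seed, integer(1))
  if (length(unique(seeds)) != 1L)
    stop("all filters must share one hash seed")
  flist <- lapply(filters, function(f)
    list(bits = f@bits, m = f@m, k = f@k, seed = f@seed))
  dest <- dispatch_reads_cpp(unname(seqs), flist, bs[1])
  new("DispatchTable", readIds = names(seqs), destinations = dest, b = bs[1])
}

#' Dispatch reads and write per-partition read files
#'
#' Runs \code{\link{dispatchReads}}, then writes each partition's reads (in
#' input order, duplicated into every destination partition so partitions
#' are independently alignable) to \code{part_<p>.reads.fq}, the IDs of
#' discarded reads to \code{discarded.txt}, and the full table to
#' \code{dispatch.tsv}.
#'
#' @param reads as in \code{\link{dispatchReads}}; if a
#'   QualityScaledDNAStringSet, its qualities are written, otherwise a
#'   constant high quality is synthesised.
#' @param filters list of per-partition \code{BloomFilter}s.
#' @param outdir output directory.
#' @return The \code{\link{DispatchTable-class}}, invisibly annotated with
#'   the file paths in \code{attr(, "files")}.
#' @export
dispatchAll <- function(reads, filters, outdir) {
  dt <- dispatchReads(reads, filters)
  seqs <- asSeqChar(reads)
  if (is.null(names(seqs))) names(seqs) <- dt@readIds
  quals <- readQualities(reads, nchar(seqs))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  P <- length(filters)
  files <- character(P)
  for (p in seq_len(P)) {
    sel <- vapply(dt@destinations, function(d) p %in% d, logical(1))
    files[p] <- file.path(outdir, sprintf("part_%d.reads.fq", p))
    writeFastq(seqs[sel], quals[sel], files[p])
  }
  discPath <- file.path(outdir, "discarded.txt")
  writeLines(discardedReads(dt), discPath)
  tabPath <- file.path(outdir, "dispatch.tsv")
  df <- data.frame(read = dt@readIds,
                   partitions = vapply(dt@destinations, paste,
                                       character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, tabPath, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(dt, "files") <- list(reads = files, discarded = discPath,
                            table = tabPath)
  invisible(dt)
}

# Extract per-read quality strings; synthesise constant Phred-40 ('I') when
# the container carries none.
readQualities <- function(reads, widths) {
  if (methods::is(reads, "QualityScaledXStringSet")) {
    as.character(Biostrings::quality(reads))
  } else {
    strrep("I", widths)
  }
}

# Minimal FASTQ writer (IDs from names, one record per read).
writeFastq <- function(seqs, quals, path) {
  if (length(seqs) == 0) { writeLines(character(), path); return(invisible(path)) }
  lines <- rbind(paste0("@", names(seqs)), unname(seqs), "+", unname(quals))
  writeLines(as.vector(lines), path)
  invisible(path)
}
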