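#' Build a seed index over a target set
#'
#' Indexes every l-mer occurrence of every target for the built-in
#' exact-match mapper.  \code{\link{seedIndexEntries}} materialises the
#' table (canonical l-mer, target, 0-based offset, strand) for inspection;
#' \code{\link{exactMap}} consumes the index directly.
#'
#' @param targets named DNAStringSet (or named character vector).
#' @param l seed length (= minimum reportable exact-match length), >= 1.
#' @return A \code{\link{SeedIndex-class}}.
#' @examples
#' idx <- buildSeedIndex(c(t = "AAAA"), l = 2)
#' seedIndexEntries(idx)   # "AA" at offsets 0,1,2, strand "+"
#' @export
buildSeedIndex <- function(targets, l) {
  l <- as.integer(l)
  if (is.na(l) || l < 1L) stop("l must be an integer >= 1")
  seqs <- asSeqChar(targets)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("target", seq_along(seqs))
  tg <- Biostrings::DNAStringSet(seqs)
  new("SeedIndex", targets = tg, seedLength = l)
}

#' @describeIn buildSeedIndex the occurrence table: one row per l-mer
#'   occurrence, with the canonical l-mer, 1-based target index, 0-based
#'   offset and the strand on which the canonical form occurs.
#' @param idx a \code{SeedIndex}.
#' @export
seedIndexEntries <- function(idx) {
  stopifnot(methods::is(idx, "SeedIndex"))
  df <- seed_index_entries_cpp(as.character(idx@targets), idx@seedLength)
  df$target <- names(idx@targets)[df$target]
  df
}

#' Exact-match seed-and-extend mapping
#'
#' The built-in aligner: every l-mer of the read (both orientations) is
#' looked up in the seed index and each hit is extended to the maximal
#' exact match on its diagonal.  The longest match wins; ties break by
#' leftmost offset in the oriented read, then target input order, then
#' smaller target position, then forward strand.  MAPQ is 60 when the
#' maximal length occurs at exactly one (target, position, strand) and 0
#' otherwise; the match length is reported as the AS tag.  Reads with no
#' exact match of length >= l yield an unmapped record.  Reverse-strand
#' hits are reported with flag 0x10 and reverse-complemented SEQ (and
#' reversed quality); unmatched flanks are soft-clipped.
#'
#' @param reads named character vector, DNAStringSet or
#'   QualityScaledDNAStringSet.
#' @param idx a \code{\link{SeedIndex-class}} built on the targets to map
#'   against.
#' @return SAM-record data.frame (one record per read) as used by
#'   \code{\link{writeSam}}.
#' @examples
#' idx <- buildSeedIndex(c(t = "GGGGACGTACGTACGTTTTT"), l = 8)
#' exactMap(c(r = "ACGTACGTACGT"), idx)[, c("rname", "pos", "cigar", "mapq")]
#' @export
exactMap <- function(reads, idx) {
  stopifnot(methods::is(idx, "SeedIndex"))
  seqs <- asSeqChar(reads)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("read", seq_along(seqs))
  quals <- readQualities(reads, nchar(seqs))
  df <- exact_map_cpp(as.character(idx@targets), names(idx@targets),
                      unname(seqs), names(seqs), idx@seedLength)
  rev <- bitwAnd(df$flag, 16L) != 0L
  qual <- quals
  if (any(rev)) qual[rev] <- reverseStrings(qual[rev])
  df$qual <- qual
  df$pos <- as.integer(df$pos)
  df$nbest <- NULL
  df
}

reverseStrings <- function(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))

#' Align one partition's reads against its targets
#'
#' Produces a complete SAM result for a partition: a header with @@SQ lines
#' for the partition's targets (in partition-FASTA order) and one record
#' per dispatched read.  The \code{"builtin"} adapter is the exact mapper
#' (\code{\link{exactMap}}); any other adapter name must be registered in
#' \code{adapters} as a command template run via
#' \code{\link{externalAdapter}}.
#'
#' @param targets partition targets: a named DNAStringSet or a FASTA path.
#' @param reads dispatched reads: a (QualityScaled)DNAStringSet, named
#'   character vector or FASTQ/FASTA path.
#' @param aligner adapter name; default \code{"builtin"}.
#' @param l minimum seed / exact-match length of the built-in aligner.
#' @param out optional path; when given the SAM is written there.
#' @param adapters named list of external command templates (see
#'   \code{\link{externalAdapter}}).
#' @return list(header, records), invisibly when \code{out} is given.
#' @export
alignPartition <- function(targets, reads, aligner = "builtin", l = 20L,
                           out = NULL, adapters = adapterPresets()) {
  targetPath <- NULL
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    targetPath <- targets
    targets <- readFastaSeqs(targets)
  }
  readPath <- NULL
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    readPath <- reads
    reads <- readReads(reads)
  }
  if (identical(aligner, "builtin")) {
    idx <- buildSeedIndex(targets, l)
    rec <- exactMap(reads, idx)
    header <- samHeader(targets)
  } else {
    if (!aligner %in% names(adapters))
      stop("unknown aligner adapter '", aligner, "'; registered: ",
           paste(names(adapters), collapse = ", "))
    if (is.null(targetPath) || is.null(readPath))
      stop("external adapters need file paths for targets and reads")
    samLines <- externalAdapter(adapters[[aligner]], targetPath, readPath)
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(samLines, tmp)
    parsed <- readSam(tmp, strict = FALSE)
    header <- parsed$header
    rec <- parsed$records
  }
  if (!is.null(out)) {
    writeSam(rec, header, out)
    return(invisible(list(header = header, records = rec)))
  }
  list(header = header, records = rec)
}

#' Run an external aligner through a command template
#'
#' The template is a shell pipeline with \code{{target}} and \code{{reads}}
#' placeholders, which are substituted with shell-quoted paths (so paths
#' with spaces are safe) and run with \code{sh -c}; the SAM output is
#' captured from stdout.  A non-zero exit aborts with the captured stderr.
#'
#' @param template command template, e.g.
#'   \code{"bwa index {target} && bwa mem {target} {reads}"}.
#' @param targetFasta partition FASTA path.
#' @param readsFile dispatched reads path.
#' @return Character vector of SAM lines.
#' @export
externalAdapter <- function(template, targetFasta, readsFile) {
  cmd <- gsub("{target}", shQuote(targetFasta), template, fixed = TRUE)
  cmd <- gsub("{reads}", shQuote(readsFile), cmd, fixed = TRUE)
  errFile <- tempfile()
  on.exit(unlink(errFile), add = TRUE)
  res <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = errFile))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    err <- paste(readLines(errFile, warn = FALSE), collapse = "\n")
    stop("aligner adapter failed (exit ", status, "): ", cmd,
         if (nzchar(err)) paste0("\n", err))
  }
  res
}

#' Preset external-adapter templates
#'
#' Command templates for common third-party aligners; the binaries are not
#' shipped and must be on PATH for the corresponding adapter to work.
#'
#' @return Named list of templates for \code{\link{externalAdapter}}.
#' @export
adapterPresets <- function() {
  list(
    bwa = "bwa index {target} >&2 && bwa mem -v 1 {target} {reads}",
    bowtie2 = paste("bowtie2-build --quiet {target} {target}.idx >&2 &&",
                    "bowtie2 -x {target}.idx -U {reads} -S /dev/stdout"),
    novoalign = "novoindex {target}.ndx {target} >&2 && novoalign -d {target}.ndx -f {reads} -o SAM"
  )
}
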