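#' Read target sequences from FASTA
#'
#' Wraps \code{Biostrings::readDNAStringSet}: multi-line records and gzip
#' are handled there.  Sequences are uppercased, names are truncated at the
#' first whitespace, and empty sequences or duplicate IDs are errors.
#'
#' @param path FASTA file (optionally gzipped).
#' @return A named DNAStringSet.
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence IDs in ", path)
  if (any(Biostrings::width(x) == 0))
    stop("empty sequence record in ", path)
  Biostrings::DNAStringSet(setNames(toupper(as.character(x)), names(x)))
}

#' Read reads from FASTQ or FASTA
#'
#' FASTQ (extensions .fq/.fastq, optionally .gz) is parsed strictly:
#' 4-line records, matching sequence/quality lengths, errors reported with
#' their line number.  FASTA reads are accepted with a synthesised constant
#' quality.
#'
#' @param path reads file.
#' @return A QualityScaledDNAStringSet.
#' @export
readReads <- function(path) {
  isFq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (isFq) {
    lines <- sub("\r$", "", readLines(path))  # file() auto-inflates gzip
    if (length(lines) == 0L)
      return(Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
    if (length(lines) %% 4L != 0L)
      stop(path, ": FASTQ line count not a multiple of 4")
    i <- seq(1L, length(lines), by = 4L)
    if (any(!startsWith(lines[i], "@")))
      stop(path, ": missing '@' header at line ",
           i[which(!startsWith(lines[i], "@"))[1]])
    if (any(!startsWith(lines[i + 2L], "+")))
      stop(path, ": missing '+' separator at line ",
           (i + 2L)[which(!startsWith(lines[i + 2L], "+"))[1]])
    seqs <- toupper(lines[i + 1L])
    quals <- lines[i + 3L]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop(path, ": sequence/quality length mismatch at line ", i[bad[1]])
    if (any(nchar(seqs) == 0L))
      stop(path, ": empty sequence at line ", i[which(nchar(seqs) == 0L)[1]])
    names(seqs) <- sub("\\s.*$", "", sub("^@", "", lines[i]))
    names(quals) <- names(seqs)
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  } else {
    s <- readFastaSeqs(path)
    x <- Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(
        setNames(strrep("I", Biostrings::width(s)), names(s))))
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads as FASTQ
#'
#' @param reads a QualityScaledDNAStringSet (or DNAStringSet, in which case
#'   a constant quality is written).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  seqs <- asSeqChar(reads)
  writeFastq(seqs, readQualities(reads, nchar(seqs)), path)
}

# ---------------------------------------------------------------------------
# Minimal strict SAM text layer.  Records travel as a data.frame with
# columns qname, flag, rname, pos, mapq, cigar, seq, qual, AS (NA when the
# aligner reported no score).  Coordinates are 1-based only here, at the
# serialisation boundary.
# ---------------------------------------------------------------------------

#' Build a SAM header for a target set
#'
#' @param targets named DNAStringSet (order defines @@SQ order).
#' @param pg optional program-line description.
#' @return A list with elements \code{sq} (data.frame rname, length) and
#'   \code{pg} (character vector of @@PG lines).
#' @export
samHeader <- function(targets, pg = "BloomAlign") {
  lens <- if (methods::is(targets, "XStringSet")) Biostrings::width(targets)
          else nchar(asSeqChar(targets))
  nm <- names(targets)
  if (is.null(nm)) nm <- character(0)
  list(sq = data.frame(rname = as.character(nm), length = as.integer(lens),
                       stringsAsFactors = FALSE),
       pg = sprintf("@PG\tID:%s\tPN:%s", pg, pg))
}

emptyRecords <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(), AS = integer(),
             stringsAsFactors = FALSE)
}

#' An unmapped SAM record
#'
#' @param qname read ID.
#' @param seq,qual sequence/quality to carry along ("*" when unknown).
#' @return One-row record data.frame (flag 4, rname "*", pos 0, cigar "*").
#' @export
unmappedRecord <- function(qname, seq = "*", qual = "*") {
  data.frame(qname = qname, flag = 4L, rname = "*", pos = 0L, mapq = 0L,
             cigar = "*", seq = seq, qual = qual, AS = NA_integer_,
             stringsAsFactors = FALSE)
}

cigarLengths <- function(cigar, ops) {
  vapply(cigar, function(cg) {
    if (identical(cg, "*")) return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    typ <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[typ %in% ops])
  }, integer(1), USE.NAMES = FALSE)
}

#' CIGAR read- and reference-consuming lengths
#'
#' @param cigar character vector of CIGAR strings ("*" gives NA).
#' @return Integer vector of consumed bases.
#' @export
cigarReadLength <- function(cigar) cigarLengths(cigar, c("M", "I", "S", "=", "X"))

#' @rdname cigarReadLength
#' @export
cigarRefLength <- function(cigar) cigarLengths(cigar, c("M", "D", "N", "=", "X"))

#' Write SAM
#'
#' @param records record data.frame (see \code{\link{readSam}} for the
#'   column contract).
#' @param header header list from \code{\link{samHeader}} or
#'   \code{\link{mergeHeaders}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(records, header, path) {
  hd <- c("@HD\tVN:1.6\tSO:unsorted",
          sprintf("@SQ\tSN:%s\tLN:%d", header$sq$rname, header$sq$length),
          header$pg)
  body <- character(0)
  if (nrow(records)) {
    tags <- ifelse(is.na(records$AS), "", sprintf("\tAS:i:%d", records$AS))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                    records$qname, records$flag, records$rname, records$pos,
                    records$mapq, records$cigar, records$seq, records$qual,
                    tags)
  }
  writeLines(c(hd, body), path)
  invisible(path)
}

#' Read SAM (strict)
#'
#' Minimal SAM text parser for the merge stage and for validating pipeline
#' outputs.  In strict mode (default) every record must reference an @@SQ
#' target (or "*"), unmapped flags must be consistent with rname/pos/cigar,
#' the CIGAR read-consuming length must equal the sequence length, and the
#' alignment must not overrun the target.
#'
#' @param path SAM file.
#' @param strict validate records against the header.
#' @return list(header = list(sq, pg), records = data.frame) with an
#'   extracted integer AS column (NA where absent).
#' @export
readSam <- function(path, strict = TRUE) {
  lines <- readLines(path)
  isHd <- startsWith(lines, "@")
  hd <- lines[isHd]
  sqLines <- hd[startsWith(hd, "@SQ")]
  sq <- data.frame(rname = character(), length = integer(),
                   stringsAsFactors = FALSE)
  if (length(sqLines)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sqLines)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sqLines))
    sq <- data.frame(rname = sn, length = ln, stringsAsFactors = FALSE)
  }
  header <- list(sq = sq, pg = hd[startsWith(hd, "@PG")])
  body <- lines[!isHd]
  body <- body[nzchar(body)]
  if (!length(body)) return(list(header = header, records = emptyRecords()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 11L)
  if (length(short))
    stop("SAM record with fewer than 11 fields at ", path, " line ",
         which(!isHd)[short[1]])
  f <- function(i) vapply(parts, `[`, character(1), i)
  asv <- vapply(parts, function(x) {
    hit <- grep("^AS:i:", x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("^AS:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  rec <- data.frame(qname = f(1), flag = as.integer(f(2)), rname = f(3),
                    pos = as.integer(f(4)), mapq = as.integer(f(5)),
                    cigar = f(6), seq = f(10), qual = f(11), AS = asv,
                    stringsAsFactors = FALSE)
  if (strict) validateSamRecords(rec, header, path)
  list(header = header, records = rec)
}

validateSamRecords <- function(rec, header, context = "SAM") {
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  bad <- unmapped & !(rec$rname == "*" & rec$pos == 0L & rec$cigar == "*")
  if (any(bad))
    stop(context, ": unmapped record with mapped fields (", rec$qname[bad][1], ")")
  mapped <- !unmapped
  if (any(mapped)) {
    unknown <- mapped & !(rec$rname %in% header$sq$rname)
    if (any(unknown))
      stop(context, ": record references unknown target ",
           rec$rname[unknown][1])
    hasSeq <- mapped & rec$seq != "*"
    rl <- cigarReadLength(rec$cigar)
    bad <- hasSeq & !is.na(rl) & rl != nchar(rec$seq)
    if (any(bad))
      stop(context, ": CIGAR/SEQ length mismatch for ", rec$qname[bad][1])
    ln <- setNames(header$sq$length, header$sq$rname)
    span <- cigarRefLength(rec$cigar)
    over <- mapped & (rec$pos < 1L |
                      rec$pos + ifelse(is.na(span), 0L, span) - 1L >
                        ln[rec$rname])
    if (any(over, na.rm = TRUE))
      stop(context, ": alignment overruns target for ",
           rec$qname[which(over)[1]])
  }
  invisible(TRUE)
}
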