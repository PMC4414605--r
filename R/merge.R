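#' Merge per-partition SAM headers
#'
#' The partitions' @@SQ sets must be pairwise disjoint (a target in two
#' partitions means the partitioning was violated) and their union must
#' cover the manifest exactly; the merged header lists @@SQ in original
#' target-file (manifest) order and adds one @@PG line for the pipeline.
#'
#' @param headers list of per-partition header lists (as from
#'   \code{\link{readSam}} or \code{\link{samHeader}}).
#' @param manifest data.frame with columns target, partition, length (as in
#'   \code{partitions.tsv}), in original target order.
#' @return A merged header list.
#' @export
mergeHeaders <- function(headers, manifest) {
  sq <- do.call(rbind, lapply(headers, `[[`, "sq"))
  dup <- sq$rname[duplicated(sq$rname)]
  if (length(dup))
    stop("target declared by more than one partition: ",
         paste(unique(dup), collapse = ", "))
  if (!setequal(sq$rname, manifest$target))
    stop("partition @SQ union does not match the manifest")
  ord <- match(manifest$target, sq$rname)
  if (!all(sq$length[ord] == manifest$length))
    stop("@SQ lengths disagree with the manifest")
  list(sq = data.frame(rname = manifest$target,
                       length = manifest$length,
                       stringsAsFactors = FALSE),
       pg = "@PG\tID:BloomAlign\tPN:BloomAlign\tCL:merge")
}

# Collect partition record streams into one frame with a partition column.
# `streams` may be record data.frames or SAM file paths.
gatherStreams <- function(streams) {
  recs <- lapply(seq_along(streams), function(p) {
    s <- streams[[p]]
    if (is.character(s)) s <- readSam(s)$records
    if (is.list(s) && !is.data.frame(s)) s <- s$records
    if (nrow(s)) s$partition <- p else s$partition <- integer(0)
    s
  })
  do.call(rbind, recs)
}

# Ranking shared by best and multi mode: higher MAPQ first, then higher AS,
# then partition index, rname, pos, forward strand — fully deterministic.
rankOrder <- function(m) {
  as <- ifelse(is.na(m$AS), -Inf, m$AS)
  order(m$qname, -m$mapq, -as, m$partition, m$rname, m$pos,
        bitwAnd(m$flag, 16L))
}

#' Best-record merge of per-partition alignments
#'
#' For each read, selects the mapped record with the highest mapping
#' quality across all partition streams (ties by AS score, then a
#' deterministic tie-break: lower partition index, target name, position,
#' forward strand).  Reads with no mapped record anywhere — including reads
#' discarded at dispatch — are emitted once as unmapped records when
#' \code{emitUnmapped} is TRUE, so every input read is accounted for
#' exactly once.
#'
#' @param streams list of per-partition record data.frames or SAM paths.
#' @param discarded character vector of read IDs discarded at dispatch.
#' @param readIds optional full read universe in desired output order; any
#'   ID present here but absent from every stream and from
#'   \code{discarded} is an accounting error.  Defaults to the IDs seen in
#'   the streams plus \code{discarded}.
#' @param emitUnmapped emit flag-4 records for unaligned reads.
#' @param flagCrossPartitionTies when TRUE, a read whose best (mapq, AS)
#'   is achieved in more than one partition gets MAPQ 0 in the output: the
#'   per-partition aligners could not see each other's copies, so their
#'   uniqueness claims are unreliable in that case.
#' @param reads optional named sequences used to fill SEQ/QUAL of unmapped
#'   records for discarded reads (otherwise "*").
#' @return Merged record data.frame, one row per read (when
#'   \code{emitUnmapped}), ordered by \code{readIds}.
#' @export
mergeBest <- function(streams, discarded = character(), readIds = NULL,
                      emitUnmapped = TRUE, flagCrossPartitionTies = FALSE,
                      reads = NULL) {
  all <- gatherStreams(streams)
  seen <- unique(all$qname)
  if (is.null(readIds)) {
    readIds <- sort(unique(c(seen, discarded)))  # arrival-order independent
  } else {
    missing <- setdiff(readIds, c(seen, discarded))
    if (length(missing))
      stop("read(s) in neither any stream nor the discarded list: ",
           paste(head(missing, 5), collapse = ", "))
  }
  mapped <- all[bitwAnd(all$flag, 4L) == 0L, , drop = FALSE]
  best <- mapped[rankOrder(mapped), , drop = FALSE]
  if (flagCrossPartitionTies && nrow(best)) {
    key <- paste(best$qname, best$mapq,
                 ifelse(is.na(best$AS), -1L, best$AS))
    nPart <- vapply(split(best$partition, key), function(p)
      length(unique(p)), integer(1))
    topKey <- key[!duplicated(best$qname)]
    tied <- names(nPart)[nPart > 1L]
    zero <- best$qname[!duplicated(best$qname)][topKey %in% tied]
  } else zero <- character(0)
  best <- best[!duplicated(best$qname), , drop = FALSE]
  if (length(zero)) best$mapq[best$qname %in% zero] <- 0L
  out <- best
  if (emitUnmapped) {
    un <- setdiff(readIds, best$qname)
    if (length(un)) {
      seqs <- rep("*", length(un)); quals <- rep("*", length(un))
      # prefer the read's own sequence when available
      if (!is.null(reads)) {
        rs <- asSeqChar(reads)
        hit <- un %in% names(rs)
        seqs[hit] <- rs[un[hit]]
        quals[hit] <- readQualities(reads, nchar(rs))[match(un[hit], names(rs))]
      } else {
        unrec <- all[bitwAnd(all$flag, 4L) != 0L, , drop = FALSE]
        hit <- match(un, unrec$qname)
        seqs[!is.na(hit)] <- unrec$seq[hit[!is.na(hit)]]
        quals[!is.na(hit)] <- unrec$qual[hit[!is.na(hit)]]
      }
      out <- rbind(out, cbind(unmappedRecord(un, seqs, quals),
                              partition = NA_integer_))
    }
  }
  out <- out[order(match(out$qname, readIds)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-record merge of per-partition alignments
#'
#' Like \code{\link{mergeBest}} but emits up to \code{maxRecords} distinct
#' mapped records per read, ranked as in best mode.  Distinctness key is
#' (rname, pos, strand, cigar); duplicates — including identical records
#' arriving from one stream — collapse to one.  The top record is primary;
#' the rest carry the secondary-alignment flag 0x100.  With
#' \code{maxRecords = 1} the output equals \code{mergeBest}.
#'
#' @inheritParams mergeBest
#' @param maxRecords maximum distinct records per read, >= 1.
#' @return Merged record data.frame.
#' @export
mergeMulti <- function(streams, discarded = character(), maxRecords = 1L,
                       readIds = NULL, emitUnmapped = TRUE, reads = NULL) {
  maxRecords <- as.integer(maxRecords)
  if (is.na(maxRecords) || maxRecords < 1L) stop("maxRecords must be >= 1")
  all <- gatherStreams(streams)
  seen <- unique(all$qname)
  if (is.null(readIds)) readIds <- sort(unique(c(seen, discarded)))
  mapped <- all[bitwAnd(all$flag, 4L) == 0L, , drop = FALSE]
  mapped <- mapped[rankOrder(mapped), , drop = FALSE]
  dkey <- paste(mapped$qname, mapped$rname, mapped$pos,
                bitwAnd(mapped$flag, 16L), mapped$cigar)
  mapped <- mapped[!duplicated(dkey), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(mapped)), mapped$qname),
                        head, maxRecords), use.names = FALSE)
  mapped <- mapped[sort(keep), , drop = FALSE]
  secondary <- duplicated(mapped$qname)
  mapped$flag <- ifelse(secondary, bitwOr(mapped$flag, 256L), mapped$flag)
  out <- mapped
  if (emitUnmapped) {
    un <- setdiff(readIds, mapped$qname)
    if (length(un)) {
      seqs <- rep("*", length(un)); quals <- rep("*", length(un))
      if (!is.null(reads)) {
        rs <- asSeqChar(reads)
        hit <- un %in% names(rs)
        seqs[hit] <- rs[un[hit]]
        quals[hit] <- readQualities(reads, nchar(rs))[match(un[hit], names(rs))]
      }
      out <- rbind(out, cbind(unmappedRecord(un, seqs, quals),
                              partition = NA_integer_))
    }
  }
  out <- out[order(match(out$qname, readIds),
                   bitwAnd(out$flag, 256L)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
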