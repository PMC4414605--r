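#' Run the full partition / index / dispatch / align / merge pipeline
#'
#' Executes the complete workflow against one read set: plan balanced
#' target partitions (respecting the adjacency graph when given), write
#' per-partition FASTAs, build one Bloom filter of canonical b-mers per
#' partition, dispatch every read to the partitions whose filter hits it,
#' align each partition independently, and merge the per-partition SAM
#' outputs into the final SAM.  All stage outputs are persisted under
#' \code{outdir} so any stage can be rerun or inspected, and a JSON run
#' report summarises the partition loads, filter occupancies and dispatch
#' statistics.
#'
#' @param targets named DNAStringSet or FASTA path of target sequences.
#' @param reads reads as a (QualityScaled)DNAStringSet, named character
#'   vector, or FASTQ/FASTA path.
#' @param graph optional \code{\link{AdjacencyGraph-class}} or edge-list
#'   TSV path; graph-linked targets are co-partitioned.
#' @param P number of partitions, >= 1.
#' @param l minimum aligner seed / exact-match length; default 20.
#' @param b dispatch b-mer length; default \code{\link{chooseB}(l)} = l.
#' @param r Bloom-filter bits per b-mer; default 8.
#' @param seed hash seed shared by all partition filters.
#' @param outdir working/output directory.
#' @param aligner adapter name for \code{\link{alignPartition}}.
#' @param mode merge mode, "best" or "multi".
#' @param maxRecords records per read in multi mode.
#' @param emitUnmapped emit unmapped records for unaligned reads.
#' @param threads process count for the per-partition align stage (uses
#'   \code{parallel::mclapply} when > 1; each partition stage is a pure
#'   function of that partition's files, so pooled and serial execution
#'   give identical output).
#' @return Invisibly, list(sam, report, plan, dispatch, partitionSams).
#' @examples
#' fr <- fragmentGenome(genGenome(4000, 1), nContigs = 4, overlap = 0,
#'                      seed = 2, keepEdges = 0)
#' sim <- simulateReads(fr$targets, 50, readLength = 60, errorRate = 0,
#'                      seed = 3)
#' out <- runPipeline(fr$targets, sim$reads, P = 2,
#'                    outdir = tempfile("pipe"))
#' out$report$dispatch$discarded
#' @export
runPipeline <- function(targets, reads, graph = NULL, P = 1L, l = 20L,
                        b = NULL, r = 8, seed = 1L, outdir, aligner = "builtin",
                        mode = c("best", "multi"), maxRecords = 3L,
                        emitUnmapped = TRUE, threads = 1L) {
  mode <- match.arg(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(targets) && length(targets) == 1L)
    targets <- readFastaSeqs(targets)
  if (is.character(reads) && length(reads) == 1L)
    reads <- readReads(reads)
  if (is.character(graph) && length(graph) == 1L)
    graph <- readAdjacencyGraph(graph, targetIds = names(targets))
  b <- chooseB(l, b)

  # distribute
  plan <- planPartitions(targets, P, graph)
  files <- writePartitionFastas(targets, plan, outdir)
  partTargets <- lapply(seq_len(plan@P), function(p)
    targets[names(targets)[plan@assignment[names(targets)] == p]])

  # index (Bloom filters)
  filters <- vector("list", plan@P)
  for (p in seq_len(plan@P)) {
    filters[[p]] <- if (length(partTargets[[p]]))
      buildFilter(partTargets[[p]], b = b, r = r, seed = seed)
    else BloomFilter(m = max(1, round(r)), k = optimalK(r), b = b, seed = seed)
    writeBloomFilter(filters[[p]], file.path(outdir, sprintf("part_%d.bf", p)))
  }

  # dispatch
  dt <- dispatchAll(reads, filters, outdir)
  dest <- dt@destinations

  # align, one partition at a time (pure per-partition stage)
  alignOne <- function(p) {
    sel <- vapply(dest, function(d) p %in% d, logical(1))
    out <- file.path(outdir, sprintf("part_%d.sam", p))
    alignPartition(partTargets[[p]], reads[sel], aligner = aligner, l = l,
                   out = out)
    out
  }
  partSams <- if (threads > 1L) {
    unlist(parallel::mclapply(seq_len(plan@P), alignOne, mc.cores = threads))
  } else vapply(seq_len(plan@P), alignOne, character(1))

  # merge
  manifest <- read.delim(files$manifest, stringsAsFactors = FALSE)
  streams <- lapply(partSams, readSam)
  header <- mergeHeaders(lapply(streams, `[[`, "header"), manifest)
  merged <- if (mode == "best") {
    mergeBest(lapply(streams, `[[`, "records"), discarded = discardedReads(dt),
              readIds = dt@readIds, emitUnmapped = emitUnmapped, reads = reads)
  } else {
    mergeMulti(lapply(streams, `[[`, "records"), discarded = discardedReads(dt),
               maxRecords = maxRecords, readIds = dt@readIds,
               emitUnmapped = emitUnmapped, reads = reads)
  }
  samOut <- file.path(outdir, "out.sam")
  writeSam(merged, header, samOut)

  multiplicity <- table(factor(lengths(dest), levels = 0:plan@P))
  report <- list(
    P = plan@P, b = b, l = as.integer(l), r = r,
    partitions = list(bases = as.numeric(plan@loads),
                      targets = as.integer(tabulate(plan@assignment, plan@P)),
                      filterOccupancy = vapply(filters, bfOccupancy, numeric(1)),
                      dispatched = dispatchCounts(dt, plan@P)),
    dispatch = list(reads = length(dt@readIds),
                    discarded = length(discardedReads(dt)),
                    multiplicityHistogram = as.list(setNames(
                      as.integer(multiplicity), names(multiplicity)))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sam = samOut, report = report, plan = plan, dispatch = dt,
                 partitionSams = partSams, merged = merged, header = header))
}
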