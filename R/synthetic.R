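# Ground-truthed simulator: random genome -> overlapping contigs with an
# adjacency graph -> reads with known source coordinates.  Everything is a
# pure function of its seed, so fixtures are regenerated rather than stored.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T of the requested length; fully reproducible from
#' the seed and independent of the caller's RNG state.
#'
#' @param length genome length in bases, >= 1.
#' @param seed RNG seed.
#' @return A single character string.
#' @examples
#' g <- genGenome(50, seed = 1)
#' nchar(g)  # 50
#' @export
genGenome <- function(length, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  withSeed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                       collapse = ""))
}

#' Fragment a genome into contigs with an overlap-derived adjacency graph
#'
#' Tiles the genome into \code{nContigs} contigs at jittered breakpoints.
#' Each interior boundary is independently kept as an adjacency edge with
#' probability \code{keepEdges}; a kept boundary makes the upstream contig
#' extend \code{overlap} bases into the downstream one (the assembler-style
#' overlap the edge records), while a withheld boundary drops both the edge
#' and the overlap, so distinct graph components share no sequence — the
#' degenerate case \code{overlap = 0, keepEdges = 0} is the unrelated
#' (static) target scenario.
#'
#' @param genome character string (or DNAString) to fragment.
#' @param nContigs number of contigs, >= 1.
#' @param overlap bases shared across each kept boundary; must be smaller
#'   than the shortest contig.
#' @param seed RNG seed (breakpoint jitter and edge retention).
#' @param keepEdges probability that an interior boundary keeps its edge.
#' @return list(targets = named DNAStringSet, graph = AdjacencyGraph,
#'   starts = 0-based contig start offsets in the genome).
#' @examples
#' fr <- fragmentGenome(genGenome(2000, 1), nContigs = 4, overlap = 20,
#'                      seed = 2)
#' length(fr$targets)  # 4
#' @export
fragmentGenome <- function(genome, nContigs, overlap = 50, seed = 1L,
                           keepEdges = 1) {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  nContigs <- as.integer(nContigs)
  if (nContigs < 1L) stop("nContigs must be >= 1")
  if (keepEdges < 0 || keepEdges > 1) stop("keepEdges must be in [0, 1]")
  span <- L / nContigs
  if (span < 2 * (overlap + 2))
    stop("infeasible: contigs too short for the requested overlap")
  withSeed(seed, {
    bp <- round(seq(0, L, length.out = nContigs + 1))
    if (nContigs > 1L) {
      jitter <- round(runif(nContigs - 1L, -span / 4, span / 4))
      bp[2:nContigs] <- bp[2:nContigs] + jitter
    }
    keep <- if (nContigs > 1L) runif(nContigs - 1L) < keepEdges else logical(0)
    ov <- c(ifelse(keep, round(overlap), 0L), 0L)  # extension past boundary i
    starts <- bp[seq_len(nContigs)]
    ends <- pmin(bp[-1] + ov, L)
    if (any(ends - starts < 1))
      stop("infeasible breakpoints (zero-length contig)")
    ids <- sprintf("ctg%03d", seq_len(nContigs))
    seqs <- substring(genome, starts + 1, ends)
    names(seqs) <- ids
    edges <- if (any(keep)) {
      cbind(ids[which(keep)], ids[which(keep) + 1L])
    } else matrix(character(), ncol = 2)
    list(targets = Biostrings::DNAStringSet(seqs),
         graph = AdjacencyGraph(ids, edges),
         starts = setNames(starts, ids))
  })
}

#' Simulate reads with known source coordinates
#'
#' Source contigs are drawn length-weighted, offsets uniformly, strands
#' Bernoulli(0.5); each base is substituted independently with probability
#' \code{errorRate} (substitutions only — no indels, matching the
#' exact-match built-in aligner).  The truth table carries, per read, the
#' source contig, the 0-based forward-strand offset of the sampled window,
#' the strand, and the number of substitutions introduced.
#'
#' @param targets named DNAStringSet (or named character vector) of source
#'   sequences.
#' @param nReads number of reads.
#' @param readLength read length; must not exceed the shortest target.
#' @param errorRate per-base substitution probability in [0, 1).
#' @param seed RNG seed.
#' @return list(reads = QualityScaledDNAStringSet with constant quality,
#'   truth = data.frame(read, target, offset, strand, nErrors)).
#' @examples
#' tg <- Biostrings::DNAStringSet(c(c1 = genGenome(500, 3)))
#' sim <- simulateReads(tg, nReads = 5, readLength = 50, errorRate = 0,
#'                      seed = 4)
#' sim$truth
#' @export
simulateReads <- function(targets, nReads, readLength = 100,
                          errorRate = 0.01, seed = 1L) {
  seqs <- asSeqChar(targets)
  if (is.null(names(seqs))) stop("targets must be named")
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  lens <- nchar(seqs)
  if (readLength > min(lens))
    stop("readLength exceeds the shortest target")
  withSeed(seed, {
    ti <- sample.int(length(seqs), nReads, replace = TRUE, prob = lens)
    off <- floor(runif(nReads) * (lens[ti] - readLength + 1))
    strand <- ifelse(runif(nReads) < 0.5, "+", "-")
    win <- substring(seqs[ti], off + 1, off + readLength)
    minus <- strand == "-"
    win[minus] <- revcomp_cpp(win[minus])
    nerr <- rbinom(nReads, readLength, errorRate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nerr > 0)) {
      p <- sample.int(readLength, nerr[i])
      ch <- strsplit(win[i], "", fixed = TRUE)[[1]]
      for (j in p) ch[j] <- sample(setdiff(bases, ch[j]), 1)
      win[i] <- paste(ch, collapse = "")
    }
    ids <- sprintf("read%06d", seq_len(nReads))
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(win, ids)),
      Biostrings::PhredQuality(strrep("I", rep(readLength, nReads))))
    truth <- data.frame(read = ids, target = names(seqs)[ti],
                        offset = as.integer(off), strand = strand,
                        nErrors = nerr, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Write a simulated fixture to disk
#'
#' Convenience for the CLI and for external-aligner experiments: writes
#' \code{genome.fa}, \code{contigs.fa}, \code{graph.tsv}, \code{reads.fq}
#' and \code{truth.tsv} under \code{outdir}.
#'
#' @param outdir output directory.
#' @param genomeLength,nContigs,overlap,keepEdges,nReads,readLength,errorRate,seed
#'   simulation parameters (see \code{\link{genGenome}},
#'   \code{\link{fragmentGenome}}, \code{\link{simulateReads}}).
#' @return Invisibly, a named list of the written paths.
#' @export
writeSimFixture <- function(outdir, genomeLength = 1e5, nContigs = 8,
                            overlap = 50, keepEdges = 1, nReads = 1e4,
                            readLength = 100, errorRate = 0.01, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- genGenome(genomeLength, seed)
  fr <- fragmentGenome(genome, nContigs, overlap, seed + 1L, keepEdges)
  sim <- simulateReads(fr$targets, nReads, readLength, errorRate, seed + 2L)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                contigs = file.path(outdir, "contigs.fa"),
                graph = file.path(outdir, "graph.tsv"),
                reads = file.path(outdir, "reads.fq"),
                truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(genome = genome)), paths$genome)
  Biostrings::writeXStringSet(fr$targets, paths$contigs)
  ed <- graphEdges(fr$graph)
  writeLines(c("# target adjacency edges",
               if (nrow(ed)) paste(ed[, 1], ed[, 2], sep = "\t")),
             paths$graph)
  writeReadsFastq(sim$reads, paths$reads)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
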