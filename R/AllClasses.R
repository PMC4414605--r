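#' BloomFilter class
#'
#' An m-bit Bloom filter with k seeded hash functions, used to summarise the
#' canonical b-mer content of one partition of target sequences.  Membership
#' queries have no false negatives; the false-positive rate is governed by
#' the bits-per-element ratio r = m/n and k (see \code{\link{bloomFPR}}).
#'
#' @slot bits raw vector holding the m-bit array (packed 8 bits per byte).
#' @slot m numeric; number of bits in the array.
#' @slot k integer; number of hash functions.
#' @slot b integer; b-mer length the filter was built for (NA if generic).
#' @slot seed integer; base seed of the hash family.
#' @slot nInserted numeric; number of insert events so far.
#'
#' @seealso \code{\link{buildFilter}}, \code{\link{bfInsert}},
#'   \code{\link{bfContains}}
#' @name BloomFilter-class
#' @aliases BloomFilter-class
#' @exportClass BloomFilter
setClass("BloomFilter",
  representation(bits = "raw", m = "numeric", k = "integer", b = "integer",
                 seed = "integer", nInserted = "numeric"))

setValidity("BloomFilter", function(object) {
  msg <- NULL
  if (length(object@m) != 1L || object@m < 1)
    msg <- c(msg, "m must be a single value >= 1")
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@bits) != ceiling(object@m / 8))
    msg <- c(msg, "bit array length inconsistent with m")
  if (object@nInserted < 0)
    msg <- c(msg, "nInserted must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an empty BloomFilter
#'
#' @param m number of bits in the array.
#' @param k number of hash functions.
#' @param b b-mer length the filter is intended for (informational; enforced
#'   by the dispatch stage, which requires all filters to share one b).
#' @param seed base seed for the hash family.
#' @return A \code{BloomFilter} with all bits zero.
#' @examples
#' f <- BloomFilter(m = 64, k = 3, b = 4L)
#' bfContains(f, "ACGT")   # FALSE: fresh filter
#' @export
BloomFilter <- function(m, k, b = NA_integer_, seed = 1L) {
  new("BloomFilter", bits = raw(ceiling(m / 8)), m = as.numeric(m),
      k = as.integer(k), b = as.integer(b), seed = as.integer(seed),
      nInserted = 0)
}

#' @describeIn BloomFilter-class number of bits m
#' @param x,object a \code{BloomFilter}.
#' @export
bfSize <- function(x) x@m

#' @describeIn BloomFilter-class number of hash functions k
#' @export
bfHashCount <- function(x) x@k

#' @describeIn BloomFilter-class b-mer length the filter was built for
#' @export
bmerLength <- function(x) x@b

#' @describeIn BloomFilter-class number of insert events
#' @export
bfInsertedCount <- function(x) x@nInserted

#' @describeIn BloomFilter-class fraction of bits set
#' @export
bfOccupancy <- function(x) popcount_raw_cpp(x@bits, x@m) / x@m

setMethod("show", "BloomFilter", function(object) {
  cat("BloomFilter: m =", format(object@m, big.mark = ","),
      "bits, k =", object@k, "\n")
  cat("  b-mer length:", object@b, " seed:", object@seed, "\n")
  cat("  inserted:", object@nInserted,
      sprintf(" occupancy: %.3f\n", bfOccupancy(object)))
})

#' PartitionPlan class
#'
#' Assignment of every target sequence to exactly one of P partitions,
#' together with the per-partition load (total bases).  Partition indices
#' are 1-based.
#'
#' @slot P integer; number of partitions.
#' @slot assignment named integer; partition index (1..P) per target ID.
#' @slot loads numeric of length P; total bases assigned to each partition.
#'
#' @seealso \code{\link{planPartitions}}, \code{\link{bestFitDecreasing}}
#' @name PartitionPlan-class
#' @aliases PartitionPlan-class
#' @exportClass PartitionPlan
setClass("PartitionPlan",
  representation(P = "integer", assignment = "integer", loads = "numeric"))

setValidity("PartitionPlan", function(object) {
  msg <- NULL
  if (length(object@P) != 1L || object@P < 1L)
    msg <- c(msg, "P must be a single integer >= 1")
  if (length(object@assignment) > 0 &&
      (is.null(names(object@assignment)) || anyNA(names(object@assignment))))
    msg <- c(msg, "assignment must be named by target ID")
  if (anyDuplicated(names(object@assignment)))
    msg <- c(msg, "target IDs must be unique")
  if (length(object@assignment) > 0 &&
      (min(object@assignment) < 1L || max(object@assignment) > object@P))
    msg <- c(msg, "partition indices must lie in 1..P")
  if (length(object@loads) != object@P)
    msg <- c(msg, "loads must have length P")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PartitionPlan-class number of partitions
#' @param x,object a \code{PartitionPlan}.
#' @export
partitionCount <- function(x) x@P

#' @describeIn PartitionPlan-class named integer vector of assignments
#' @export
partitionAssignment <- function(x) x@assignment

#' @describeIn PartitionPlan-class per-partition total bases
#' @export
partitionLoads <- function(x) x@loads

#' @describeIn PartitionPlan-class largest partition load (balance objective)
#' @export
planMakespan <- function(x) if (length(x@loads)) max(x@loads) else 0

setMethod("show", "PartitionPlan", function(object) {
  cat("PartitionPlan:", length(object@assignment), "targets over",
      object@P, "partitions\n")
  cat("  loads:", paste(format(object@loads, big.mark = ","),
                        collapse = ", "), "\n")
})

#' AdjacencyGraph class
#'
#' Undirected graph over target IDs, typically the contig-overlap relation
#' reported by an assembler.  Edges force their endpoints into the same
#' partition.  Self-loops are tolerated and ignored.
#'
#' @slot nodes character; target IDs.
#' @slot edges two-column character matrix of unordered ID pairs.
#'
#' @seealso \code{\link{connectedComponents}}, \code{\link{readAdjacencyGraph}}
#' @name AdjacencyGraph-class
#' @aliases AdjacencyGraph-class
#' @exportClass AdjacencyGraph
setClass("AdjacencyGraph",
  representation(nodes = "character", edges = "matrix"))

setValidity("AdjacencyGraph", function(object) {
  msg <- NULL
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node IDs must be unique")
  if (nrow(object@edges) > 0) {
    if (ncol(object@edges) != 2L)
      msg <- c(msg, "edges must have two columns")
    unknown <- setdiff(as.vector(object@edges), object@nodes)
    if (length(unknown))
      msg <- c(msg, paste0("edge endpoint(s) not in node set: ",
                           paste(head(unknown, 5), collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an AdjacencyGraph
#'
#' @param nodes character vector of target IDs.
#' @param edges two-column character matrix (or data.frame) of ID pairs; may
#'   have zero rows.
#' @return An \code{AdjacencyGraph}.
#' @examples
#' g <- AdjacencyGraph(c("a", "b", "c"), cbind("a", "b"))
#' connectedComponents(g)
#' @export
AdjacencyGraph <- function(nodes, edges = matrix(character(), ncol = 2)) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (length(edges) == 0) edges <- matrix(character(), ncol = 2)
  new("AdjacencyGraph", nodes = as.character(nodes), edges = edges)
}

#' @describeIn AdjacencyGraph-class node IDs
#' @param x,object an \code{AdjacencyGraph}.
#' @export
graphNodes <- function(x) x@nodes

#' @describeIn AdjacencyGraph-class edge matrix
#' @export
graphEdges <- function(x) x@edges

setMethod("show", "AdjacencyGraph", function(object) {
  cat("AdjacencyGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

#' DispatchTable class
#'
#' Per-read destination sets produced by the dispatch stage.  A read with an
#' empty destination set was discarded (no partition filter hit any of its
#' b-mers).
#'
#' @slot readIds character; read IDs in input order.
#' @slot destinations list of sorted integer vectors of 1-based partition
#'   indices, parallel to \code{readIds}.
#' @slot b integer; b-mer length used.
#'
#' @seealso \code{\link{dispatchReads}}, \code{\link{dispatchAll}}
#' @name DispatchTable-class
#' @aliases DispatchTable-class
#' @exportClass DispatchTable
setClass("DispatchTable",
  representation(readIds = "character", destinations = "list", b = "integer"))

setValidity("DispatchTable", function(object) {
  msg <- NULL
  if (length(object@readIds) != length(object@destinations))
    msg <- c(msg, "readIds and destinations must be parallel")
  if (anyDuplicated(object@readIds))
    msg <- c(msg, "read IDs must be unique")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn DispatchTable-class named list of destination sets
#' @param x,object a \code{DispatchTable}.
#' @export
dispatchDestinations <- function(x) setNames(x@destinations, x@readIds)

#' @describeIn DispatchTable-class IDs of discarded reads (empty destinations)
#' @export
discardedReads <- function(x) x@readIds[lengths(x@destinations) == 0L]

#' @describeIn DispatchTable-class reads dispatched to each partition index
#' @param P number of partitions (defaults to the largest index seen).
#' @export
dispatchCounts <- function(x, P = NULL) {
  idx <- unlist(x@destinations, use.names = FALSE)
  if (is.null(P)) P <- if (length(idx)) max(idx) else 0L
  tabulate(idx, nbins = P)
}

setMethod("show", "DispatchTable", function(object) {
  nd <- sum(lengths(object@destinations) == 0L)
  cat("DispatchTable:", length(object@readIds), "reads, b =", object@b, "\n")
  cat("  discarded:", nd, " multiply dispatched:",
      sum(lengths(object@destinations) > 1L), "\n")
})

#' SeedIndex class
#'
#' Seed index of a target set for the built-in exact mapper: conceptually a
#' map from canonical l-mer to its occurrences (target, offset, strand).
#' The table is materialised on demand by \code{\link{seedIndexEntries}};
#' \code{\link{exactMap}} uses an equivalent internal representation.
#'
#' @slot targets DNAStringSet of the indexed targets.
#' @slot seedLength integer; l, the seed / minimum exact-match length.
#'
#' @seealso \code{\link{buildSeedIndex}}, \code{\link{exactMap}}
#' @name SeedIndex-class
#' @aliases SeedIndex-class
#' @exportClass SeedIndex
setClass("SeedIndex",
  representation(targets = "ANY", seedLength = "integer"))

setValidity("SeedIndex", function(object) {
  if (length(object@seedLength) != 1L || object@seedLength < 1L)
    "seedLength must be a single integer >= 1" else TRUE
})

#' @describeIn SeedIndex-class seed length l
#' @param x,object a \code{SeedIndex}.
#' @export
seedLength <- function(x) x@seedLength

#' @describeIn SeedIndex-class the indexed targets
#' @export
indexTargets <- function(x) x@targets

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex: l =", object@seedLength, "over",
      length(object@targets), "targets (",
      sum(Biostrings::width(object@targets)), "bases )\n")
})
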