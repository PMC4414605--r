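#' Best-fit-decreasing multiway partitioning
#'
#' Greedy load balancing of weighted items over P partitions: items are
#' sorted by decreasing weight (ties broken by ID, ascending) and each is
#' assigned to the currently least-loaded partition (ties broken by lowest
#' partition index).  With a fixed number of bins and no capacity limit this
#' is the classic LPT/best-fit-decreasing heuristic for multiway number
#' partitioning, with makespan at most 4/3 of the optimum.
#'
#' @param weights named numeric vector of positive item weights (names are
#'   item IDs, must be unique).
#' @param P number of partitions, >= 1.
#' @return A \code{\link{PartitionPlan-class}} object.
#' @examples
#' p <- bestFitDecreasing(c(a = 9, b = 7, c = 6, d = 5, e = 4, f = 3), P = 3)
#' partitionLoads(p)   # 12, 11, 11
#' @export
bestFitDecreasing <- function(weights, P) {
  P <- as.integer(P)
  if (is.na(P) || P < 1L) stop("P must be an integer >= 1")
  ids <- names(weights)
  if (length(weights) > 0) {
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      stop("weights must be named by item ID")
    if (anyDuplicated(ids)) stop("item IDs must be unique")
    if (any(weights < 1)) stop("all weights must be >= 1")
  }
  loads <- numeric(P)
  assignment <- integer(length(weights))
  ord <- order(-weights, ids)
  for (i in ord) {
    p <- which.min(loads)           # lowest index wins ties
    assignment[i] <- p
    loads[p] <- loads[p] + weights[i]
  }
  names(assignment) <- ids
  new("PartitionPlan", P = P, assignment = assignment, loads = loads)
}

#' Connected components of an adjacency graph
#'
#' Maximal connected node sets of the undirected target-adjacency graph.
#' Members of each component are sorted, and components are ordered by
#' their smallest member ID, so the output is deterministic.
#'
#' @param g an \code{\link{AdjacencyGraph-class}} object.
#' @return List of character vectors, one per component.
#' @examples
#' g <- AdjacencyGraph(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
#' connectedComponents(g)  # list(c("a","b"), c("c","d"))
#' @export
connectedComponents <- function(g) {
  stopifnot(methods::is(g, "AdjacencyGraph"))
  validObject(g)
  if (length(g@nodes) == 0L) return(list())
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(g@edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = g@nodes)
  memb <- igraph::components(ig)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

#' Plan balanced target partitions
#'
#' Assigns every target to one of P partitions by best-fit-decreasing over
#' atomic items.  Without a graph the items are the individual targets,
#' weighted by length.  With a graph the items are the connected components
#' (targets absent from the graph are singleton components), weighted by
#' summed member length, so graph-linked targets are never separated.
#' Components are never split, even when one exceeds the ideal load.
#'
#' @param targets a named DNAStringSet (or named character vector) of target
#'   sequences.
#' @param P number of partitions.
#' @param graph optional \code{\link{AdjacencyGraph-class}}; its nodes must
#'   all be target IDs (unknown nodes are an error, to fail loudly on
#'   inconsistent inputs).
#' @return A \code{\link{PartitionPlan-class}}; all members of a graph
#'   component share one partition index.
#' @examples
#' tg <- Biostrings::DNAStringSet(c(a = strrep("A", 50), b = strrep("C", 50),
#'                                  c = strrep("G", 60)))
#' g <- AdjacencyGraph(c("a", "b"), cbind("a", "b"))
#' p <- planPartitions(tg, P = 2, graph = g)
#' partitionAssignment(p)[["a"]] == partitionAssignment(p)[["b"]]  # TRUE
#' @export
planPartitions <- function(targets, P, graph = NULL) {
  seqs <- asSeqChar(targets)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("targets must have unique names")
  lens <- setNames(nchar(seqs), ids)
  if (is.null(graph)) {
    items <- as.list(ids)
  } else {
    stopifnot(methods::is(graph, "AdjacencyGraph"))
    unknown <- setdiff(graph@nodes, ids)
    if (length(unknown))
      stop("graph nodes absent from targets: ",
           paste(head(unknown, 5), collapse = ", "))
    comps <- connectedComponents(graph)
    singletons <- as.list(setdiff(ids, graph@nodes))
    items <- c(comps, singletons)
    items <- items[order(vapply(items, `[`, character(1), 1L))]
  }
  wts <- vapply(items, function(m) sum(lens[m]), numeric(1))
  names(wts) <- vapply(items, `[`, character(1), 1L)  # item ID = smallest member
  if (P > length(items) && length(items) > 0)
    warning("P (", P, ") exceeds the number of atomic items (", length(items),
            "); some partitions will be empty")
  itemPlan <- bestFitDecreasing(wts, P)
  assignment <- integer(length(ids))
  names(assignment) <- ids
  for (i in seq_along(items))
    assignment[items[[i]]] <- itemPlan@assignment[[names(wts)[i]]]
  loads <- vapply(seq_len(itemPlan@P), function(p)
    sum(lens[assignment == p]), numeric(1))
  new("PartitionPlan", P = itemPlan@P, assignment = assignment, loads = loads)
}

#' Read a target adjacency graph from a TSV edge list
#'
#' Two tab-separated columns of target IDs per line; blank lines and lines
#' starting with '#' are ignored.  The node set is the union of endpoints
#' plus, when supplied, all target IDs (so targets without edges become
#' singleton components downstream).
#'
#' @param path edge-list file.
#' @param targetIds optional character vector of all target IDs to include
#'   as nodes.
#' @return An \code{\link{AdjacencyGraph-class}}.
#' @export
readAdjacencyGraph <- function(path, targetIds = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      stop("malformed graph line ", bad[1], " in ", path)
    edges <- t(vapply(parts, function(x) x[1:2], character(2)))
  } else {
    edges <- matrix(character(), ncol = 2)
  }
  nodes <- union(as.vector(edges), targetIds)
  AdjacencyGraph(nodes, edges)
}

#' Write per-partition FASTA files and the partition manifest
#'
#' Partition p's FASTA (\code{part_<p>.fa}) contains exactly its assigned
#' targets, in original input order; \code{partitions.tsv} (columns target,
#' partition, length) round-trips the plan via
#' \code{\link{readPartitionManifest}}.
#'
#' @param targets named DNAStringSet of all targets.
#' @param plan a \code{\link{PartitionPlan-class}} covering all targets.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the FASTA paths and the manifest path.
#' @export
writePartitionFastas <- function(targets, plan, outdir) {
  if (!methods::is(targets, "XStringSet"))
    targets <- Biostrings::DNAStringSet(asSeqChar(targets))
  ids <- names(targets)
  if (!setequal(ids, names(plan@assignment)))
    stop("plan does not cover exactly the supplied targets")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fastas <- character(plan@P)
  for (p in seq_len(plan@P)) {
    keep <- ids[plan@assignment[ids] == p]   # input order preserved
    fastas[p] <- file.path(outdir, sprintf("part_%d.fa", p))
    Biostrings::writeXStringSet(targets[keep], fastas[p])
  }
  manifest <- file.path(outdir, "partitions.tsv")
  df <- data.frame(target = ids,
                   partition = unname(plan@assignment[ids]),
                   length = Biostrings::width(targets),
                   stringsAsFactors = FALSE)
  write.table(df, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fastas = fastas, manifest = manifest))
}

#' Reload a PartitionPlan from a manifest TSV
#'
#' @param path \code{partitions.tsv} as written by
#'   \code{\link{writePartitionFastas}}.
#' @return The reconstructed \code{\link{PartitionPlan-class}}.
#' @export
readPartitionManifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target", "partition", "length") %in% names(df)))
  P <- max(df$partition)
  loads <- vapply(seq_len(P), function(p)
    sum(df$length[df$partition == p]), numeric(1))
  new("PartitionPlan", P = as.integer(P),
      assignment = setNames(as.integer(df$partition), df$target),
      loads = loads)
}
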