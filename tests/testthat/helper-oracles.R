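# Independent oracles used across the suite: deliberately brute-force and
# kept free of the code paths they check.

rcChar <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x) {
    ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
    paste(unname(comp[ch]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Longest exact common substring between `read` (either strand) and any of
# `targets`, by the classic O(n*m) suffix-match DP.
bruteLongestMatch <- function(read, targets) {
  best <- 0L
  for (q in c(read, rcChar(read))) {
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    for (t in targets) {
      tc <- strsplit(t, "", fixed = TRUE)[[1]]
      prev <- integer(length(tc))
      for (i in seq_along(qc)) {
        cur <- integer(length(tc))
        hit <- which(tc == qc[i])
        cur[hit] <- c(0L, prev)[hit] + 1L
        best <- max(best, cur)
        prev <- cur
      }
    }
  }
  best
}

# Partitions holding a true exact match of length >= b to either strand.
bruteTrueDispatch <- function(read, partSeqs, b) {
  which(vapply(partSeqs, function(tg)
    bruteLongestMatch(read, tg) >= b, logical(1)))
}

# Exhaustive optimal makespan over all P^n assignments (n small).
exhaustiveMakespan <- function(weights, P) {
  n <- length(weights)
  total <- P^n
  stopifnot(total <= 3e6)
  idx <- 0:(total - 1)
  makespan <- rep(0, total)
  loads <- matrix(0, nrow = total, ncol = P)
  for (j in seq_len(n)) {
    digit <- (idx %/% P^(j - 1)) %% P
    for (p in 0:(P - 1))
      loads[, p + 1] <- loads[, p + 1] + weights[j] * (digit == p)
  }
  min(apply(loads, 1, max))
}

# Connected components by iterated label propagation (no graph library).
bruteComponents <- function(nodes, edges) {
  lab <- setNames(nodes, nodes)
  repeat {
    changed <- FALSE
    if (nrow(edges)) for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) { lab[a] <- m; lab[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  comps <- lapply(unname(split(names(lab), lab)), sort)
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# Comparison key for alignment-record equivalence: identity of the mapped
# locus and quality, ignoring bookkeeping columns.
alnKey <- function(rec) {
  k <- rec[, c("qname", "flag", "rname", "pos", "mapq", "AS")]
  k[order(k$qname), ]
}

# Small reusable synthetic instance (static targets, error-free reads).
makeTinyInstance <- function(seed = 7, nContigs = 4, genomeLen = 8000,
                             nReads = 120, readLen = 60, errorRate = 0,
                             overlap = 0, keepEdges = 0) {
  genome <- genGenome(genomeLen, seed)
  fr <- fragmentGenome(genome, nContigs, overlap = overlap, seed = seed + 1,
                       keepEdges = keepEdges)
  sim <- simulateReads(fr$targets, nReads, readLen, errorRate, seed = seed + 2)
  c(fr, sim)
}
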