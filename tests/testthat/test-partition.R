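test_that("best-fit-decreasing follows the greedy rule and its tie-breaks", {
  # single bin
  p1 <- bestFitDecreasing(c(c1 = 100), P = 1)
  expect_identical(unname(partitionAssignment(p1)), 1L)
  expect_identical(partitionLoads(p1), 100)

  # P equal items over P partitions: one each, equal loads
  p2 <- bestFitDecreasing(setNames(rep(10, 4), letters[1:4]), P = 4)
  expect_identical(sort(unname(partitionAssignment(p2))), 1:4)
  expect_true(all(partitionLoads(p2) == 10))

  # hand-simulated greedy: 9|3, 7|4, 6|5
  p3 <- bestFitDecreasing(c(a = 9, b = 7, c = 6, d = 5, e = 4, f = 3), P = 3)
  expect_identical(sort(partitionLoads(p3), decreasing = TRUE), c(12, 11, 11))
  a <- partitionAssignment(p3)
  expect_identical(a[["a"]], a[["f"]])
  expect_identical(a[["b"]], a[["e"]])
  expect_identical(a[["c"]], a[["d"]])
  # cross-check makespan against exhaustive search
  expect_identical(max(partitionLoads(p3)),
                   exhaustiveMakespan(c(9, 7, 6, 5, 4, 3), 3))

  # weight ties resolve by ID, load ties by lowest partition index
  pt <- bestFitDecreasing(c(z = 5, a = 5), P = 2)
  expect_identical(unname(partitionAssignment(pt)[c("a", "z")]), c(1L, 2L))
})

test_that("best-fit-decreasing rejects invalid input and handles empties", {
  expect_error(bestFitDecreasing(c(a = 1), P = 0), "P must be")
  expect_error(bestFitDecreasing(c(a = 0.5), P = 1), "weights")
  expect_error(bestFitDecreasing(c(a = 1, a = 2), P = 1), "unique")
  p <- bestFitDecreasing(setNames(numeric(0), character(0)), P = 3)
  expect_identical(partitionLoads(p), c(0, 0, 0))
})

test_that("greedy makespan stays within 4/3 of the exhaustive optimum", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    P <- sample(2:4, 1)
    w <- setNames(sample(1:50, n, replace = TRUE), sprintf("i%02d", 1:n))
    got <- max(partitionLoads(bestFitDecreasing(w, P)))
    opt <- exhaustiveMakespan(unname(w), P)
    expect_lte(got, 4 / 3 * opt)
    expect_gte(got, opt)
  }
})

test_that("connected components are maximal, deterministic and validated", {
  g0 <- AdjacencyGraph(c("a", "b", "c"))
  expect_identical(connectedComponents(g0), list("a", "b", "c"))

  g1 <- AdjacencyGraph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_identical(connectedComponents(g1), list(c("a", "b", "c")))

  g2 <- AdjacencyGraph(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  expect_identical(connectedComponents(g2), list(c("a", "b"), c("c", "d")))

  expect_error(AdjacencyGraph(c("a"), rbind(c("a", "zz"))), "not in node set")

  # random graphs agree with a label-propagation oracle
  set.seed(202)
  for (rep in 1:25) {
    nodes <- sprintf("n%02d", 1:sample(4:12, 1))
    ne <- sample(0:10, 1)
    edges <- if (ne) t(replicate(ne, sample(nodes, 2))) else
      matrix(character(), ncol = 2)
    g <- AdjacencyGraph(nodes, edges)
    expect_identical(connectedComponents(g), bruteComponents(nodes, edges))
  }
})

test_that("planPartitions keeps graph components atomic and balances loads", {
  # no graph: identical to best-fit-decreasing on the individual targets
  tg <- setNames(strrep("A", c(40, 30, 20, 10)), c("a", "b", "c", "d"))
  direct <- bestFitDecreasing(setNames(nchar(tg), names(tg)), 2)
  viaPlan <- planPartitions(tg, 2)
  expect_identical(partitionAssignment(viaPlan), partitionAssignment(direct))

  # components weighted by summed length; members co-partitioned
  tg2 <- setNames(strrep("C", c(50, 50, 60)), c("a", "b", "c"))
  g <- AdjacencyGraph(c("a", "b"), cbind("a", "b"))
  p <- planPartitions(tg2, 2, graph = g)
  a <- partitionAssignment(p)
  expect_identical(a[["a"]], a[["b"]])
  expect_setequal(partitionLoads(p), c(100, 60))

  # every edge co-partitioned on random graph-constrained instances
  set.seed(303)
  for (rep in 1:20) {
    ids <- sprintf("t%02d", 1:12)
    tgr <- setNames(strrep("G", sample(5:80, 12, replace = TRUE)), ids)
    ne <- sample(1:8, 1)
    edges <- t(replicate(ne, sample(ids, 2)))
    gr <- AdjacencyGraph(ids, edges)
    ar <- partitionAssignment(planPartitions(tgr, sample(2:4, 1), graph = gr))
    expect_true(all(ar[edges[, 1]] == ar[edges[, 2]]))
    # conservation
    expect_equal(sum(partitionLoads(planPartitions(tgr, 3, graph = gr))),
                 sum(nchar(tgr)))
  }

  expect_warning(planPartitions(tg2, 5, graph = g), "empty")
  expect_error(planPartitions(tg2, 2, graph = AdjacencyGraph(c("a", "zz"))),
               "absent from targets")
})

test_that("partition FASTAs and the manifest conserve and round-trip the plan", {
  inst <- makeTinyInstance(seed = 11, nContigs = 5)
  plan <- planPartitions(inst$targets, 3)
  outdir <- withr::local_tempdir()
  files <- writePartitionFastas(inst$targets, plan, outdir)

  parts <- lapply(files$fastas, readFastaSeqs)
  combined <- do.call(c, parts)
  combined <- combined[names(inst$targets)]   # re-sort to input order
  expect_identical(as.character(combined), as.character(inst$targets))
  expect_identical(sum(lengths(lapply(parts, names))), length(inst$targets))

  plan2 <- readPartitionManifest(files$manifest)
  expect_identical(partitionAssignment(plan2), partitionAssignment(plan))
  expect_identical(partitionLoads(plan2), partitionLoads(plan))

  # P = 1 reproduces the input records
  plan1 <- planPartitions(inst$targets, 1)
  d1 <- withr::local_tempdir()
  f1 <- writePartitionFastas(inst$targets, plan1, d1)
  expect_identical(as.character(readFastaSeqs(f1$fastas[1])),
                   as.character(inst$targets))
})

test_that("planning is deterministic across runs", {
  inst <- makeTinyInstance(seed = 21, nContigs = 6, overlap = 30,
                           keepEdges = 0.5)
  p1 <- planPartitions(inst$targets, 3, graph = inst$graph)
  p2 <- planPartitions(inst$targets, 3, graph = inst$graph)
  expect_identical(partitionAssignment(p1), partitionAssignment(p2))
})
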