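mkRec <- function(qname, rname, pos, mapq, flag = 0L, cigar = "10M",
                  seq = strrep("A", 10), AS = NA_integer_) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = strrep("I", 10),
             AS = AS, stringsAsFactors = FALSE)
}

test_that("mergeHeaders enforces disjoint @SQ sets covering the manifest", {
  manifest <- data.frame(target = c("c1", "c2", "c3"),
                         partition = c(1L, 2L, 1L),
                         length = c(100L, 80L, 60L), stringsAsFactors = FALSE)
  h1 <- list(sq = data.frame(rname = c("c1", "c3"), length = c(100L, 60L),
                             stringsAsFactors = FALSE), pg = character(0))
  h2 <- list(sq = data.frame(rname = "c2", length = 80L,
                             stringsAsFactors = FALSE), pg = character(0))
  merged <- mergeHeaders(list(h1, h2), manifest)
  expect_identical(merged$sq$rname, c("c1", "c2", "c3"))  # manifest order
  expect_identical(merged$sq$length, manifest$length)

  # P = 1: header equals the single partition's @SQ
  m1 <- mergeHeaders(list(list(sq = merged$sq, pg = character(0))), manifest)
  expect_identical(m1$sq, merged$sq)

  dup <- list(sq = data.frame(rname = "c1", length = 100L,
                              stringsAsFactors = FALSE), pg = character(0))
  expect_error(mergeHeaders(list(h1, dup), manifest), "more than one partition")
  expect_error(mergeHeaders(list(h1), manifest), "does not match the manifest")
})

test_that("mergeBest picks the highest-quality record and accounts every read", {
  s1 <- rbind(mkRec("r1", "c1", 5, 30L, AS = 50L),
              mkRec("r3", "c1", 9, 60L))
  s2 <- rbind(mkRec("r1", "c2", 7, 10L, AS = 80L),
              mkRec("r2", "c2", 2, 60L))
  out <- mergeBest(list(s1, s2), discarded = "r9",
                   readIds = c("r1", "r2", "r3", "r9"))
  expect_identical(out$qname, c("r1", "r2", "r3", "r9"))
  expect_identical(out$rname[1], "c1")      # mapq 30 beats mapq 10
  expect_identical(out$rname[2], "c2")      # mapped in one stream only
  expect_identical(out$flag[4], 4L)         # discarded read emitted unmapped
  expect_identical(out$rname[4], "*")

  # AS breaks MAPQ ties; partition index breaks full ties
  t1 <- mkRec("q", "c1", 5, 60L, AS = 40L)
  t2 <- mkRec("q", "c2", 9, 60L, AS = 55L)
  expect_identical(mergeBest(list(t1, t2))$rname, "c2")
  u1 <- mkRec("q", "c1", 5, 60L)
  u2 <- mkRec("q", "c2", 9, 60L)
  expect_identical(mergeBest(list(u1, u2))$rname, "c1")

  # accounting error: read in no stream and not discarded
  expect_error(mergeBest(list(s1), readIds = c("r1", "r3", "rX")),
               "neither any stream nor the discarded")
})

test_that("mergeBest is idempotent, deterministic, and can flag cross-partition ties", {
  s <- rbind(mkRec("a", "c1", 3, 60L), mkRec("b", "c1", 8, 0L),
             unmappedRecord("c"))
  lone <- mergeBest(list(s), emitUnmapped = FALSE)
  expect_identical(lone[, names(s)], s[bitwAnd(s$flag, 4L) == 0L, ])

  # permuting stream arrival order leaves the result unchanged
  s1 <- rbind(mkRec("r1", "c1", 5, 30L), mkRec("r2", "c1", 4, 20L))
  s2 <- rbind(mkRec("r2", "c2", 6, 50L), mkRec("r1", "c2", 1, 10L))
  a <- mergeBest(list(s1, s2))
  b <- mergeBest(list(s1[2:1, ], s2[2:1, ]))
  expect_identical(a[, names(a) != "partition"], b[, names(b) != "partition"])

  # equal-quality records in two partitions: optional MAPQ zeroing
  v1 <- mkRec("q", "c1", 5, 60L, AS = 70L)
  v2 <- mkRec("q", "c2", 9, 60L, AS = 70L)
  expect_identical(mergeBest(list(v1, v2))$mapq, 60L)
  expect_identical(mergeBest(list(v1, v2), flagCrossPartitionTies = TRUE)$mapq,
                   0L)
  # a tie within one partition is not a cross-partition tie
  w <- rbind(mkRec("q", "c1", 5, 60L, AS = 70L),
             mkRec("q", "c1", 50, 60L, AS = 70L))
  expect_identical(mergeBest(list(w), flagCrossPartitionTies = TRUE)$mapq, 60L)
})

test_that("mergeMulti emits up to N distinct ranked records", {
  s1 <- rbind(mkRec("r", "c1", 5, 60L, AS = 90L),
              mkRec("r", "c1", 5, 60L, AS = 90L))   # duplicate within stream
  s2 <- rbind(mkRec("r", "c2", 7, 50L, AS = 80L),
              mkRec("r", "c3", 2, 40L, AS = 70L))

  # N = 1 reduces to mergeBest
  m1 <- mergeMulti(list(s1, s2), maxRecords = 1)
  bb <- mergeBest(list(s1, s2))
  expect_identical(m1, bb)

  # top 2 of 3 distinct records; secondary flag on the second
  m2 <- mergeMulti(list(s1, s2), maxRecords = 2)
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$rname, c("c1", "c2"))
  expect_identical(bitwAnd(m2$flag, 256L), c(0L, 256L))

  # duplicates collapse to one even with a large N
  m9 <- mergeMulti(list(s1), maxRecords = 9)
  expect_identical(nrow(m9), 1L)

  expect_error(mergeMulti(list(s1), maxRecords = 0), "maxRecords")
})
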