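test_that("canonical b-mers are strand-symmetric and reject bad input", {
  expect_identical(canonicalBmer("ACGT"), "ACGT")   # RC palindrome
  expect_identical(canonicalBmer("TTTT"), "AAAA")
  expect_true(is.na(canonicalBmer("ACNT")))
  expect_error(canonicalBmer("ACGT", b = 5), "length")

  # involution: canonical(s) == canonical(revcomp(s))
  set.seed(1)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    expect_identical(canonicalBmer(s), canonicalBmer(rcChar(s)))
    expect_true(canonicalBmer(s) <= s)
  }
})

test_that("hash positions are deterministic, in range and near-uniform", {
  p1 <- hashPositions("ACGTACGTAC", k = 5, m = 1e6, seed = 9)
  p2 <- hashPositions("ACGTACGTAC", k = 5, m = 1e6, seed = 9)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  expect_true(all(p1 >= 0 & p1 < 1e6))
  expect_false(identical(p1, hashPositions("ACGTACGTAC", 5, 1e6, seed = 10)))
  expect_identical(hashPositions("X", k = 1, m = 1), 0)

  # chi-square uniformity of single-hash bucket occupancy
  set.seed(2)
  keys <- unique(do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), 5e4 * 12, TRUE), ncol = 12))))
  m <- 2^12
  pos <- vapply(keys, function(k) hashPositions(k, 1, m, seed = 3), numeric(1))
  counts <- tabulate(pos + 1, nbins = m)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("insert/contains give no false negatives and a fresh filter is empty", {
  f <- BloomFilter(m = 512, k = 4, b = 8L, seed = 5L)
  expect_false(any(bfContains(f, c("AAAAAAAA", "ACGTACGT", "ZZZ"))))
  set.seed(4)
  keys <- replicate(40, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                              collapse = ""))
  f <- bfInsert(f, keys)
  expect_true(all(bfContains(f, keys)))          # exhaustive on the set
  expect_equal(bfInsertedCount(f), 40)
  expect_lte(popcountBits <- bfOccupancy(f) * bfSize(f),
             min(bfSize(f), 4 * 40))
})

test_that("the analytic FPR matches its printed special cases", {
  expect_equal(bloomFPR(8, 5), (1 - exp(-5 / 8))^5)
  expect_gt(bloomFPR(8, 5), 0.02)            # "slightly larger than 2%"
  expect_lt(bloomFPR(8, 5), 0.025)
  # monotone decreasing in r at fixed k
  rs <- c(2, 4, 8, 16, 64, 256)
  expect_true(all(diff(bloomFPR(rs, 5)) < 0))
  expect_lt(bloomFPR(1e6, 5), 1e-25)
  # F^(1/r) = 0.6185 at the real-valued optimum k = r ln 2, for any r
  for (r in c(4, 8, 16))
    expect_equal(round(bloomFPR(r, r * log(2))^(1 / r), 4), 0.6185)
  expect_error(bloomFPR(0, 5), "positive")
})

test_that("optimalK floors r*ln2, clamps at 1, and is near the true optimum", {
  expect_identical(optimalK(8), 5L)
  expect_identical(optimalK(1), 1L)
  expect_identical(optimalK(16), 11L)
  for (r in c(2, 5, 8, 12, 16)) {
    ks <- 1:(3 * r)
    kBest <- ks[which.min(bloomFPR(r, ks))]   # integer-scan oracle
    expect_lte(abs(optimalK(r) - kBest), 1)
    expect_lte(bloomFPR(r, optimalK(r)), bloomFPR(r, kBest) * 1.5)
  }
})

test_that("buildFilter inserts every valid canonical b-mer with stride 1", {
  f <- buildFilter(c(t = "ACGTA"), b = 3, r = 8)
  expect_equal(bfInsertedCount(f), 3)          # L - b + 1
  for (bm in c("ACG", "CGT", "GTA"))
    expect_true(bfContains(f, canonicalBmer(bm)))

  # every b-length substring of a target or of its RC is found
  set.seed(6)
  tg <- setNames(paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
                 "t1")
  fb <- buildFilter(tg, b = 12)
  subs <- substring(tg, 1:(300 - 11), 12:300)
  expect_true(all(bfContains(fb, canonicalBmer(subs))))
  expect_true(all(bfContains(fb, canonicalBmer(rcChar(subs)))))
  expect_equal(bfInsertedCount(fb), 289)
  expect_equal(bfSize(fb), 8 * 289)

  # N-containing windows are skipped
  fn <- buildFilter(c(t = "ACGTNACGT"), b = 4)
  expect_equal(bfInsertedCount(fn), 2)         # ACGT twice, N windows skipped

  expect_warning(buildFilter(c(t = "ACG"), b = 10), "empty")
})

test_that("filter files round-trip bits and parameters exactly", {
  f <- buildFilter(c(t = genGenome(500, 31)), b = 15, r = 8, seed = 99L)
  path <- withr::local_tempfile(fileext = ".bf")
  writeBloomFilter(f, path)
  g <- readBloomFilter(path)
  expect_identical(g@bits, f@bits)
  expect_identical(bfSize(g), bfSize(f))
  expect_identical(bfHashCount(g), bfHashCount(f))
  expect_identical(bmerLength(g), bmerLength(f))
  expect_identical(g@seed, f@seed)
  expect_identical(bfInsertedCount(g), bfInsertedCount(f))
  expect_error(readBloomFilter(withr::local_tempfile(lines = "nope")),
               "not a Bloom filter")
})
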