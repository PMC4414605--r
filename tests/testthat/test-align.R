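test_that("seed index records every l-mer occurrence", {
  e <- seedIndexEntries(buildSeedIndex(c(t = "AAAA"), l = 2))
  expect_identical(e$kmer, rep("AA", 3))       # canonical("TT") is "AA"
  expect_identical(e$offset, 0:2)
  expect_identical(e$strand, rep("+", 3))

  expect_identical(nrow(seedIndexEntries(
    buildSeedIndex(setNames(character(0), character(0)), l = 3))), 0L)

  # every stored occurrence verified by direct substring comparison
  set.seed(61)
  tg <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    character(1)), c("x", "y", "z"))
  ent <- seedIndexEntries(buildSeedIndex(tg, l = 7))
  for (i in seq_len(nrow(ent))) {
    win <- substr(tg[[ent$target[i]]], ent$offset[i] + 1, ent$offset[i] + 7)
    expect_identical(canonicalBmer(win), ent$kmer[i])
    if (ent$strand[i] == "+") expect_identical(win, ent$kmer[i])
    else expect_identical(rcChar(win), ent$kmer[i])
  }
  # completeness: one entry per ACGT-only window
  expect_identical(nrow(ent), 3L * (80L - 6L))
})

test_that("exactMap reports the maximal unique match with SAM semantics", {
  set.seed(62)
  t1 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  idx <- buildSeedIndex(c(t1 = t1), l = 20)

  # exact 100 bp substring at 0-based offset 9
  r <- substr(t1, 10, 109)
  rec <- exactMap(c(q = r), idx)
  expect_identical(rec$rname, "t1")
  expect_identical(rec$pos, 10L)
  expect_identical(rec$cigar, "100M")
  expect_identical(rec$mapq, 60L)
  expect_identical(rec$AS, 100L)

  # reverse-complement read: flag 16, SEQ re-oriented to the forward strand
  rr <- exactMap(c(q = rcChar(r)), idx)
  expect_identical(rr$flag, 16L)
  expect_identical(rr$pos, 10L)
  expect_identical(rr$seq, r)

  # no shared l-mer: unmapped record
  un <- exactMap(c(q = strrep("A", 30)), idx)
  expect_identical(un$flag, 4L)
  expect_identical(un$rname, "*")
  expect_identical(un$pos, 0L)
  expect_identical(un$cigar, "*")

  # soft-clipped flanks around an embedded exact core
  core <- substr(t1, 51, 90)
  read2 <- paste0("TTTTTTTT", core, "GGGGGGG")  # flanks unlikely to extend
  rec2 <- exactMap(c(q = read2), idx)
  expect_identical(rec2$rname, "t1")
  expect_match(rec2$cigar, "^[0-9]+S[0-9]+M[0-9]+S$")
  expect_gte(rec2$AS, 40L)
})

test_that("repeated loci give MAPQ 0 and the documented tie-break", {
  # identical 60 bp cassette planted at two loci
  set.seed(63)
  cassette <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  spacer <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  tg <- c(t1 = paste0(cassette, spacer, cassette))
  idx <- buildSeedIndex(tg, l = 20)
  rec <- exactMap(c(q = cassette), idx)
  expect_identical(rec$mapq, 0L)
  expect_identical(rec$pos, 1L)      # smaller target position wins
  expect_identical(rec$flag, 0L)

  # same cassette on two targets: first target by input order wins
  tg2 <- c(b = paste0(spacer, cassette), a = paste0(cassette, spacer))
  rec2 <- exactMap(c(q = cassette), buildSeedIndex(tg2, l = 20))
  expect_identical(rec2$rname, "b")
  expect_identical(rec2$mapq, 0L)
})

test_that("reported match length equals the brute-force longest common substring", {
  set.seed(64)
  for (rep in 1:15) {
    tg <- setNames(vapply(1:2, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
      character(1)), c("u", "v"))
    idx <- buildSeedIndex(tg, l = 8)
    # a read stitched from target pieces and random bases
    src <- tg[[sample(2, 1)]]
    a <- sample(40, 1)
    piece <- substr(src, a, a + sample(12:40, 1))
    read <- paste0(genGenome(sample(5:15, 1), rep),
                   if (runif(1) < 0.5) piece else rcChar(piece),
                   genGenome(sample(5:15, 1), rep + 100))
    rec <- exactMap(c(q = read), idx)
    expected <- bruteLongestMatch(read, unname(tg))
    if (expected >= 8) expect_identical(rec$AS, expected)
    else expect_identical(rec$flag, 4L)
  }
})

test_that("alignPartition emits a valid SAM with correct header contract", {
  inst <- makeTinyInstance(seed = 65, nContigs = 3, genomeLen = 5000,
                           nReads = 60, readLen = 60)
  out <- withr::local_tempfile(fileext = ".sam")
  res <- alignPartition(inst$targets, inst$reads, l = 20, out = out)
  parsed <- readSam(out, strict = TRUE)   # strict parse is the validity check
  expect_identical(parsed$header$sq$rname, names(inst$targets))
  expect_identical(parsed$header$sq$length,
                   unname(vapply(as.character(inst$targets), nchar, 1L)))
  expect_identical(nrow(parsed$records), 60L)

  # error-free unique-locus reads map at the simulated coordinates
  rec <- parsed$records
  tr <- inst$truth
  m <- match(tr$read, rec$qname)
  expect_true(all(rec$mapq[m] == 60L))
  expect_identical(rec$rname[m], tr$target)
  expect_identical(rec$pos[m], tr$offset + 1L)
  expect_identical(bitwAnd(rec$flag[m], 16L) != 0L, tr$strand == "-")

  # zero dispatched reads: header-only SAM
  out0 <- withr::local_tempfile(fileext = ".sam")
  alignPartition(inst$targets, setNames(character(0), character(0)),
                 l = 20, out = out0)
  p0 <- readSam(out0)
  expect_identical(nrow(p0$records), 0L)
  expect_identical(p0$header$sq$rname, names(inst$targets))
})

test_that("external adapters are invoked through quoted templates", {
  fix <- withr::local_tempdir()
  dir.create(file.path(fix, "with space"))
  tfa <- file.path(fix, "with space", "t.fa")
  rfq <- file.path(fix, "with space", "r.fq")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(t1 = "ACGTACGT")), tfa)
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), rfq)

  mockSam <- "@SQ\\tSN:t1\\tLN:8\\nr1\\t0\\tt1\\t1\\t60\\t8M\\t*\\t0\\t0\\tACGTACGT\\tIIIIIIII"
  tmpl <- paste0("ls {target} {reads} >&2 && printf '", mockSam, "\\n'")
  lines <- externalAdapter(tmpl, tfa, rfq)
  expect_identical(length(lines), 2L)
  rec <- alignPartition(tfa, rfq, aligner = "mock",
                        adapters = list(mock = tmpl))
  expect_identical(rec$records$qname, "r1")
  expect_identical(rec$records$pos, 1L)

  expect_error(externalAdapter("exit 1", tfa, rfq), "exit 1")
  expect_error(alignPartition(tfa, rfq, aligner = "nope"), "unknown aligner")
})
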