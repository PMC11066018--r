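test_that("error-free simulated reads are exact design substrings", {
  designs <- qcTestDesigns()
  reads <- simulateReads(designs, nReads = 20, readLen = 200, seed = 5)
  for (i in seq_along(reads)) {
    truth <- strsplit(names(reads)[i], "|", fixed = TRUE)[[1]]
    conc <- strrep(designs[[truth[2]]], 6)
    expect_true(grepl(reads[[i]], conc, fixed = TRUE))
  }
})

test_that("read simulation is deterministic and errors behave as rates", {
  designs <- qcTestDesigns()
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulateReads(designs, nReads = 15, readLen = 150, subRate = 0.01,
                indelRate = 0.002, revcompFraction = 0.3, seed = 9,
                file = f1)
  simulateReads(designs, nReads = 15, readLen = 150, subRate = 0.01,
                indelRate = 0.002, revcompFraction = 0.3, seed = 9,
                file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # substitution rate shows up as mean edit distance ~ rate * length
  reads <- simulateReads(designs, nReads = 40, readLen = 250,
                         subRate = 0.01, seed = 21)
  eds <- vapply(seq_along(reads), function(i) {
    truth <- strsplit(names(reads)[i], "|", fixed = TRUE)[[1]]
    alignReadCircular(reads[[i]], designs[[truth[2]]])@nEdits
  }, integer(1))
  expect_lt(abs(mean(eds) - 0.01 * 250), 0.8)
  expect_error(simulateReads(designs, nReads = 2, readLen = 10000,
                             seed = 1), "readLen|concatemer")
})

test_that("circular alignment recovers edits, phase and orientation", {
  designs <- qcTestDesigns()
  unit <- designs[[1]]
  r3 <- strrep(unit, 3)
  a <- alignReadCircular(r3, unit)
  expect_identical(a@nEdits, 0L)
  expect_identical(a@nPerfectRepeats, 3L)
  expect_identical(a@orientation, "forward")
  expect_identical(a@phaseOffset, 0L)
  # reverse complement: same reference, flipped orientation, same edits
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(r3)))
  arc <- alignReadCircular(rc, unit)
  expect_identical(arc@orientation, "reverse_complement")
  expect_identical(arc@nEdits, 0L)
  # one substitution in the middle copy
  r3s <- r3
  mid <- 100L
  substr(r3s, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r3, mid, mid))[1]
  as1 <- alignReadCircular(r3s, unit)
  expect_identical(as1@nEdits, 1L)
  expect_identical(as1@nPerfectRepeats, 2L)
  expect_error(alignReadCircular("ACGTACGT", unit), "20 nt")
})

test_that("alignment edit distance equals the full DP oracle", {
  designs <- qcTestDesigns()
  set.seed(31)
  for (i in 1:8) {
    unit <- designs[[sample.int(3, 1)]]
    len <- sample(60:160, 1)
    phase <- sample(0:71, 1)
    raw <- substr(strrep(unit, 5), phase + 1, phase + len)
    b <- strsplit(raw, "")[[1]]
    nerr <- sample(0:5, 1)
    for (p in sample(seq_along(b), nerr))
      b[p] <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.3) b <- b[-sample(seq_along(b), 1)]  # one deletion
    read <- paste(b, collapse = "")
    if (runif(1) < 0.5)
      read <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read)))
    got <- alignReadCircular(read, unit)@nEdits
    expect_identical(got, as.integer(oracleCircularEdit(read, unit)),
                     label = paste("case", i))
  }
})

test_that("filters fire exactly on constructed fixtures", {
  designs <- qcTestDesigns()
  unit <- designs[[1]]
  thr <- qcThresholds()
  # clean 3-copy read passes
  clean <- strrep(unit, 3)
  v0 <- classifyRead(alignReadCircular(clean, unit), clean, thr)
  expect_identical(v0$status, "pass")
  # two perfect repeats only
  r2 <- substr(strrep(unit, 3), 1, 144)
  v2 <- classifyRead(alignReadCircular(r2, unit), r2, thr)
  expect_identical(v2$status, "fail")
  expect_true("few_perfect_repeats" %in% v2$reasons)
  # too short
  r1 <- substr(unit, 1, 80)
  v1 <- classifyRead(alignReadCircular(r1, unit), r1, thr)
  expect_true("too_short" %in% v1$reasons)
  # nonsense: in-frame TAA in the first copy of a 4-copy read (phase 0)
  rn <- strrep(unit, 4)
  substr(rn, 10, 12) <- "TAA"
  vn <- classifyRead(alignReadCircular(rn, unit), rn, thr)
  expect_true("nonsense" %in% vn$reasons)
  # large frameshift: 1-nt deletion near the end, frame never restored
  rf <- strrep(unit, 4)
  rf <- paste0(substr(rf, 1, 229), substr(rf, 231, 288))
  vf <- classifyRead(alignReadCircular(rf, unit), rf, thr)
  expect_true("large_frameshift" %in% vf$reasons)
  # poor alignment: heavily corrupted read
  set.seed(4)
  bad <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  vb <- classifyRead(alignReadCircular(bad, unit), bad, thr)
  expect_true("poor_alignment" %in% vb$reasons)
})

test_that("added errors never reduce edits nor add perfect repeats", {
  designs <- qcTestDesigns()
  unit <- designs[[2]]
  set.seed(17)
  for (rep in 1:5) {
    clean <- substr(strrep(unit, 5), 1, 288)
    a0 <- alignReadCircular(clean, unit)
    b <- strsplit(clean, "")[[1]]
    k <- sample(2:8, 1)
    for (p in sample(seq_along(b), k))
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    noisy <- paste(b, collapse = "")
    a1 <- alignReadCircular(noisy, unit)
    expect_gte(a1@nEdits, a0@nEdits)
    expect_lte(a1@nEdits, k)
    expect_lte(a1@nPerfectRepeats, a0@nPerfectRepeats)
  }
})

test_that("library summary counts forward and reverse references", {
  designs <- qcTestDesigns()
  fwd <- simulateReads(designs, nReads = 15, readLen = 216, seed = 2)
  rev1 <- simulateReads(designs[3], nReads = 3, readLen = 216,
                        revcompFraction = 1, seed = 3)
  reads <- c(fwd, rev1)
  alns <- alignReadsToLibrary(reads, designs)
  verdicts <- lapply(seq_along(alns), function(i)
    classifyRead(alns[[i]], reads[[i]]))
  s <- summarizeLibrary(alns, verdicts, unname(reads))
  expect_identical(s$revcompRefs, 1L)
  expect_lte(s$forwardRefs, 3L)
  expect_identical(s$uniquePassing, length(unique(unname(reads))))
  # planted-truth recovery: every pass read maps to its generating design
  truth <- vapply(strsplit(names(reads), "|", fixed = TRUE),
                  function(x) x[2], "")
  orient <- vapply(strsplit(names(reads), "|", fixed = TRUE),
                   function(x) x[4], "")
  for (i in seq_along(alns)) {
    expect_identical(alns[[i]]@reference, truth[i])
    expect_identical(alns[[i]]@orientation, orient[i])
  }
})

test_that("FASTQ written by the simulator reads back verbatim", {
  designs <- qcTestDesigns()
  fq <- tempfile(fileext = ".fastq")
  reads <- simulateReads(designs, nReads = 8, readLen = 120, seed = 13,
                         file = fq)
  back <- readFastq(fq)
  expect_identical(unname(back), unname(reads))
  expect_identical(names(back), names(reads))
})
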