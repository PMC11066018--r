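# Printed tag units used throughout: the three solubility tags and the
# mutant repeat units.
TAG1 <- strrep("GQSGLP", 24)                       # SynIDP-1 tag region
TAG2 <- strrep("GTHGTP", 24)                       # SynIDP-2 tag region
TAG3 <- strrep("GAGAIPGAEAIPGAGAIPGAGAIP", 6)      # SynIDP-3 tag region

test_that("construct assembly obeys length arithmetic and phase identity", {
  con <- assembleConstruct("GQSGLP", 24)
  expect_identical(nchar(con), 164L)                # 5 + 144 + 15
  expect_identical(nchar(assembleConstruct("GQSGLP", 0)), 20L)
  expect_error(assembleConstruct("GQSGLP", -1), ">= 0")
  # leader ends in P: GXXXXP and PGXXXX phases give identical constructs
  a <- assembleConstruct("GQSGLP", 24)
  b <- paste0("MSKG", strrep("PGQSGL", 24), "P", "GENLYFQGHHHHHHG")
  expect_identical(a, b)
  # 20-repeat variant
  expect_identical(nchar(assembleConstruct("GIGQAP", 20)), 140L)
})

test_that("mean hydropathy is a permutation-invariant bounded average", {
  sc <- urryScale()
  expect_identical(meanHydropathy("GGGG"), unname(sc[["G"]]))
  set.seed(8)
  s <- paste(sample(strsplit(TAG1, "")[[1]]), collapse = "")
  expect_identical(meanHydropathy(s), meanHydropathy(TAG1))
  expect_gte(meanHydropathy(TAG2), min(sc))
  expect_lte(meanHydropathy(TAG2), max(sc))
  expect_error(meanHydropathy(""), "empty")
  expect_error(meanHydropathy("GGB"), "not in scale")
  # injectable scale
  flat <- setNames(rep(1, 20), names(sc))
  expect_identical(meanHydropathy(TAG3, flat), 1)
})

test_that("the three printed tags rank above the fusion threshold", {
  thr <- solubilityThresholds()
  for (tag in c(TAG1, TAG2, TAG3)) {
    h <- meanHydropathy(tag)
    expect_identical(classifySolubility(h, "fusion", thr), "soluble")
  }
})

test_that("separation threshold is the smallest separating integer", {
  expect_identical(separationThreshold(c(40, 50),
                                       c("insoluble", "soluble")), 41L)
  expect_true(is.na(separationThreshold(c(50, 40),
                                        c("insoluble", "soluble"))))
  expect_identical(
    separationThreshold(c(41.9, 30, 42.5, 55),
                        c("insoluble", "insoluble", "soluble", "soluble")),
    42L)
  expect_error(separationThreshold(c(1, 2), c("soluble", "soluble")),
               "per class")
  # random separable inputs against an exhaustive integer scan
  set.seed(12)
  for (i in 1:20) {
    t <- sample(20:60, 1)
    ins <- t - runif(5, 0.05, 12)
    sol <- t + runif(5, 0.05, 12)
    got <- separationThreshold(c(ins, sol),
                               rep(c("insoluble", "soluble"), each = 5))
    scan <- Filter(function(k) all(ins < k) && all(sol > k), 1:100)
    expect_identical(got, as.integer(min(scan)))
  }
  # overlapping classes: no separating integer
  expect_true(is.na(separationThreshold(
    c(45, 44), c("insoluble", "soluble"))))
})

test_that("hydropathy classification respects context and boundaries", {
  expect_identical(classifySolubility(43, "standalone"), "soluble")
  expect_identical(classifySolubility(43, "fusion"), "insoluble")
  expect_identical(classifySolubility(42, "standalone"), "indeterminate")
  expect_error(solubilityThresholds(standalone = 50, fusion = 40),
               ">=")
})

test_that("Wilkinson-Harrison canonical variable and probability", {
  # zero turn formers, mean charge exactly 0.03: CV = 0, soluble, 0.8507
  s <- paste0(strrep("A", 97), strrep("K", 3))
  wh <- wilkinsonHarrison(s)
  expect_equal(wh$CV, 0, tolerance = 1e-12)
  expect_identical(wh$class, "soluble")
  expect_equal(wh$probability, 0.4934 + 0.276 * 1.71 - 0.0392 * 1.71^2,
               tolerance = 1e-12)
  expect_equal(round(wh$probability, 4), 0.8507)
  # boundary CV = CV': probability 0.4934 (via the injectable weights)
  s2 <- paste0(strrep("G", 10), strrep("K", 3), strrep("A", 87))
  whB <- wilkinsonHarrison(s2, lambda1 = 17.1)
  expect_equal(whB$discriminant, 0, tolerance = 1e-12)
  expect_equal(whB$probability, 0.4934, tolerance = 1e-12)
  # probability bounded in [0, 1] and CV permutation-invariant
  set.seed(3)
  for (i in 1:10) {
    sq <- paste(sample(AA_STANDARD_TEST, 60, replace = TRUE), collapse = "")
    wh1 <- wilkinsonHarrison(sq)
    expect_gte(wh1$probability, 0)
    expect_lte(wh1$probability, 1)
    perm <- paste(sample(strsplit(sq, "")[[1]]), collapse = "")
    expect_equal(wilkinsonHarrison(perm)$CV, wh1$CV, tolerance = 1e-12)
  }
  # the glycine/proline-rich tags are called insoluble by this model
  # (turn-former fraction near 1), the documented failure the Urry ranking
  # corrects for two of the three tags
  expect_identical(wilkinsonHarrison(TAG1)$class, "insoluble")
  expect_identical(wilkinsonHarrison(TAG3)$class, "insoluble")
})

test_that("composition report counts the relevant residue classes", {
  g <- compositionReport("GGGG")
  expect_identical(g$glycineFraction, 1)
  expect_identical(g$aromaticFraction, 0)
  c1 <- compositionReport(TAG1)
  expect_identical(c1$aromaticFraction, 0)
  expect_identical(c1$positiveFraction, 0)
  expect_identical(c1$netCharge, 0L)
  expect_equal(c1$prolineFraction, 1 / 6)
  # SynIDP-3 unit carries one glutamate per 24-mer: net charge -1 per unit
  u3 <- "GAGAIPGAEAIPGAGAIPGAGAIP"
  expect_identical(compositionReport(u3)$netCharge, -1L)
  expect_identical(compositionReport(TAG3)$netCharge, -6L)
})

test_that("peptide masses are additive and in the expected range", {
  expect_equal(averageMass("G"), 75.07, tolerance = 0.01)
  expect_equal(averageMass("G", monoisotopic = TRUE), 75.032,
               tolerance = 0.001)
  # additivity: mass(s1 + s2) = mass(s1) + mass(s2) - water
  m1 <- averageMass("GQSGLP"); m2 <- averageMass("MSKGP")
  expect_equal(averageMass("GQSGLPMSKGP"), m1 + m2 - 18.01528,
               tolerance = 1e-9)
  # assembled tag constructs sit in the 10-20 kDa window
  for (u in list(c("GQSGLP", 24), c("GTHGTP", 24), c("GIGQAP", 20))) {
    m <- averageMass(assembleConstruct(u[1], as.integer(u[2])))
    expect_gte(m, 10000)
    expect_lte(m, 20000)
  }
  m3 <- averageMass(assembleConstruct("GAGAIPGAEAIPGAGAIPGAGAIP", 24))
  expect_gte(m3, 10000); expect_lte(m3, 20000)
  expect_error(averageMass("GXZ"), "non-standard")
})

test_that("solubility report aggregates all per-sequence metrics", {
  seqs <- c(tag1 = TAG1, tag2 = TAG2)
  rep <- solubilityReport(seqs, context = "fusion")
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$id, c("tag1", "tag2"))
  expect_true(all(c("hydropathy", "class", "whProbability", "massDa")
                  %in% names(rep)))
  expect_true(all(rep$aromaticFraction == 0))
})
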