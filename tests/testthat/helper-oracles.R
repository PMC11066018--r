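# Independent oracles used to cross-check the package implementations.
# These deliberately use naive exhaustive algorithms, not the package code.

# Brute-force motif enumeration: iterate over ALL ordered X1..X4 tuples,
# apply the positional constraints directly, collapse to sorted multisets.
oracleEnumerate <- function(alphabet, requiredResidue = "G",
                            forbiddenAtX4 = "G",
                            junctionSet = NULL) {
  tuples <- expand.grid(rep(list(alphabet), 4), stringsAsFactors = FALSE)
  keep <- apply(tuples, 1, function(x) {
    if (!(requiredResidue %in% x)) return(FALSE)
    if (x[4] %in% forbiddenAtX4) return(FALSE)
    if (!is.null(junctionSet) && !(x[4] %in% junctionSet)) return(FALSE)
    TRUE
  })
  sort(unique(apply(tuples[keep, , drop = FALSE], 1, function(x)
    paste(sort(x), collapse = ""))))
}

# Exhaustive O(n^3) longest-direct-repeat: every substring pair.
oracleDirectRepeat <- function(s) {
  n <- nchar(s)
  if (n == 0) return(0L)
  for (L in (n - 1):1) {
    subs <- substring(s, 1:(n - L + 1), L:n)
    if (anyDuplicated(subs)) return(max(L, 1L))
  }
  1L
}

# Exhaustive longest inverted repeat with disjoint occurrences.
oracleInvertedRepeat <- function(s, minGap = 0L) {
  n <- nchar(s)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  maxL <- (n - minGap) %/% 2L
  for (L in rev(seq_len(maxL))) {
    for (i in 1:(n - L + 1)) {
      a <- substr(s, i, i + L - 1)
      arc <- rc(a)
      for (j in 1:(n - L + 1)) {
        if (j >= i + L + minGap || i >= j + L + minGap) {
          if (substr(s, j, j + L - 1) == arc) return(L)
        }
      }
    }
  }
  0L
}

# Full semi-global edit-distance DP (read end-to-end, subject free at both
# ends), plain quadratic dynamic programming.
oracleSemiGlobalEdit <- function(read, subject) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(subject, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- rep(0L, m + 1L)          # D[0, j] = 0: free subject start
  for (i in 1:n) {
    cur <- integer(m + 1L)
    cur[1] <- i
    for (j in 1:m) {
      cur[j + 1L] <- min(prev[j] + (a[i] != b[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)                        # free subject end
}

# Circular-reference edit distance oracle: both orientations against the
# tiled unit.
oracleCircularEdit <- function(read, unit) {
  tiled <- strrep(unit, ceiling(nchar(read) / nchar(unit)) + 2L)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  min(oracleSemiGlobalEdit(read, tiled), oracleSemiGlobalEdit(rc, tiled))
}

AA_STANDARD_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random DNA string.
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Small deterministic oligo set shared across QC tests (built once per
# test run; three designs over the {A,G,S} alphabet).
qcTestDesigns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib <- enumerateMotifs(MotifSpec(alphabet = c("A", "G", "S")))
      m <- motifTable(lib)[1:3, ]
      cache <<- setNames(vapply(seq_len(nrow(m)), function(i)
        oligoSeq(reverseTranslateScrambled(
          buildRepeatUnit(m$peptide[i], 4L),
          seed = 100L + i, iterations = 150L)), ""),
        m$multisetKey)
    }
    cache
  }
})
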