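# Codon-level engineering of the 72-nt repeat oligonucleotides.
#
# Each oligo encodes one 24-residue repeat unit (PGX1X2X3X4)4 and must carry
# exactly one SexAI recognition site (degenerate pattern ACCWGGT), split
# across the circular junction so that the site only exists after
# circularization. Because the product is highly repetitive, codons are
# scrambled (seeded simulated annealing over synonymous choices) to minimize
# direct and inverted nucleotide repeats, the stated failure modes of the
# downstream polymerase/ligase reactions.

#' E. coli K-12 codon usage table
#'
#' Relative synonymous-codon fractions for E. coli K-12, packaged as the
#' default usage table for the codon scrambler.
#'
#' @return data.frame(codon, aa, fraction).
#' @export
defaultCodonUsage <- function() {
  path <- system.file("extdata", "ecoli_k12_codon_usage.tsv",
                      package = "SynIDPDesign")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Admissible codons per residue after the usage cutoff. Residues whose
# codons all fall below the cutoff keep their single most-used codon.
admissibleCodons <- function(usage, cutoff = 0.10) {
  keep <- split(usage, usage$aa)
  lapply(keep, function(d) {
    d <- d[order(-d$fraction), ]
    ok <- d$codon[d$fraction >= cutoff]
    if (length(ok) == 0L) ok <- d$codon[1L]
    ok
  })
}

# Most frequent A-ending codon per residue (junction position). Exempt from
# the usage cutoff: the junction codon is a hard structural requirement.
junctionCodon <- function(aa, usage) {
  d <- usage[usage$aa == aa & endsWith(usage$codon, "A"), ]
  if (nrow(d) == 0L) return(NA_character_)
  d$codon[which.max(d$fraction)]
}

#' Longest direct and inverted nucleotide repeats of a sequence
#'
#' `longestDirectRepeat` is the length of the longest substring occurring at
#' two or more distinct positions (overlaps allowed); by convention a
#' nonempty sequence scores at least 1. `longestInvertedRepeat` is the
#' longest s such that s and its reverse complement occur at disjoint
#' (non-overlapping) positions; `hairpinStem` additionally requires a loop
#' of at least `minLoop` nucleotides between the two arms. The composite is
#' w1*max(0, direct-k0) + w2*max(0, inverted-k0); hairpins weigh double
#' because they are the stated failure mode for polymerase/ligase steps.
#'
#' @param ntSeq DNA sequence over A,C,G,T.
#' @param k0 repeat length below which no penalty accrues (default 8 nt).
#' @param w1,w2 weights for direct and inverted repeats.
#' @param minLoop minimum hairpin loop (default 3 nt).
#' @return list(longestDirectRepeat, longestInvertedRepeat, hairpinStem,
#'   composite).
#' @examples
#' repeatStructureScore("AAAAAA")$longestDirectRepeat   # 5
#' repeatStructureScore("AAATTT")$longestInvertedRepeat # 3
#' @export
repeatStructureScore <- function(ntSeq, k0 = 8L, w1 = 1, w2 = 2,
                                 minLoop = 3L) {
  if (nchar(ntSeq) == 0L)
    return(list(longestDirectRepeat = 0L, longestInvertedRepeat = 0L,
                hairpinStem = 0L, composite = 0))
  if (grepl("[^ACGT]", ntSeq)) stop("sequence must be over A,C,G,T")
  dir <- longestDirectRepeat(ntSeq)
  inv <- longestInvertedRepeat(ntSeq, minGap = 0L)
  stem <- longestInvertedRepeat(ntSeq, minGap = minLoop)
  comp <- w1 * max(0L, dir - k0) + w2 * max(0L, inv - k0)
  list(longestDirectRepeat = dir, longestInvertedRepeat = inv,
       hairpinStem = stem, composite = comp)
}

# Binary search on repeat length; a length-L repeat implies one of L-1.
longestDirectRepeat <- function(s) {
  n <- nchar(s)
  hasDup <- function(L) {
    if (L > n - 1L) return(FALSE)
    subs <- substring(s, 1:(n - L + 1L), L:n)
    anyDuplicated(subs) > 0L
  }
  lo <- 1L; hi <- n - 1L
  if (!hasDup(1L)) return(1L) # convention: nonempty sequences score >= 1
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (hasDup(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

longestInvertedRepeat <- function(s, minGap = 0L) {
  n <- nchar(s)
  rc <- revcomp(s)
  # positions of rc substrings map back to s: rc[i..i+L-1] is the revcomp of
  # s[n-L-i+2 .. n-i+1]; search directly on s for each candidate length.
  has <- function(L) {
    if (2L * L + minGap > n) return(FALSE)
    subs <- substring(s, 1:(n - L + 1L), L:n)
    rcsubs <- substring(rc, 1:(n - L + 1L), L:n)
    # rcsubs[j] equals revcomp of s at start position n - L - j + 2
    for (i in seq_along(subs)) {
      j <- which(rcsubs == subs[i])
      if (length(j)) {
        starts <- n - L - j + 2L
        # disjoint with required gap, in either order
        if (any(starts >= i + L + minGap | i >= starts + L + minGap))
          return(TRUE)
      }
    }
    FALSE
  }
  lo <- 0L; hi <- (n - minGap) %/% 2L
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Scan for restriction-site matches with IUPAC degeneracy
#'
#' The default pattern ACCWGGT (SexAI) is its own reverse complement under
#' W = A/T, so scanning one strand covers both.
#'
#' @param ntSeq DNA sequence.
#' @param pattern IUPAC pattern (default "ACCWGGT").
#' @param circular scan across the origin of a circular sequence.
#' @return Integer vector of 1-based match start positions (wraparound
#'   matches report their start within the linear sequence).
#' @examples
#' scanRestrictionSites("AAACCTGGTAAA")  # 3
#' @export
scanRestrictionSites <- function(ntSeq, pattern = "ACCWGGT",
                                 circular = FALSE) {
  if (!all(chars(pattern) %in% names(Biostrings::IUPAC_CODE_MAP)))
    stop("invalid IUPAC code in pattern")
  subject <- if (circular)
    paste0(ntSeq, substr(ntSeq, 1L, min(nchar(pattern) - 1L, nchar(ntSeq))))
  else ntSeq
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject),
                                   fixed = FALSE)
  pos <- BiocGenerics::start(hits)
  if (circular) pos <- unique((pos - 1L) %% nchar(ntSeq) + 1L)
  sort(pos)
}

#' Reverse-translate a repeat unit into a scrambled 72-nt oligo design
#'
#' Codons are drawn from the usage table (relative fraction >= `cutoff`),
#' with three fixed junction codons: the leading Pro and Gly are CCT and
#' GGT and the final residue uses its most frequent A-ending codon, so that
#' circularization creates the SexAI site ACCTGGT exactly once across the
#' junction. The remaining codons are optimized by seeded simulated
#' annealing to minimize the composite repeat score of the circular
#' sequence; any internal ACCWGGT match carries a large penalty and aborts
#' acceptance of the design if it cannot be removed.
#'
#' @param aaUnit amino-acid repeat unit in PGXXXX phase (length divisible
#'   by 6, starting "PG").
#' @param usage codon usage table (see [defaultCodonUsage]).
#' @param seed integer seed (same seed, same inputs: identical output).
#' @param cutoff usage-fraction admissibility cutoff (default 0.10).
#' @param iterations annealing iterations (default 400).
#' @param k0,w1,w2 repeat-score parameters passed to
#'   [repeatStructureScore].
#' @param nRestarts independent annealing restarts before giving up on the
#'   internal-site constraint.
#' @return An [OligoDesign-class].
#' @export
reverseTranslateScrambled <- function(aaUnit, usage = defaultCodonUsage(),
                                      seed = 1L, cutoff = 0.10,
                                      iterations = 400L,
                                      k0 = 8L, w1 = 1, w2 = 2,
                                      nRestarts = 4L) {
  aa <- chars(aaUnit)
  if (!all(aa %in% AA20)) stop("non-standard residue in unit")
  if (length(aa) %% 6L != 0L || substr(aaUnit, 1L, 2L) != "PG")
    stop("unit must be in PGXXXX phase (length a multiple of 6)")
  adm <- admissibleCodons(usage, cutoff)
  if (!all(aa %in% names(adm)))
    stop("residue with no admissible codon: ",
         paste(setdiff(aa, names(adm)), collapse = ","))
  nC <- length(aa)
  fixed <- rep(FALSE, nC)
  fixedCodon <- rep(NA_character_, nC)
  fixedCodon[1L] <- "CCT"; fixedCodon[2L] <- "GGT"
  jc <- junctionCodon(aa[nC], usage)
  if (is.na(jc))
    stop("design failure: residue ", aa[nC],
         " at the junction position has no A-ending codon")
  fixedCodon[nC] <- jc
  fixed[c(1L, 2L, nC)] <- TRUE

  objective <- function(codons) {
    s <- paste(codons, collapse = "")
    sc <- repeatStructureScore(s, k0 = k0, w1 = w1, w2 = w2)
    internal <- internalSiteCount(s)
    sc$composite + 1000 * internal
  }

  best <- NULL; bestObj <- Inf
  for (attempt in seq_len(nRestarts)) {
    res <- withSeed(deriveSeed(seed, attempt), {
      codons <- vapply(seq_len(nC), function(i) {
        if (fixed[i]) fixedCodon[i] else {
          opts <- adm[[aa[i]]]
          opts[sample.int(length(opts), 1L)]
        }
      }, "")
      cur <- objective(codons)
      curCodons <- codons
      free <- which(!fixed & vapply(aa, function(a)
        length(adm[[a]]) > 1L, logical(1)))
      if (length(free)) {
        temps <- seq(4, 0.05, length.out = iterations)
        for (it in seq_len(iterations)) {
          i <- free[sample.int(length(free), 1L)]
          opts <- setdiff(adm[[aa[i]]], curCodons[i])
          prop <- curCodons
          prop[i] <- opts[sample.int(length(opts), 1L)]
          val <- objective(prop)
          if (val <= cur || runif(1) < exp((cur - val) / temps[it])) {
            cur <- val; curCodons <- prop
          }
        }
      }
      list(codons = curCodons, obj = cur)
    })
    if (res$obj < bestObj) { bestObj <- res$obj; best <- res$codons }
    if (bestObj < 1000) break
  }
  nt <- paste(best, collapse = "")
  if (internalSiteCount(nt) > 0L)
    stop("design failure: internal ACCWGGT site could not be removed for ",
         aaUnit)
  design <- new("OligoDesign",
                ntSeq = nt, encodedUnit = aaUnit,
                sitePattern = "ACCWGGT",
                score = repeatStructureScore(nt, k0 = k0, w1 = w1, w2 = w2),
                seed = as.integer(seed), motifId = "")
  embedJunctionSite(design)
}

# Count ACCWGGT matches on the circularized sequence, excluding the single
# junction-spanning site (which starts at the last base of the linear seq).
internalSiteCount <- function(nt) {
  pos <- scanRestrictionSites(nt, circular = TRUE)
  sum(pos != nchar(nt))
}

#' Verify the junction-split SexAI site of an oligo design
#'
#' Confirms the contract of the split-site layout: the linear oligo begins
#' with CCTGGT (the 3' fragment of the site) and ends with the A that
#' completes ACCTGGT upon circularization; the circularized sequence
#' matches the degenerate pattern exactly once (at the junction) on either
#' strand; and the translation round-trips to the encoded unit.
#'
#' @param design an [OligoDesign-class] (or plain DNA string plus `unit`).
#' @param unit encoded unit, required when `design` is a plain string.
#' @return The validated [OligoDesign-class]; errors on violation.
#' @export
embedJunctionSite <- function(design, unit = NULL) {
  if (!is(design, "OligoDesign")) {
    if (is.null(unit)) stop("unit required for a plain sequence")
    design <- new("OligoDesign", ntSeq = design, encodedUnit = unit,
                  sitePattern = "ACCWGGT",
                  score = repeatStructureScore(design),
                  seed = NA_integer_, motifId = "")
  }
  nt <- design@ntSeq
  if (substr(nt, 1L, 6L) != "CCTGGT")
    stop("linear oligo must begin with CCTGGT (3' fragment of the site)")
  if (substr(nt, nchar(nt), nchar(nt)) != "A")
    stop("linear oligo must end in A (5' fragment of the site)")
  pos <- scanRestrictionSites(nt, design@sitePattern, circular = TRUE)
  if (!identical(pos, nchar(nt)))
    stop("circularized design must contain the recognition site exactly ",
         "once, at the junction (found at: ",
         paste(pos, collapse = ","), ")")
  if (translateDNA(nt) != design@encodedUnit)
    stop("translation does not round-trip to the encoded unit")
  design
}

#' Naive most-frequent-codon encoding (scrambler baseline)
#'
#' @param aaUnit amino-acid sequence.
#' @param usage codon usage table.
#' @return DNA string using each residue's single most frequent codon.
#' @export
naiveEncoding <- function(aaUnit, usage = defaultCodonUsage()) {
  topCodon <- vapply(split(usage, usage$aa),
                     function(d) d$codon[which.max(d$fraction)], "")
  paste(topCodon[chars(aaUnit)], collapse = "")
}

#' Digest a circular multimer of a design and translate the fragments
#'
#' Cuts a circular n-mer of the oligo at every SexAI junction (top strand
#' cut after the leading A), yielding fragments that translate in the
#' (GX1X2X3X4P)n phase.
#'
#' @param design an [OligoDesign-class].
#' @param nCopies number of tandem copies in the circle.
#' @return data.frame(fragment, translation).
#' @export
digestCircularMultimer <- function(design, nCopies = 2L) {
  embedJunctionSite(design)
  # cutting after the junction A releases fragments identical to the linear
  # oligo: CCTGGT ... A. Rotating a fragment by one codon (CCT to the back)
  # puts it in the GX1X2X3X4P reading phase.
  frags <- rep(design@ntSeq, nCopies)
  trans <- vapply(frags, function(f)
    translateDNA(rotateString(f, 3L)), "", USE.NAMES = FALSE)
  data.frame(fragment = frags, translation = trans,
             stringsAsFactors = FALSE)
}
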