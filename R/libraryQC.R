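# Library verification from sequencing reads.
#
# Reads are tandem-repeat substrings of concatemerized 72-nt designs. Each
# read is aligned circularly (against the infinitely tiled unit, over all
# 72 phase offsets and both orientations) by exact semi-global edit-distance
# DP, then filtered by the rules used for the real sequencing run: too
# short, poor alignment, nonsense mutation, large frameshift, or fewer than
# 3 perfect repeats.

#' Simulate sequencing reads from a set of oligo designs
#'
#' Emulates the verification sequencing input: each read is a substring of
#' a concatemerized design with injected substitutions and 1-nt indels, in
#' forward or reverse-complement orientation. Ground truth (design, phase,
#' orientation, error count) is recorded in the read names as
#' `read<k>|<design>|<phase>|<orientation>|<subs>|<indels>`.
#'
#' @param designs list of [OligoDesign-class] (or named character vector of
#'   72-nt sequences).
#' @param nReads number of reads.
#' @param readLen read length (nt).
#' @param subRate per-base substitution probability.
#' @param indelRate per-base indel probability (single-base events).
#' @param revcompFraction fraction of reads drawn in reverse complement.
#' @param seed integer seed; same seed gives byte-identical output.
#' @param file optional FASTQ path; when given, reads are also written.
#' @param concatemerUnits repeat units per cloned concatemer (default 8,
#'   the top of the gel-selection window); reads longer than the
#'   concatemer are an error.
#' @return Named character vector of reads (names carry provenance).
#' @export
simulateReads <- function(designs, nReads = 100L, readLen = 250L,
                          subRate = 0, indelRate = 0,
                          revcompFraction = 0, seed = 1L, file = NULL,
                          concatemerUnits = 8L) {
  stopifnot(subRate >= 0, subRate <= 1, indelRate >= 0, indelRate <= 1,
            revcompFraction >= 0, revcompFraction <= 1)
  seqs <- if (is.list(designs))
    vapply(designs, oligoSeq, "") else designs
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- sprintf("design%03d", seq_along(seqs))
  unitLen <- unique(nchar(seqs))
  if (length(unitLen) != 1L) stop("all designs must share one unit length")
  if (readLen < 1L) stop("readLen must be positive")
  if (readLen > concatemerUnits * unitLen)
    stop("readLen exceeds the concatemer length (",
         concatemerUnits * unitLen, " bp)")
  nTile <- ceiling(readLen / unitLen) + 2L
  reads <- withSeed(seed, {
    out <- character(nReads)
    nm <- character(nReads)
    for (i in seq_len(nReads)) {
      d <- sample.int(length(seqs), 1L)
      conc <- strrep(seqs[[d]], nTile)
      if (readLen > nchar(conc)) stop("readLen exceeds concatemer length")
      phase <- sample.int(unitLen, 1L) - 1L
      raw <- substr(conc, phase + 1L, phase + readLen)
      b <- chars(raw)
      subs <- which(runif(length(b)) < subRate)
      for (p in subs) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
      nIndel <- 0L
      if (indelRate > 0) {
        pos <- which(runif(length(b)) < indelRate)
        nIndel <- length(pos)
        for (p in rev(pos)) {
          if (runif(1) < 0.5) b <- b[-p]               # deletion
          else b <- append(b, sample(c("A", "C", "G", "T"), 1L), after = p)
        }
      }
      rd <- paste(b, collapse = "")
      orient <- "forward"
      if (runif(1) < revcompFraction) {
        rd <- revcomp(rd)
        orient <- "reverse_complement"
      }
      out[i] <- rd
      nm[i] <- sprintf("read%05d|%s|%d|%s|%d|%d",
                       i, names(seqs)[d], phase, orient,
                       length(subs), nIndel)
    }
    setNames(out, nm)
  })
  if (!is.null(file)) {
    x <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(
      x, file, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  }
  reads
}

# Edit-distance semi-global alignment of a read against the tiled unit in
# one orientation. Exact DP via Biostrings::pairwiseAlignment with unit
# costs (match 0, mismatch/gap -1), pattern-global / subject-local.
alignOneOrientation <- function(read, unit) {
  tiled <- tileString(unit, nchar(read) + 2L * nchar(unit))
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(tiled),
    type = "global-local", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 1)
  ins <- Biostrings::indel(Biostrings::pattern(aln))[[1]] # gaps in read view
  del <- Biostrings::indel(Biostrings::subject(aln))[[1]]
  indels <- rbind(
    if (length(ins)) data.frame(position = BiocGenerics::start(ins),
                                width = BiocGenerics::width(ins),
                                type = "deletion") else NULL,
    if (length(del)) data.frame(position = BiocGenerics::start(del),
                                width = BiocGenerics::width(del),
                                type = "insertion") else NULL)
  if (is.null(indels))
    indels <- data.frame(position = integer(), width = integer(),
                         type = character())
  nSubs <- Biostrings::nmismatch(aln)
  list(edits = as.integer(-BiocGenerics::score(aln)),
       nSubs = as.integer(nSubs),
       phase = (BiocGenerics::start(Biostrings::subject(aln)) - 1L) %%
         nchar(unit),
       indels = indels)
}

# Count of exact 72-nt unit copies in a read: positions matching any cyclic
# rotation of the unit, maximized over the 72 phase classes (occurrences in
# one class are spaced >= 72 nt, hence disjoint).
countPerfectRepeats <- function(read, unit) {
  L <- nchar(unit)
  n <- nchar(read)
  if (n < L) return(0L)
  starts <- seq_len(n - L + 1L)
  rots <- vapply(0:(L - 1L), function(k) rotateString(unit, k), "")
  wins <- substring(read, starts, starts + L - 1L)
  hit <- wins %in% rots
  if (!any(hit)) return(0L)
  classes <- (starts[hit] - 1L) %% L
  max(table(classes))
}

#' Circular alignment of a read against a 72-nt reference unit
#'
#' Minimal-edit alignment over all phase offsets of the infinitely tiled
#' reference and both orientations (exact semi-global DP; the read is
#' aligned end-to-end, the tiled reference locally).
#'
#' @param read DNA read (>= 20 nt).
#' @param referenceUnit 72-nt reference unit (linear oligo sequence).
#' @param readId identifier stored in the result.
#' @param referenceId reference identifier stored in the result.
#' @return A [ReadAlignment-class].
#' @export
alignReadCircular <- function(read, referenceUnit, readId = "read",
                              referenceId = "ref") {
  if (nchar(read) < 20L) stop("read must be at least 20 nt")
  fwd <- alignOneOrientation(read, referenceUnit)
  rev <- alignOneOrientation(revcomp(read), referenceUnit)
  orient <- if (rev$edits < fwd$edits) "reverse_complement" else "forward"
  best <- if (orient == "forward") fwd else rev
  oriented <- if (orient == "forward") read else revcomp(read)
  new("ReadAlignment",
      readId = readId, reference = referenceId, orientation = orient,
      phaseOffset = as.integer(best$phase),
      nEdits = best$edits, nSubs = best$nSubs,
      indelEvents = best$indels,
      nPerfectRepeats = as.integer(countPerfectRepeats(oriented,
                                                       referenceUnit)),
      alignScore = best$edits / nchar(read),
      readLength = nchar(read))
}

#' Align reads against a reference library
#'
#' Each read is aligned circularly against every reference unit; the best
#' (minimum-edit) reference is reported.
#'
#' @param reads named character vector of reads.
#' @param refs named character vector of 72-nt reference units.
#' @return list of [ReadAlignment-class], one per read.
#' @export
alignReadsToLibrary <- function(reads, refs) {
  if (is.null(names(refs))) names(refs) <- sprintf("ref%03d", seq_along(refs))
  lapply(seq_along(reads), function(i) {
    alns <- lapply(seq_along(refs), function(j)
      alignReadCircular(reads[[i]], refs[[j]],
                        readId = names(reads)[i] %||% paste0("read", i),
                        referenceId = names(refs)[j]))
    edits <- vapply(alns, function(a) a@nEdits, integer(1))
    alns[[which.min(edits)]]
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Default QC filter thresholds
#'
#' @param tooShort minimum read length (nt).
#' @param poorAlignment maximum edits per aligned base.
#' @param frameshiftWindow frame must be restored within this many nt.
#' @param minPerfectRepeats minimum count of exact 72-nt unit copies.
#' @return Named list of thresholds.
#' @export
qcThresholds <- function(tooShort = 100L, poorAlignment = 0.10,
                         frameshiftWindow = 24L, minPerfectRepeats = 3L) {
  list(tooShort = tooShort, poorAlignment = poorAlignment,
       frameshiftWindow = frameshiftWindow,
       minPerfectRepeats = minPerfectRepeats)
}

#' Filter verdict for an aligned read
#'
#' Applies the library-verification filtering rules: reads failing any of
#' too_short, poor_alignment, nonsense (in-frame stop in the repeat reading
#' frame), large_frameshift (net frame disruption not restored within the
#' threshold window), or few_perfect_repeats (< 3 exact unit copies).
#'
#' @param aln a [ReadAlignment-class].
#' @param read the (oriented or raw) read sequence; reverse-complemented
#'   internally when the alignment is in reverse orientation.
#' @param thresholds see [qcThresholds].
#' @return list(status = "pass"|"fail", reasons = character()).
#' @export
classifyRead <- function(aln, read, thresholds = qcThresholds()) {
  reasons <- character()
  if (aln@readLength < thresholds$tooShort)
    reasons <- c(reasons, "too_short")
  if (aln@alignScore > thresholds$poorAlignment)
    reasons <- c(reasons, "poor_alignment")
  oriented <- if (aln@orientation == "reverse_complement")
    revcomp(read) else read
  if (hasNonsense(oriented, aln@phaseOffset))
    reasons <- c(reasons, "nonsense")
  if (hasLargeFrameshift(aln@indelEvents, aln@readLength,
                         thresholds$frameshiftWindow))
    reasons <- c(reasons, "large_frameshift")
  if (aln@nPerfectRepeats < thresholds$minPerfectRepeats)
    reasons <- c(reasons, "few_perfect_repeats")
  list(status = if (length(reasons)) "fail" else "pass", reasons = reasons)
}

# In-frame stop in the repeat reading frame. The reference unit is
# codon-aligned at phase 0, so the first complete codon of a read at phase
# p starts at read offset (3 - p %% 3) %% 3.
hasNonsense <- function(read, phaseOffset) {
  off <- (3L - phaseOffset %% 3L) %% 3L
  aa <- translateDNA(substr(read, off + 1L, nchar(read)))
  grepl("*", aa, fixed = TRUE)
}

# Walk indel events along the read; a stretch with nonzero cumulative frame
# offset longer than `window` nt (or unresolved at read end) is a large
# frameshift.
hasLargeFrameshift <- function(indels, readLen, window = 24L) {
  if (nrow(indels) == 0L) return(FALSE)
  sgn <- ifelse(indels$type == "insertion", 1L, -1L)
  ev <- data.frame(pos = indels$position, shift = sgn * indels$width)
  ev <- ev[order(ev$pos), , drop = FALSE]
  frame <- 0L
  startBad <- NA_integer_
  for (i in seq_len(nrow(ev))) {
    prevFrame <- frame
    frame <- (frame + ev$shift[i]) %% 3L
    if (prevFrame == 0L && frame != 0L) startBad <- ev$pos[i]
    if (prevFrame != 0L && frame == 0L) {
      if (ev$pos[i] - startBad > window) return(TRUE)
      startBad <- NA_integer_
    }
  }
  if (frame != 0L && !is.na(startBad) && (readLen - startBad) > window)
    return(TRUE)
  FALSE
}

#' Library-level summary of alignments and verdicts
#'
#' Reports the four fields used to summarize the real verification run:
#' unique (reference, edit-pattern) alignments; unique read sequences
#' passing all filters; distinct references hit in forward orientation;
#' distinct references hit in reverse complement.
#'
#' @param alignments list of [ReadAlignment-class].
#' @param verdicts list of verdicts from [classifyRead] (same order).
#' @param reads the read sequences (same order).
#' @return list(uniqueAlignments, uniquePassing, forwardRefs, revcompRefs).
#' @export
summarizeLibrary <- function(alignments, verdicts, reads) {
  pat <- vapply(alignments, function(a)
    paste(a@reference, a@nEdits, a@nSubs, nrow(a@indelEvents),
          a@phaseOffset, sep = ":"), "")
  pass <- vapply(verdicts, function(v) v$status == "pass", logical(1))
  fwd <- vapply(alignments, function(a) a@orientation == "forward",
                logical(1))
  refs <- vapply(alignments, function(a) a@reference, "")
  list(uniqueAlignments = length(unique(pat)),
       uniquePassing = length(unique(reads[pass])),
       forwardRefs = length(unique(refs[pass & fwd])),
       revcompRefs = length(unique(refs[pass & !fwd])))
}

#' Read a FASTQ file as a named character vector
#'
#' @param file FASTQ path.
#' @return Named character vector of read sequences.
#' @export
readFastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  setNames(as.character(x), names(x))
}
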