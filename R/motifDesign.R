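# Motif enumeration and repeat-unit construction.
#
# A SynIDP repeat motif is the hexapeptide P-G-X1-X2-X3-X4. Motifs are
# identified up to permutation of the X residues, so the library is
# enumerated over residue *multisets* and each multiset is realized as one
# canonical ordered motif.

#' Construct a MotifSpec
#'
#' @param alphabet candidate residues for the X positions. Default: the 20
#'   standard residues minus the globally forbidden ones.
#' @param forbiddenGlobal residues excluded from all X positions (default
#'   proline and cysteine).
#' @param requiredResidue residue required at least once among X1..X4
#'   (default glycine).
#' @param forbiddenAtX4 residues excluded from X4 (default glycine, so no
#'   GP dipeptide forms across the repeat boundary).
#' @param requireJunctionCodon require a junction-codon-capable residue at
#'   X4 (an A-ending codon completes the split SexAI site); default TRUE.
#' @param curationExcludes optional character vector of multiset keys to
#'   exclude from enumeration (hook for matching an externally curated list).
#' @return A validated [MotifSpec-class].
#' @examples
#' spec <- MotifSpec(alphabet = c("A", "G", "S"))
#' enumerateMotifs(spec)
#' @export
MotifSpec <- function(alphabet = NULL,
                      forbiddenGlobal = c("P", "C"),
                      requiredResidue = "G",
                      forbiddenAtX4 = "G",
                      requireJunctionCodon = TRUE,
                      curationExcludes = character()) {
  if (is.null(alphabet)) alphabet <- setdiff(AA20, forbiddenGlobal)
  alphabet <- sort(setdiff(unique(alphabet), forbiddenGlobal))
  new("MotifSpec",
      alphabet = alphabet,
      forbiddenGlobal = forbiddenGlobal,
      requiredResidue = requiredResidue,
      forbiddenAtX4 = forbiddenAtX4,
      scaffold = c("P", "G"),
      nX = 4L,
      requireJunctionCodon = requireJunctionCodon,
      junctionResidues = junctionCapableResidues(),
      curationExcludes = as.character(curationExcludes))
}

#' Residues with at least one A-ending codon
#'
#' The SexAI recognition site ACCTGGT is split across the circular junction
#' of the 72-nt oligo as ...A | CCTGGT..., so the codon of the last residue
#' of the repeat unit (X4) must end in A. Only residues owning an A-ending
#' codon in the standard genetic code can occupy that position.
#'
#' @return Character vector of residues (stop codons excluded).
#' @export
junctionCapableResidues <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(setdiff(unique(gc[endsWith(names(gc), "A")]), "*"))
}

# Residues admissible at X4 under a spec.
x4Candidates <- function(spec) {
  cand <- setdiff(spec@alphabet, spec@forbiddenAtX4)
  if (spec@requireJunctionCodon) cand <- intersect(cand, spec@junctionResidues)
  cand
}

# Canonical multiset key: residues sorted ascending, concatenated.
multisetKey <- function(x) paste(sort(x), collapse = "")

#' Enumerate all admissible motifs under a spec
#'
#' One canonical motif per admissible residue multiset, in lexicographic
#' order of the multiset key. A multiset is admissible when all members are
#' in the alphabet, the required residue occurs at least once, and at least
#' one member can legally occupy X4 (not forbidden there; with the junction
#' rule on, also junction-codon capable). Under the default spec with the
#' full 18-residue alphabet this yields the 1020-motif design library.
#'
#' @param spec a [MotifSpec-class].
#' @return A [MotifLibrary-class].
#' @export
enumerateMotifs <- function(spec) {
  stopifnot(is(spec, "MotifSpec"))
  validObject(spec)
  alpha <- spec@alphabet
  # All size-4 multisets as non-decreasing index 4-tuples.
  n <- length(alpha)
  combs <- combIndex4(n)
  keys <- apply(combs, 1L, function(i) paste(alpha[i], collapse = ""))
  keep <- vapply(seq_len(nrow(combs)), function(r) {
    xs <- alpha[combs[r, ]]
    if (!(spec@requiredResidue %in% xs)) return(FALSE)
    length(intersect(xs, x4Candidates(spec))) > 0L
  }, logical(1))
  keys <- keys[keep]
  keys <- setdiff(keys, spec@curationExcludes)
  keys <- sort(keys)
  rows <- lapply(keys, function(k) {
    m <- realizeMotif(chars(k), spec)
    data.frame(x1 = m[1], x2 = m[2], x3 = m[3], x4 = m[4],
               multisetKey = k,
               peptide = paste0("PG", paste(m, collapse = "")),
               stringsAsFactors = FALSE)
  })
  motifs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x1 = character(), x2 = character(), x3 = character(),
               x4 = character(), multisetKey = character(),
               peptide = character(), stringsAsFactors = FALSE)
  new("MotifLibrary", motifs = motifs, spec = spec)
}

# Non-decreasing 4-tuples of indices 1..n (multiset enumeration).
combIndex4 <- function(n) {
  out <- matrix(0L, nrow = choose(n + 3, 4), ncol = 4)
  r <- 0L
  for (a in seq_len(n)) for (b in a:n) for (cc in b:n) for (d in cc:n) {
    r <- r + 1L
    out[r, ] <- c(a, b, cc, d)
  }
  out
}

#' Realize a residue multiset as a canonical ordered motif
#'
#' Canonicalization: X4 is the lexicographically largest admissible
#' candidate in the multiset (not the required residue; not forbidden at
#' X4; junction-codon capable when that rule is on); the remaining three
#' residues are sorted ascending into X1..X3.
#'
#' @param multiset character vector of 4 residues (any order).
#' @param spec a [MotifSpec-class].
#' @return Character vector of 4 residues, X1..X4.
#' @export
realizeMotif <- function(multiset, spec) {
  stopifnot(length(multiset) == 4L)
  xs <- sort(multiset)
  cand <- intersect(xs, x4Candidates(spec))
  cand <- setdiff(cand, spec@requiredResidue)
  if (length(cand) == 0L) {
    # fall back to any admissible X4 (covers e.g. a required residue that is
    # X4-legal under a relaxed spec); otherwise the multiset is unrealizable
    cand <- intersect(xs, x4Candidates(spec))
    if (length(cand) == 0L)
      stop("multiset {", paste(xs, collapse = ","),
           "} has no admissible residue for X4")
  }
  x4 <- max(cand)
  rest <- xs[-match(x4, xs)]
  c(sort(rest), x4)
}

#' Build the repeat unit encoded by a motif
#'
#' @param motif character vector X1..X4, a motif peptide string "PGxxxx",
#'   or a single row taken from [motifTable].
#' @param nRepeats number of hexapeptide repeats (default 4, giving the
#'   24-residue unit encoded by one 72-nt oligo).
#' @param phase "PG" returns (PGX1X2X3X4)_n as designed; "GP" returns the
#'   cyclic rotation (GX1X2X3X4P)_n seen in digested fragments.
#' @return Amino-acid sequence of length 6 * nRepeats.
#' @examples
#' buildRepeatUnit(c("Q", "S", "G", "L"), 4)           # (PGQSGL)4
#' buildRepeatUnit("PGTHGT", 4, phase = "GP")          # (GTHGTP)4
#' @export
buildRepeatUnit <- function(motif, nRepeats = 4L, phase = c("PG", "GP")) {
  phase <- match.arg(phase)
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  if (is.character(motif) && length(motif) == 1L) {
    if (!startsWith(motif, "PG") || nchar(motif) != 6L)
      stop("motif string must be a PGxxxx hexapeptide")
    motif <- chars(substr(motif, 3L, 6L))
  }
  stopifnot(length(motif) == 4L)
  hexa <- paste0("PG", paste(motif, collapse = ""))
  unit <- strrep(hexa, nRepeats)
  if (phase == "GP") unit <- rotateString(unit, 1L)
  unit
}

#' Validate a motif library against a spec
#'
#' Report-only check used to audit imported or externally edited libraries.
#'
#' @param library a [MotifLibrary-class] (or its motif table).
#' @param spec a [MotifSpec-class].
#' @return data.frame(multisetKey, peptide, violation); zero rows iff the
#'   library is valid.
#' @export
validateLibrary <- function(library, spec) {
  m <- if (is(library, "MotifLibrary")) motifTable(library) else library
  out <- list()
  for (r in seq_len(nrow(m))) {
    xs <- c(m$x1[r], m$x2[r], m$x3[r], m$x4[r])
    bad <- character()
    if (any(xs %in% spec@forbiddenGlobal))
      bad <- c(bad, "forbidden residue")
    if (m$x4[r] %in% spec@forbiddenAtX4)
      bad <- c(bad, "forbidden at X4")
    if (!(spec@requiredResidue %in% xs))
      bad <- c(bad, "missing required residue")
    if (spec@requireJunctionCodon &&
        !(m$x4[r] %in% spec@junctionResidues))
      bad <- c(bad, "X4 lacks A-ending codon")
    if (!all(xs %in% spec@alphabet))
      bad <- c(bad, "residue outside alphabet")
    for (b in bad)
      out[[length(out) + 1L]] <- data.frame(
        multisetKey = m$multisetKey[r], peptide = m$peptide[r],
        violation = b, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(multisetKey = character(), peptide = character(),
               violation = character(), stringsAsFactors = FALSE)
}

#' Export a motif library
#'
#' Writes the protein repeat units as FASTA and the motif table as TSV.
#'
#' @param library a [MotifLibrary-class].
#' @param fastaFile,tsvFile output paths (either may be NULL to skip).
#' @param nRepeats repeats per unit for the FASTA export.
#' @return Invisibly, the motif table.
#' @export
exportLibrary <- function(library, fastaFile = NULL, tsvFile = NULL,
                          nRepeats = 4L) {
  m <- motifTable(library)
  if (!is.null(fastaFile)) {
    units <- vapply(m$peptide, buildRepeatUnit, "", nRepeats = nRepeats)
    aa <- Biostrings::AAStringSet(setNames(units, m$multisetKey))
    Biostrings::writeXStringSet(aa, fastaFile)
  }
  if (!is.null(tsvFile))
    write.table(m, tsvFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
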