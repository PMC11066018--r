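#' MotifSpec: constraints defining admissible PG-X4 repeat motifs
#'
#' A motif is the hexapeptide P-G-X1-X2-X3-X4. This object records the residue
#' alphabet available for the X positions, globally forbidden residues
#' (default proline, to keep the scaffold periodicity unique, and cysteine,
#' which forms aggregation-prone disulfides), the residue required at least
#' once among X1..X4 (default glycine), and residues forbidden at X4
#' (default glycine, to avoid GP dipeptides across the repeat boundary).
#'
#' When `requireJunctionCodon` is `TRUE` (the default) a multiset is only
#' admissible if some non-required member can sit at X4 with a codon ending
#' in A, which is what lets the split SexAI recognition site (A|CCTGGT) form
#' across the circular junction of the 72-nt oligonucleotide. Under the full
#' 18-residue alphabet this rule yields exactly 1020 motifs.
#'
#' @slot alphabet candidate residues for the X positions.
#' @slot forbiddenGlobal residues excluded everywhere.
#' @slot requiredResidue residue required at least once among X1..X4.
#' @slot forbiddenAtX4 residues excluded from X4.
#' @slot scaffold fixed dipeptide prefix, "P","G".
#' @slot nX number of X positions (fixed at 4).
#' @slot requireJunctionCodon logical; enforce the A-ending-codon rule at X4.
#' @slot junctionResidues residues owning at least one A-ending codon.
#' @slot curationExcludes optional multiset keys to drop from enumeration.
#' @exportClass MotifSpec
setClass("MotifSpec",
  representation(
    alphabet = "character",
    forbiddenGlobal = "character",
    requiredResidue = "character",
    forbiddenAtX4 = "character",
    scaffold = "character",
    nX = "integer",
    requireJunctionCodon = "logical",
    junctionResidues = "character",
    curationExcludes = "character"
  )
)

setValidity("MotifSpec", function(object) {
  msg <- character()
  if (length(object@requiredResidue) != 1L)
    msg <- c(msg, "requiredResidue must be a single residue")
  if (object@requiredResidue %in% object@forbiddenGlobal)
    msg <- c(msg, "required residue is globally forbidden: spec inconsistent")
  if (!all(object@alphabet %in% AA20))
    msg <- c(msg, "alphabet contains non-standard residues")
  if (object@nX != 4L)
    msg <- c(msg, "only the 4-X-position design is supported")
  if (!identical(object@scaffold, c("P", "G")))
    msg <- c(msg, "scaffold must be the P,G dipeptide")
  if (!(object@requiredResidue %in% object@alphabet))
    msg <- c(msg, "required residue must be in the alphabet")
  if (length(msg)) msg else TRUE
})

#' MotifLibrary: an enumerated, deduplicated motif library
#'
#' One canonical motif per admissible residue multiset, in lexicographic
#' order of the multiset key, together with the generating [MotifSpec-class].
#'
#' @slot motifs data.frame with columns x1..x4, multisetKey, peptide.
#' @slot spec the generating MotifSpec.
#' @exportClass MotifLibrary
setClass("MotifLibrary",
  representation(motifs = "data.frame", spec = "MotifSpec")
)

setValidity("MotifLibrary", function(object) {
  m <- object@motifs
  need <- c("x1", "x2", "x3", "x4", "multisetKey", "peptide")
  if (!all(need %in% names(m)))
    return("motifs table must have columns x1..x4, multisetKey, peptide")
  if (anyDuplicated(m$multisetKey))
    return("duplicate multiset keys: library not deduplicated")
  TRUE
})

#' OligoDesign: a 72-nt codon-level encoding of one repeat unit
#'
#' @slot ntSeq 72-nt DNA sequence (character); the linear oligo begins with
#'   CCTGGT (the 3' fragment of the SexAI site) and ends with the A that
#'   completes the site upon circularization.
#' @slot encodedUnit the 24-residue repeat unit in PGXXXX phase.
#' @slot sitePattern IUPAC recognition pattern (ACCWGGT).
#' @slot score repeat-structure score list (see [repeatStructureScore]).
#' @slot seed integer seed used by the codon scrambler.
#' @slot motifId multiset key of the generating motif ("" if free-standing).
#' @exportClass OligoDesign
setClass("OligoDesign",
  representation(
    ntSeq = "character",
    encodedUnit = "character",
    sitePattern = "character",
    score = "list",
    seed = "integer",
    motifId = "character"
  )
)

setValidity("OligoDesign", function(object) {
  msg <- character()
  if (nchar(object@ntSeq) != 3L * nchar(object@encodedUnit))
    msg <- c(msg, "nucleotide length must be 3x the encoded unit length")
  if (grepl("[^ACGT]", object@ntSeq))
    msg <- c(msg, "ntSeq must be over A,C,G,T")
  if (length(msg)) msg else TRUE
})

#' ProtectionModel: stochastic 5mC protection of restriction sites
#'
#' During RCA a fraction `fMC` of dCTP is replaced by 5-methyl-dCTP. A
#' recognition site carrying a methylated cytosine at any of its
#' `cBlocking` dcm-context positions resists cleavage, so the per-site
#' protection probability is q = 1 - (1 - fMC)^cBlocking.
#'
#' @slot fMC fraction of dCTP replaced by 5-methyl-dCTP, in [0, 1].
#' @slot cBlocking number of cytosines per site whose methylation blocks
#'   cleavage (default 4: the dcm-context cytosines on both strands).
#' @exportClass ProtectionModel
setClass("ProtectionModel",
  representation(fMC = "numeric", cBlocking = "integer")
)

setValidity("ProtectionModel", function(object) {
  if (object@fMC < 0 || object@fMC > 1)
    return("fMC must lie in [0, 1]")
  if (object@cBlocking < 0L)
    return("cBlocking must be non-negative")
  TRUE
})

#' FragmentDistribution: geometric law for digest fragment lengths
#'
#' With independent per-site protection q, the number of repeat units per
#' internal fragment is geometric: P(L = k) = q^(k-1) (1 - q), mean 1/(1-q).
#'
#' @slot q per-site protection probability.
#' @slot k fragment lengths in repeat units (1..kMax).
#' @slot pmf probabilities for each k (untruncated geometric values).
#' @exportClass FragmentDistribution
setClass("FragmentDistribution",
  representation(q = "numeric", k = "integer", pmf = "numeric")
)

#' ScatteringProfile: a 1-D small-angle scattering curve
#'
#' @slot q scattering vector (1/Angstrom), strictly increasing, positive.
#' @slot intensity intensity I(q), arbitrary units, positive.
#' @slot sigma optional 1-sigma uncertainties (length 0 when absent).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric")
)

setValidity("ScatteringProfile", function(object) {
  msg <- character()
  if (length(object@q) != length(object@intensity))
    msg <- c(msg, "q and intensity must have equal length")
  if (length(object@sigma) &&
      length(object@sigma) != length(object@q))
    msg <- c(msg, "sigma must be empty or match q in length")
  if (any(object@q <= 0))
    msg <- c(msg, "q must be strictly positive")
  if (is.unsorted(object@q, strictly = TRUE))
    msg <- c(msg, "q must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' PEVFit: fitted polymer-excluded-volume parameters
#'
#' @slot Rg radius of gyration (Angstrom).
#' @slot nu Flory excluded-volume exponent; the high-q power-law slope is
#'   -1/nu.
#' @slot scale forward-scattering scale factor.
#' @slot background flat background.
#' @slot stderr named 1-sigma uncertainties for the four parameters.
#' @slot converged logical convergence flag from the optimizer.
#' @slot rss weighted residual sum of squares at the optimum.
#' @exportClass PEVFit
setClass("PEVFit",
  representation(
    Rg = "numeric", nu = "numeric", scale = "numeric",
    background = "numeric", stderr = "numeric",
    converged = "logical", rss = "numeric"
  )
)

#' ReadAlignment: a read aligned circularly against a 72-nt reference unit
#'
#' @slot readId read identifier.
#' @slot reference identifier of the best reference unit.
#' @slot orientation "forward" or "reverse_complement".
#' @slot phaseOffset 0-based offset (0..71) of the read start within the unit.
#' @slot nEdits total edit distance (substitutions + inserted/deleted bases).
#' @slot nSubs substitution count.
#' @slot indelEvents data.frame(position, width, type) in read coordinates.
#' @slot nPerfectRepeats number of exact 72-nt unit copies in the read.
#' @slot alignScore edits per aligned base.
#' @slot readLength read length (nt).
#' @exportClass ReadAlignment
setClass("ReadAlignment",
  representation(
    readId = "character", reference = "character", orientation = "character",
    phaseOffset = "integer", nEdits = "integer", nSubs = "integer",
    indelEvents = "data.frame", nPerfectRepeats = "integer",
    alignScore = "numeric", readLength = "integer"
  )
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "MotifSpec", function(object) {
  cat("MotifSpec: P-G-X1..X4 repeat motif constraints\n")
  cat("  X alphabet:      ", paste(object@alphabet, collapse = ""), "\n")
  cat("  forbidden:       ", paste(object@forbiddenGlobal, collapse = ","),
      "(global);", paste(object@forbiddenAtX4, collapse = ","), "at X4\n")
  cat("  required among X:", object@requiredResidue, "\n")
  cat("  junction-codon rule at X4:",
      if (object@requireJunctionCodon) "on" else "off", "\n")
})

setMethod("show", "MotifLibrary", function(object) {
  cat("MotifLibrary with", nrow(object@motifs), "motifs over alphabet",
      paste(object@spec@alphabet, collapse = ""), "\n")
  if (nrow(object@motifs))
    cat("  first:", head(object@motifs$peptide, 3L), "...\n")
})

setMethod("show", "OligoDesign", function(object) {
  cat("OligoDesign (", nchar(object@ntSeq), "nt ) encoding",
      object@encodedUnit, "\n")
  cat("  ", object@ntSeq, "\n")
  if (length(object@score))
    cat("  repeat score: direct", object@score$longestDirectRepeat,
        "nt, inverted", object@score$longestInvertedRepeat,
        "nt, composite", object@score$composite, "\n")
})

setMethod("show", "ProtectionModel", function(object) {
  cat(sprintf("ProtectionModel: fMC = %.3f, cBlocking = %d, q = %.4f\n",
              object@fMC, object@cBlocking,
              protectionProbability(object@fMC, object@cBlocking)))
})

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d points, q in [%.4g, %.4g] 1/Angstrom%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with uncertainties" else ""))
})

setMethod("show", "PEVFit", function(object) {
  cat(sprintf(
    "PEV fit: Rg = %.2f A (+/- %.2f), nu = %.3f (+/- %.3f)%s\n",
    object@Rg, object@stderr[["Rg"]], object@nu, object@stderr[["nu"]],
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "ReadAlignment", function(object) {
  cat(sprintf(
    "ReadAlignment %s -> %s (%s), phase %d, edits %d, perfect repeats %d\n",
    object@readId, object@reference, object@orientation,
    object@phaseOffset, object@nEdits, object@nPerfectRepeats))
})
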