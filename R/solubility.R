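# Sequence-based solubility prediction and construct assembly.
#
# The central predictor is mean residue hydropathy on an Urry-type scale
# (derived from elastin-like-polypeptide phase-transition temperatures,
# i.e. measured on disordered repeat proteins rather than globular ones),
# with an integer threshold separating insoluble from soluble tags. The
# classical Wilkinson-Harrison canonical-variable model is provided for
# comparison, along with composition and molecular-mass reports.

# Residues ordered from most hydrophobic to most hydrophilic by their
# Urry-type inverse-transition temperatures; ties broken by this fixed
# order. The packaged scale is a rank normalization of that ordering.
URRY_ORDER <- c("W", "Y", "F", "H", "P", "L", "I", "M", "V", "C",
                "A", "T", "S", "N", "G", "R", "Q", "K", "D", "E")

#' Urry-derived hydrophilicity scale
#'
#' Rank-normalized hydrophilicity index: residues are ranked from most
#' hydrophobic (W) to most hydrophilic (E) following the Urry
#' inverse-transition-temperature ordering for elastin-like polypeptides,
#' and assigned the value 5 * rank (range 5..100). Higher is more
#' hydrophilic. The scale is injectable everywhere: any named 20-residue
#' numeric vector can replace it.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
urryScale <- function() {
  setNames(5 * match(AA20, URRY_ORDER), AA20)
}

#' Assemble a SynIDP expression construct
#'
#' Leader + repeat region + tail (+ optional cargo). The default leader
#' MSKGP ends in proline, so the PGXXXX and GXXXXP phase forms of the
#' repeat unit produce identical assembled sequences; this identity is
#' asserted.
#'
#' @param unit hexapeptide repeat (e.g. "GQSGLP" or "PGQSGL") or a longer
#'   repeat unit whose length divides the repeat region.
#' @param n number of hexapeptide repeats (n >= 0).
#' @param leader N-terminal leader (default "MSKGP").
#' @param tail C-terminal tail (default "GENLYFQGHHHHHHG": tev protease
#'   site followed by a His6 purification tag).
#' @param cargo optional fused cargo sequence appended after the tail.
#' @return Amino-acid sequence of the construct.
#' @examples
#' nchar(assembleConstruct("GQSGLP", 24))  # 164
#' @export
assembleConstruct <- function(unit, n, leader = "MSKGP",
                              tail = "GENLYFQGHHHHHHG", cargo = "") {
  if (n < 0) stop("n must be >= 0")
  if (nchar(unit) %% 6L != 0L) stop("unit length must be a multiple of 6")
  reps <- n * 6L / nchar(unit)
  if (reps != floor(reps))
    stop("n hexapeptide repeats must tile the given unit exactly")
  region <- strrep(unit, reps)
  # phase equivalence when the leader ends in P and the unit ends in P:
  # leader + (GxxxxP)n == leader[-P] + (PGxxxx)n + P. Asserted.
  if (endsWith(leader, "P") && nchar(region) >= 6L &&
      startsWith(region, "G") && endsWith(region, "P")) {
    alt <- paste0(substr(leader, 1L, nchar(leader) - 1L),
                  rotateString(region, -1L), "P")
    stopifnot(identical(paste0(leader, region), alt))
  }
  paste0(leader, region, tail, cargo)
}

#' Mean residue hydropathy
#'
#' Arithmetic mean of per-residue scale values; order-invariant.
#'
#' @param seq amino-acid sequence.
#' @param scale named residue-value map (default [urryScale]).
#' @return Mean hydropathy score.
#' @export
meanHydropathy <- function(seq, scale = urryScale()) {
  if (nchar(seq) == 0L) stop("empty sequence")
  aa <- chars(seq)
  if (!all(aa %in% names(scale)))
    stop("residue not in scale: ",
         paste(setdiff(aa, names(scale)), collapse = ","))
  mean(scale[aa])
}

#' Smallest integer threshold separating two labeled score sets
#'
#' Returns the smallest integer t with every insoluble score strictly
#' below t and every soluble score strictly above t, or NA when the class
#' ranges overlap (no separating integer exists).
#'
#' @param scores numeric scores.
#' @param labels "soluble"/"insoluble" per score (or logical, TRUE =
#'   soluble).
#' @return Integer threshold or NA.
#' @examples
#' separationThreshold(c(40, 50), c("insoluble", "soluble"))  # 41
#' @export
separationThreshold <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "soluble", "insoluble")
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("soluble", "insoluble")))
  ins <- scores[labels == "insoluble"]
  sol <- scores[labels == "soluble"]
  if (length(ins) == 0L || length(sol) == 0L)
    stop("need at least one score per class")
  lo <- floor(max(ins)) + 1L         # smallest integer > all insoluble
  if (all(ins < lo) && all(sol > lo)) return(as.integer(lo))
  NA_integer_
}

#' Default solubility thresholds
#'
#' Integer mean-hydropathy thresholds for the standalone tag and for the
#' tag fused to a hydrophobic cargo (fusion context shifts the bar upward).
#'
#' @param standalone standalone threshold (default 42).
#' @param fusion fusion-context threshold (default 47).
#' @return list(standalone, fusion).
#' @export
solubilityThresholds <- function(standalone = 42L, fusion = 47L) {
  if (fusion < standalone) stop("fusion threshold must be >= standalone")
  list(standalone = standalone, fusion = fusion)
}

#' Classify a hydropathy score
#'
#' Soluble strictly above the context threshold, insoluble strictly below,
#' indeterminate exactly at it.
#'
#' @param score mean hydropathy score.
#' @param context "standalone" or "fusion".
#' @param thresholds see [solubilityThresholds].
#' @return "soluble", "insoluble" or "indeterminate".
#' @export
classifySolubility <- function(score, context = c("standalone", "fusion"),
                               thresholds = solubilityThresholds()) {
  context <- match.arg(context)
  t <- thresholds[[context]]
  if (score > t) "soluble" else if (score < t) "insoluble" else
    "indeterminate"
}

#' Wilkinson-Harrison solubility model
#'
#' Canonical variable CV = l1 * f(turn formers N,G,P,S) +
#' l2 * |mean residue charge - 0.03|; the protein is predicted insoluble
#' when CV - CV' > 0 (CV' = 1.71), and the probability of the predicted
#' class is the clipped polynomial 0.4934 + 0.276 |CV-CV'| -
#' 0.0392 (CV-CV')^2.
#'
#' @param seq amino-acid sequence.
#' @param lambda1,lambda2 model weights (defaults 15.43, -29.56).
#' @param chargeOffset charge offset (default 0.03).
#' @param cvPrime discriminant threshold (default 1.71).
#' @param includeH count histidine as half a positive charge (default
#'   FALSE, matching the cited calculator).
#' @return list(CV, discriminant, class, probability).
#' @examples
#' wilkinsonHarrison("AAKA")  # zero turn formers
#' @export
wilkinsonHarrison <- function(seq, lambda1 = 15.43, lambda2 = -29.56,
                              chargeOffset = 0.03, cvPrime = 1.71,
                              includeH = FALSE) {
  aa <- chars(seq)
  if (length(aa) == 0L) stop("empty sequence")
  if (!all(aa %in% AA20)) stop("non-standard residue")
  n <- length(aa)
  turn <- sum(aa %in% c("N", "G", "P", "S")) / n
  pos <- sum(aa %in% c("K", "R")) + if (includeH) 0.5 * sum(aa == "H") else 0
  neg <- sum(aa %in% c("D", "E"))
  charge <- (pos - neg) / n
  cv <- lambda1 * turn + lambda2 * abs(charge - chargeOffset)
  disc <- cv - cvPrime
  cls <- if (disc > 0) "insoluble" else "soluble"
  prob <- 0.4934 + 0.276 * abs(disc) - 0.0392 * disc^2
  prob <- min(max(prob, 0), 1)
  list(CV = cv, discriminant = disc, class = cls, probability = prob)
}

#' Composition report
#'
#' Fractions of proline, glycine, aromatics (F, Y, W) and positive residues
#' (K, R, optionally H), plus integer net charge at neutral pH
#' ((K + R) - (D + E)) and length.
#'
#' @param seq amino-acid sequence.
#' @param includeH count histidine among positive residues.
#' @return Named list of composition statistics.
#' @export
compositionReport <- function(seq, includeH = FALSE) {
  aa <- chars(seq)
  if (length(aa) == 0L) stop("empty sequence")
  n <- length(aa)
  posSet <- c("K", "R", if (includeH) "H")
  list(length = n,
       prolineFraction = sum(aa == "P") / n,
       glycineFraction = sum(aa == "G") / n,
       aromaticFraction = sum(aa %in% c("F", "Y", "W")) / n,
       positiveFraction = sum(aa %in% posSet) / n,
       netCharge = sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E")))
}

# Residue masses (Da): average and monoisotopic, plus one water per chain.
RESIDUE_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
RESIDUE_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
WATER_AVG <- 18.01528
WATER_MONO <- 18.010565

#' Molecular mass of a peptide
#'
#' Sum of residue masses plus one water.
#'
#' @param seq amino-acid sequence.
#' @param monoisotopic use monoisotopic masses (default FALSE: average).
#' @return Mass in Da.
#' @examples
#' averageMass("G")  # about 75.07
#' @export
averageMass <- function(seq, monoisotopic = FALSE) {
  aa <- chars(seq)
  tbl <- if (monoisotopic) RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  if (!all(aa %in% names(tbl)))
    stop("non-standard residue: ",
         paste(setdiff(aa, names(tbl)), collapse = ","))
  sum(tbl[aa]) + if (monoisotopic) WATER_MONO else WATER_AVG
}

#' Per-sequence solubility report table
#'
#' Convenience wrapper producing one row per sequence with hydropathy,
#' classification, Wilkinson-Harrison output, composition and mass.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param context classification context ("standalone" or "fusion").
#' @param scale hydropathy scale.
#' @param thresholds see [solubilityThresholds].
#' @return data.frame, one row per sequence.
#' @export
solubilityReport <- function(seqs, context = "standalone",
                             scale = urryScale(),
                             thresholds = solubilityThresholds()) {
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    h <- meanHydropathy(s, scale)
    wh <- wilkinsonHarrison(s)
    comp <- compositionReport(s)
    data.frame(id = names(seqs)[i] %||% paste0("seq", i),
               length = comp$length,
               hydropathy = h,
               class = classifySolubility(h, context, thresholds),
               whCV = wh$CV, whClass = wh$class,
               whProbability = wh$probability,
               prolineFraction = comp$prolineFraction,
               glycineFraction = comp$glycineFraction,
               aromaticFraction = comp$aromaticFraction,
               positiveFraction = comp$positiveFraction,
               netCharge = comp$netCharge,
               massDa = averageMass(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
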