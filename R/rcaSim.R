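# Rolling-circle amplification / methylation-protected digestion model.
#
# RCA around a circular 72-nt template produces a tandem concatemer with a
# SexAI site at every unit junction. Partial substitution of dCTP by
# 5-methyl-dCTP stochastically protects sites from cleavage, so digestion
# fragments come in multiples of 72 bp with a geometric length law.

#' Per-site protection probability
#'
#' A site is protected when any of its `cBlocking` relevant cytosines was
#' drawn as 5-methyl-dCTP: q = 1 - (1 - fMC)^cBlocking.
#'
#' @param fMC fraction of dCTP replaced by 5-methyl-dCTP, in [0, 1].
#' @param cBlocking cytosine positions per site whose methylation blocks
#'   cleavage (default 4).
#' @return Protection probability q in [0, 1].
#' @examples
#' protectionProbability(0.25, 4)  # 0.6836
#' @export
protectionProbability <- function(fMC, cBlocking = 4L) {
  if (any(fMC < 0 | fMC > 1)) stop("fMC must lie in [0, 1]")
  if (any(cBlocking < 0)) stop("cBlocking must be >= 0")
  1 - (1 - fMC)^cBlocking
}

#' Construct a ProtectionModel
#'
#' @inheritParams protectionProbability
#' @return A [ProtectionModel-class].
#' @export
ProtectionModel <- function(fMC = 0.25, cBlocking = 4L) {
  new("ProtectionModel", fMC = fMC, cBlocking = as.integer(cBlocking))
}

#' Simulate methylation-protected digestion of an RCA concatemer
#'
#' Builds a linear concatemer of `nUnits` repeat units, protects each of
#' the nUnits - 1 internal junction sites independently with probability q,
#' cuts at every unprotected site, and returns fragment lengths in bp. The
#' two terminal fragments of the linear product are flagged: they are
#' boundary artifacts outside the geometric law.
#'
#' @param nUnits number of repeat units in the concatemer (>= 1).
#' @param model a [ProtectionModel-class] (or a bare q via `q`).
#' @param seed integer seed.
#' @param unitLen repeat unit length in bp (default 72).
#' @param q optional explicit protection probability overriding `model`.
#' @param template optional [OligoDesign-class]; when supplied, fragment
#'   sequences are returned as well.
#' @return data.frame(lengthBp, units, terminal[, sequence]).
#' @examples
#' f <- simulateDigest(1000, ProtectionModel(0.25, 4), seed = 1)
#' mean(f$units[!f$terminal])      # about 1 / (1 - 0.6836)
#' @export
simulateDigest <- function(nUnits, model = ProtectionModel(), seed = 1L,
                           unitLen = 72L, q = NULL, template = NULL) {
  if (nUnits < 1L) stop("nUnits must be >= 1")
  nUnits <- as.integer(nUnits)
  unitLen <- as.integer(unitLen)
  if (is.null(q)) q <- protectionProbability(model@fMC, model@cBlocking)
  nSites <- nUnits - 1L
  protected <- if (nSites > 0L)
    withSeed(seed, runif(nSites) < q) else logical(0)
  cuts <- which(!protected)               # cut site i separates unit i, i+1
  bounds <- c(0L, cuts, nUnits)
  units <- diff(bounds)
  terminal <- rep(FALSE, length(units))
  terminal[1L] <- TRUE
  terminal[length(units)] <- TRUE
  out <- data.frame(lengthBp = units * unitLen, units = units,
                    terminal = terminal)
  if (!is.null(template)) {
    stopifnot(is(template, "OligoDesign"))
    out$sequence <- vapply(units, function(k)
      strrep(template@ntSeq, k), "")
  }
  out
}

#' Geometric fragment-length law
#'
#' P(L = k) = q^(k-1) (1 - q) for k = 1, 2, ...; mean 1/(1 - q).
#'
#' @param q per-site protection probability, 0 <= q < 1.
#' @param kMax largest k tabulated.
#' @return A [FragmentDistribution-class].
#' @export
fragmentLengthPmf <- function(q, kMax = 50L) {
  if (q < 0 || q >= 1)
    stop("q must lie in [0, 1); q = 1 leaves the concatemer uncut")
  k <- seq_len(kMax)
  new("FragmentDistribution", q = q, k = as.integer(k),
      pmf = q^(k - 1) * (1 - q))
}

#' Mean of the fragment-length law
#'
#' @param x a [FragmentDistribution-class] or bare q.
#' @return Mean fragment length in repeat units, 1/(1-q).
#' @export
meanFragmentUnits <- function(x) {
  q <- if (is(x, "FragmentDistribution")) x@q else x
  1 / (1 - q)
}

#' Gel size selection
#'
#' Retains fragments with lo <= length <= hi and reports number and mass
#' (bp-weighted) yield fractions.
#'
#' @param fragments fragment lengths in bp.
#' @param lo,hi selection window in bp (default 360-576, i.e. 5-8 repeat
#'   units of a 72-bp template).
#' @return list(retained, countFraction, massFraction).
#' @examples
#' sizeSelect(c(72, 360, 432, 576, 648))$retained
#' @export
sizeSelect <- function(fragments, lo = 360L, hi = 576L) {
  if (lo > hi) stop("lo must be <= hi")
  if (length(fragments) == 0L)
    return(list(retained = numeric(0), countFraction = 0, massFraction = 0))
  keep <- fragments >= lo & fragments <= hi
  list(retained = fragments[keep],
       countFraction = mean(keep),
       massFraction = sum(fragments[keep]) / sum(fragments))
}

#' Optimal protection probability for a size window
#'
#' The number fraction of fragments in the window [kLo, kHi] (repeat units)
#' is q^(kLo-1) - q^kHi. Setting the derivative to zero gives the closed
#' form q* = ((kLo-1)/kHi)^(1/(kHi-kLo+1)). For the 5-8 unit window this is
#' 2^(-1/4), retaining a quarter of all fragments.
#'
#' @param windowK integer window in repeat units, c(kLo, kHi); kHi may be
#'   Inf (degenerate: any q retains all mass, q* = 0 by convention).
#' @param cBlocking if given, also invert the protection model to report
#'   the methyl-dCTP fraction f achieving q*.
#' @return list(q, fraction, fMC).
#' @examples
#' optimizeProtection(c(5, 8))$q   # 2^(-1/4)
#' @export
optimizeProtection <- function(windowK = c(5L, 8L), cBlocking = NULL) {
  kLo <- windowK[1]; kHi <- windowK[2]
  if (kLo < 1 || kLo > kHi) stop("window must satisfy 1 <= kLo <= kHi")
  if (is.infinite(kHi)) {
    q <- 0
    frac <- if (kLo == 1) 1 else NA_real_
    if (kLo > 1) { # maximize q^(kLo-1): sup at q -> 1, degenerate
      q <- NA_real_; frac <- NA_real_
    }
  } else if (kLo == 1) {
    q <- 0                               # 1 - q^kHi maximal at q = 0
    frac <- 1
  } else {
    q <- ((kLo - 1) / kHi)^(1 / (kHi - kLo + 1))
    frac <- q^(kLo - 1) - q^kHi
  }
  fMC <- if (!is.null(cBlocking) && !is.na(q))
    1 - (1 - q)^(1 / cBlocking) else NA_real_
  list(q = q, fraction = frac, fMC = fMC)
}

#' Number fraction of fragments inside a repeat-unit window
#'
#' @param q protection probability.
#' @param windowK c(kLo, kHi) in repeat units.
#' @return q^(kLo-1) - q^kHi.
#' @export
windowNumberFraction <- function(q, windowK = c(5L, 8L)) {
  q^(windowK[1] - 1) - q^windowK[2]
}
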