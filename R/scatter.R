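# Polymer-chain small-angle scattering analysis.
#
# Analytic form factors for the three reference chain states (ideal random
# walk = Debye function, infinitely thin rigid rod, polymer excluded
# volume), a bead-chain ensemble simulator serving as an in-package Monte
# Carlo oracle, Kratky-plot classification, Porod-exponent estimation, PEV
# fitting, the TdT polymerization stoichiometry model, and the CD
# random-coil rule.

#' Construct a ScatteringProfile
#'
#' @param q scattering vector (1/Angstrom), strictly increasing, positive.
#' @param intensity intensities I(q).
#' @param sigma optional 1-sigma uncertainties.
#' @return A [ScatteringProfile-class].
#' @export
ScatteringProfile <- function(q, intensity, sigma = numeric(0)) {
  new("ScatteringProfile", q = as.numeric(q),
      intensity = as.numeric(intensity), sigma = as.numeric(sigma))
}

#' Debye form factor of an ideal random-walk chain
#'
#' I(q) = 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2; I -> 1 as q -> 0,
#' and the high-q log-log slope is -2 (Porod exponent 2).
#'
#' @param q scattering vector grid (1/Angstrom).
#' @param Rg radius of gyration (Angstrom).
#' @return A [ScatteringProfile-class].
#' @examples
#' intensity(debyeChain(1 / 42, 42))  # x = 1: 2/e
#' @export
debyeChain <- function(q, Rg) {
  if (Rg <= 0) stop("Rg must be positive")
  x <- (q * Rg)^2
  I <- ifelse(x < 1e-8, 1 - x / 3, 2 * (exp(-x) + x - 1) / x^2)
  ScatteringProfile(q, I)
}

#' Form factor of an infinitely thin rigid rod
#'
#' I(q) = 2 Si(qL)/(qL) - 4 sin^2(qL/2)/(qL)^2, with Si the sine integral;
#' I -> 1 as q -> 0 and the high-q envelope decays as 1/q (Porod
#' exponent 1).
#'
#' @param q scattering vector grid (1/Angstrom).
#' @param L rod length (Angstrom).
#' @return A [ScatteringProfile-class].
#' @export
rodFormFactor <- function(q, L) {
  if (L <= 0) stop("L must be positive")
  x <- q * L
  si <- vapply(x, pracma::Si, numeric(1))
  I <- ifelse(x < 1e-6, 1, 2 * si / x - 4 * sin(x / 2)^2 / x^2)
  ScatteringProfile(q, I)
}

#' Polymer-excluded-volume (PEV) form factor
#'
#' With U = q^2 Rg^2 (2 nu + 1)(2 nu + 2) / 6 and gamma the lower
#' incomplete gamma function,
#' I = gamma(1/(2 nu), U) / (nu U^(1/(2 nu))) -
#'     gamma(1/nu, U) / (nu U^(1/nu)),
#' then scale and background are applied. At nu = 1/2 this reduces
#' algebraically to the Debye function; the high-q slope is -1/nu.
#'
#' @param q scattering vector grid (1/Angstrom).
#' @param Rg radius of gyration (Angstrom).
#' @param nu Flory excluded-volume exponent, in (1/3, 1].
#' @param scale forward-scattering scale (default 1).
#' @param background flat background (default 0).
#' @return A [ScatteringProfile-class].
#' @export
pevIntensity <- function(q, Rg, nu, scale = 1, background = 0) {
  if (Rg <= 0) stop("Rg must be positive")
  if (nu <= 1 / 3 || nu > 1) stop("nu must lie in (1/3, 1]")
  U <- q^2 * Rg^2 * (2 * nu + 1) * (2 * nu + 2) / 6
  a1 <- 1 / (2 * nu); a2 <- 1 / nu
  lincg <- function(a, x) pgamma(x, a) * gamma(a)
  I <- ifelse(U < 1e-10, 1,
              lincg(a1, U) / (nu * U^a1) - lincg(a2, U) / (nu * U^a2))
  ScatteringProfile(q, scale * I + background)
}

#' Simulate scattering from a bead-chain ensemble
#'
#' Generates conformers (freely jointed random walk, which can cross
#' itself, or a rigid rod) and computes the orientation-averaged Debye sum
#' I(q) = (1/N^2) sum_ij sin(q r_ij)/(q r_ij), averaged over conformers.
#' Serves as the in-package Monte Carlo oracle for the analytic forms.
#'
#' @param model "random_walk" or "rigid_rod".
#' @param nBeads beads per chain.
#' @param bondLength bond length (Angstrom).
#' @param nConformers number of conformers (1 suffices for the rod).
#' @param q scattering vector grid.
#' @param seed integer seed.
#' @return list(profile = [ScatteringProfile-class], Rg = ensemble mean
#'   radius of gyration, contourLength).
#' @export
simulateChainScattering <- function(model = c("random_walk", "rigid_rod"),
                                    nBeads = 100L, bondLength = 3.8,
                                    nConformers = 100L, q, seed = 1L) {
  model <- match.arg(model)
  if (nConformers < 1L) stop("nConformers must be >= 1")
  if (model == "rigid_rod") nConformers <- 1L
  acc <- numeric(length(q))
  rg2 <- numeric(nConformers)
  withSeed(seed, {
    for (cf in seq_len(nConformers)) {
      coords <- if (model == "random_walk") {
        steps <- matrix(rnorm(3 * (nBeads - 1L)), ncol = 3)
        steps <- steps / sqrt(rowSums(steps^2)) * bondLength
        apply(rbind(0, steps), 2, cumsum)
      } else {
        cbind((seq_len(nBeads) - 1) * bondLength, 0, 0)
      }
      ctr <- sweep(coords, 2, colMeans(coords))
      rg2[cf] <- mean(rowSums(ctr^2))
      d <- as.numeric(dist(coords))
      for (k in seq_along(q)) {
        x <- q[k] * d
        acc[k] <- acc[k] + (nBeads + 2 * sum(sin(x) / x)) / nBeads^2
      }
    }
  })
  list(profile = ScatteringProfile(q, acc / nConformers),
       Rg = sqrt(mean(rg2)),
       contourLength = (nBeads - 1L) * bondLength)
}

#' Porod (mass-fractal) exponent from the mid-q slope
#'
#' Least-squares slope of log I versus log q over a q window; the Porod
#' exponent is its negative. Default window 0.03-0.2 1/Angstrom.
#'
#' @param profile a [ScatteringProfile-class].
#' @param window c(qMin, qMax) in 1/Angstrom.
#' @return list(exponent, stderr, n).
#' @export
porodExponent <- function(profile, window = c(0.03, 0.2)) {
  q <- profileQ(profile); I <- intensity(profile)
  keep <- q >= window[1] & q <= window[2] & I > 0
  if (sum(keep) < 5L) stop("need at least 5 points in the q window")
  fit <- lm(log(I[keep]) ~ log(q[keep]))
  sm <- suppressWarnings(summary(fit))   # exact power laws fit perfectly
  list(exponent = -unname(coef(fit)[2]),
       stderr = unname(sm$coefficients[2, 2]),
       n = sum(keep))
}

#' Fit the PEV model to a scattering profile
#'
#' Sigma-weighted least squares (unit weights when no uncertainties are
#' present) via Levenberg-Marquardt, with seeded Latin-hypercube
#' multistarts over the parameter bounds; mildly multimodal in (nu, Rg),
#' hence the restarts.
#'
#' @param profile a [ScatteringProfile-class].
#' @param init optional named start values (Rg, nu, scale, background).
#' @param lower,upper named bounds; defaults Rg in [5, 200] A, nu in
#'   (0.34, 1], scale in [1e-3, 1e3] relative to I(qmin), background in
#'   [0, 0.5 I(qmax)].
#' @param seed integer seed for the multistarts.
#' @param nStarts number of Latin-hypercube starts (default 8).
#' @return A [PEVFit-class]; `converged` is FALSE when no start converged.
#' @export
fitPev <- function(profile, init = NULL, lower = NULL, upper = NULL,
                   seed = 1L, nStarts = 8L) {
  q <- profileQ(profile); I <- intensity(profile)
  s <- sigmaUnc(profile)
  w <- if (length(s) && all(s > 0)) 1 / s else rep(1, length(q))
  i0 <- mean(head(I[order(q)], 3L))
  lo <- c(Rg = 5, nu = 0.34, scale = 1e-3 * i0, background = 0)
  hi <- c(Rg = 200, nu = 1, scale = 1e3 * i0,
          background = 0.5 * min(I[I > 0]))
  if (hi[["background"]] <= 0) hi[["background"]] <- 1e-6
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  resid <- function(p) {
    w * (pevIntensity(q, p[1], p[2], p[3], p[4])@intensity - I)
  }
  starts <- withSeed(seed, {
    u <- lhs::randomLHS(max(nStarts, 1L), 4)
    sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  })
  # data-driven start: Guinier estimate of Rg from the low-q points and
  # 1/(Porod slope) for nu from the top half-decade; anchors the search in
  # the physically sensible basin
  guin <- tryCatch({
    nlow <- max(8L, sum(q <= 1.3 * min(q)))
    sl <- coef(lm(log(I[seq_len(nlow)]) ~ I(q[seq_len(nlow)]^2)))[2]
    sqrt(max(-3 * sl, lo[["Rg"]]^2))
  }, error = function(e) 40)
  nu0 <- tryCatch({
    topw <- c(max(q) / 3, max(q))
    1 / porodExponent(ScatteringProfile(q, pmax(I, 1e-12)),
                      window = topw)$exponent
  }, error = function(e) 0.55)
  smart <- c(Rg = min(max(guin, lo[["Rg"]]), hi[["Rg"]]),
             nu = min(max(nu0, lo[["nu"]]), hi[["nu"]]),
             scale = i0, background = 0)
  starts <- rbind(smart, starts)
  if (!is.null(init)) {
    v <- smart
    v[names(init)] <- unlist(init)
    starts <- rbind(v, starts)
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[r, ], lo), hi),
                         lower = lo, upper = hi, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new("PEVFit", Rg = NA_real_, nu = NA_real_, scale = NA_real_,
               background = NA_real_,
               stderr = c(Rg = NA_real_, nu = NA_real_, scale = NA_real_,
                          background = NA_real_),
               converged = FALSE, rss = NA_real_))
  p <- best$fit$par
  se <- tryCatch(sqrt(diag(solve(best$fit$hessian)) * best$rss /
                        max(1L, length(q) - 4L)),
                 error = function(e) rep(NA_real_, 4))
  names(p) <- names(se) <- c("Rg", "nu", "scale", "background")
  conv <- best$fit$info %in% 1:4
  new("PEVFit", Rg = p[["Rg"]], nu = p[["nu"]], scale = p[["scale"]],
      background = p[["background"]], stderr = se,
      converged = conv, rss = best$rss)
}

#' Kratky-plot classification of a scattering profile
#'
#' Computes q^2 I(q). A compact (globular) chain shows a well-defined
#' interior maximum (peak exceeding the high-q tail by `peakRatio`); an
#' extended chain shows a sustained positive Kratky slope over the top
#' third of the q window; otherwise the profile is a flexible disordered
#' chain (Kratky plateau).
#'
#' @param profile a [ScatteringProfile-class].
#' @param peakRatio ratio defining a "well-defined maximum" (default 1.3).
#' @return "compact", "extended" or "flexible_disordered".
#' @export
kratkyClassify <- function(profile, peakRatio = 1.3) {
  q <- profileQ(profile); I <- intensity(profile)
  if (length(q) < 10L) stop("too few points to classify")
  k <- q^2 * I
  tail3 <- k[q >= q[1] + 2 / 3 * (q[length(q)] - q[1])]
  peakIdx <- which.max(k)
  interior <- peakIdx > 2L && peakIdx < length(k) - 2L &&
    q[peakIdx] < q[1] + 2 / 3 * (q[length(q)] - q[1])
  if (interior && max(k) > peakRatio * mean(tail3)) return("compact")
  topQ <- q >= q[1] + 2 / 3 * (q[length(q)] - q[1])
  slope <- coef(lm(k[topQ] ~ q[topQ]))[2]
  relRise <- slope * (max(q) - min(q)) / mean(k[topQ])
  if (relRise > 0.2) "extended" else "flexible_disordered"
}

#' TdT-catalyzed polymerization length model
#'
#' Template-free single-nucleotide additions distribute monomers over
#' initiators: mean degree of polymerization DP = ratio * conversion, the
#' length law is Poisson(DP) (memoryless additions), and the dispersity is
#' 1 + 1/DP.
#'
#' @param ratio monomer:initiator molar ratio (e.g. 500 for 1:500).
#' @param conversion fraction of monomer consumed, in [0, 1].
#' @param kMax largest length tabulated in the pmf (default DP + 6 sd).
#' @return list(meanDP, pmf = data.frame(k, p), dispersity).
#' @examples
#' tcepLengthModel(500, 1)$meanDP       # 500
#' tcepLengthModel(500, 1)$dispersity   # 1.002
#' @export
tcepLengthModel <- function(ratio, conversion = 1, kMax = NULL) {
  if (ratio < 0) stop("ratio must be >= 0")
  if (conversion < 0 || conversion > 1) stop("conversion must be in [0, 1]")
  dp <- ratio * conversion
  if (is.null(kMax))
    kMax <- if (dp > 0) ceiling(dp + 6 * sqrt(dp)) else 0L
  k <- 0:kMax
  list(meanDP = dp,
       pmf = data.frame(k = k, p = dpois(k, dp)),
       dispersity = if (dp > 0) 1 + 1 / dp else NA_real_)
}

#' Random-coil check for a CD spectrum
#'
#' TRUE iff the global minimum of the ellipticity is negative and falls in
#' 195-200 nm and a positive local maximum falls in 212-218 nm - the
#' canonical random-coil signature (negative peak near 197 nm, positive
#' peak near 215 nm).
#'
#' @param wavelength wavelengths (nm); must cover 190-260 nm.
#' @param ellipticity mean residue ellipticity values.
#' @return list(isRandomCoil, minimumNm, maximumNm).
#' @export
cdRandomCoilCheck <- function(wavelength, ellipticity) {
  stopifnot(length(wavelength) == length(ellipticity))
  if (min(wavelength) > 190 || max(wavelength) < 260)
    stop("spectrum must cover 190-260 nm")
  o <- order(wavelength)
  wl <- wavelength[o]; el <- ellipticity[o]
  iMin <- which.min(el)
  minOk <- el[iMin] < 0 && wl[iMin] >= 195 && wl[iMin] <= 200
  win <- which(wl >= 212 & wl <= 218)
  maxOk <- FALSE; maxNm <- NA_real_
  if (length(win)) {
    iMax <- win[which.max(el[win])]
    # positive local maximum within the window
    lo <- max(1L, iMax - 1L); hi <- min(length(el), iMax + 1L)
    maxOk <- el[iMax] > 0 && el[iMax] >= el[lo] && el[iMax] >= el[hi]
    if (maxOk) maxNm <- wl[iMax]
  }
  list(isRandomCoil = minOk && maxOk,
       minimumNm = wl[iMin], maximumNm = maxNm)
}

#' Read a 3-column scattering profile (q, I, sigma)
#'
#' Whitespace- or comma-separated text; lines starting with "#" ignored;
#' the third column is optional.
#'
#' @param file path.
#' @return A [ScatteringProfile-class].
#' @export
readScatteringProfile <- function(file) {
  txt <- readLines(file)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  sep <- if (any(grepl(",", txt, fixed = TRUE))) "," else ""
  d <- read.table(text = txt, sep = sep, header = FALSE)
  ScatteringProfile(d[[1]], d[[2]],
                    if (ncol(d) >= 3) d[[3]] else numeric(0))
}

#' Write a scattering profile as 3-column text
#'
#' @param profile a [ScatteringProfile-class].
#' @param file path.
#' @return Invisibly, the file path.
#' @export
writeScatteringProfile <- function(profile, file) {
  s <- sigmaUnc(profile)
  d <- data.frame(q = profileQ(profile), I = intensity(profile))
  if (length(s)) d$sigma <- s
  write.table(format(d, digits = 8, trim = TRUE), file,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
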