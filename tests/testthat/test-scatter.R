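qGrid <- function(lo = 0.012, hi = 0.6, n = 120)
  exp(seq(log(lo), log(hi), length.out = n))

test_that("Debye form factor: normalization, x = 1 value, high-q slope", {
  expect_equal(intensity(debyeChain(1e-6, 42)), 1, tolerance = 1e-6)
  # x = (q Rg)^2 = 1  ->  I = 2/e
  expect_equal(intensity(debyeChain(1 / 42, 42)), 2 * exp(-1),
               tolerance = 1e-12)
  prof <- debyeChain(qGrid(1e-3, 1, 400), 42)
  expect_true(all(intensity(prof) > 0))
  expect_error(debyeChain(0.1, -1), "positive")
})

test_that("rod form factor: normalization and quadrature oracle", {
  expect_equal(intensity(rodFormFactor(1e-7, 300)), 1, tolerance = 1e-6)
  # qL = pi, with Si computed by independent quadrature
  siPi <- integrate(function(t) sin(t) / t, 0, pi, rel.tol = 1e-12)$value
  want <- 2 * siPi / pi - 4 * sin(pi / 2)^2 / pi^2
  expect_equal(intensity(rodFormFactor(pi / 300, 300)), want,
               tolerance = 1e-10)
  expect_equal(round(want, 4), 0.7737)
})

test_that("PEV reduces to Debye at nu = 1/2 and has slope -1/nu", {
  q <- qGrid(1e-3, 1, 300)
  pev <- intensity(pevIntensity(q, 42, 0.5))
  deb <- intensity(debyeChain(q, 42))
  expect_lt(max(abs(pev - deb) / deb), 1e-6)
  # normalization with scale and background
  expect_equal(intensity(pevIntensity(1e-7, 42, 0.6, scale = 3,
                                      background = 0.25)), 3.25,
               tolerance = 1e-5)
  # numeric high-q slope approaches -1/nu
  for (nu in c(0.5, 0.6, 0.7)) {
    hi <- qGrid(6 / 42, 30 / 42, 100)
    m <- porodExponent(pevIntensity(hi, 42, nu),
                       window = range(hi))$exponent
    expect_lt(abs(m - 1 / nu), 0.1 / nu)
  }
  expect_error(pevIntensity(0.1, 42, 0.2), "nu")
  expect_error(pevIntensity(0.1, 42, 1.2), "nu")
})

test_that("two-bead ensemble matches the closed-form pair interference", {
  q <- seq(0.05, 2, length.out = 30)
  mc <- simulateChainScattering("rigid_rod", nBeads = 2, bondLength = 7,
                                nConformers = 1, q = q)
  want <- (1 + sin(q * 7) / (q * 7)) / 2
  expect_equal(intensity(mc$profile), want, tolerance = 1e-12)
})

test_that("random-walk ensemble scattering matches the Debye function", {
  q <- seq(0.01, 0.18, length.out = 20)
  mc <- simulateChainScattering("random_walk", nBeads = 100,
                                bondLength = 3.8, nConformers = 250,
                                q = q, seed = 6)
  deb <- intensity(debyeChain(q, mc$Rg))
  # qRg < 3 region, Monte-Carlo tolerance
  keep <- q * mc$Rg < 3
  expect_true(sum(keep) > 8)
  expect_lt(max(abs(intensity(mc$profile)[keep] - deb[keep]) /
                  deb[keep]), 0.05)
})

test_that("rigid-rod ensemble scattering matches the thin-rod form", {
  q <- seq(0.02, 1.5, length.out = 30)
  mc <- simulateChainScattering("rigid_rod", nBeads = 400, bondLength = 1,
                                nConformers = 1, q = q)
  rod <- intensity(rodFormFactor(q, mc$contourLength))
  expect_lt(max(abs(intensity(mc$profile) - rod) / rod), 0.02)
})

test_that("Porod exponent estimation on exact and asymptotic power laws", {
  q <- qGrid(0.01, 0.5, 200)
  p3 <- porodExponent(ScatteringProfile(q, q^-3), window = c(0.02, 0.4))
  expect_equal(p3$exponent, 3, tolerance = 1e-9)
  # ideal chain: rounds to 2 in the asymptotic window qRg in [4, 10]
  Rg <- 42
  deb <- debyeChain(qGrid(1e-3, 1, 600), Rg)
  m2 <- porodExponent(deb, window = c(4 / Rg, 10 / Rg))$exponent
  expect_identical(round(m2), 2)
  # thin rod: rounds to 1 in qL in [10, 60]
  L <- 300
  rod <- rodFormFactor(qGrid(1e-3, 1, 600), L)
  m1 <- porodExponent(rod, window = c(10 / L, 60 / L))$exponent
  expect_identical(round(m1), 1)
  expect_error(porodExponent(deb, window = c(2, 3)), "5 points")
})

test_that("PEV fitting recovers parameters from clean and noisy curves", {
  q <- qGrid()
  clean <- pevIntensity(q, 42, 0.588)
  f <- fitPev(clean, seed = 1)
  expect_true(f@converged)
  expect_lt(abs(pevRg(f) - 42) / 42, 1e-3)
  expect_lt(abs(pevNu(f) - 0.588), 1e-3)
  # 2% noise, a few seeds here (wider sweep in the acceptance suite)
  for (s in 1:3) {
    fx <- makeFixtures("scattering",
                       list(model = "pev", Rg = 42, nu = 0.55,
                            noise = 0.02), seed = s)
    fs <- fitPev(fx$profile, seed = s)
    expect_lt(abs(pevRg(fs) - 42) / 42, 0.10)
    expect_lt(abs(pevNu(fs) - 0.55), 0.05)
  }
  # internal consistency: fitted 1/nu against the mid-q Porod slope
  prof <- pevIntensity(qGrid(1e-3, 2, 500), 42, 0.6)
  fit <- fitPev(prof, seed = 2)
  m <- porodExponent(prof, window = c(6 / 42, 40 / 42))$exponent
  expect_lt(abs(m - 1 / pevNu(fit)) / (1 / pevNu(fit)), 0.1)
})

test_that("Kratky classification separates the three chain states", {
  q <- seq(0.012, 0.6, length.out = 150)
  expect_identical(kratkyClassify(debyeChain(q, 42)),
                   "flexible_disordered")
  expect_identical(kratkyClassify(rodFormFactor(q, 300)), "extended")
  x <- q * 30
  sphere <- ScatteringProfile(q, (3 * (sin(x) - x * cos(x)) / x^3)^2 +
                                1e-9)
  expect_identical(kratkyClassify(sphere), "compact")
  expect_error(kratkyClassify(ScatteringProfile(q[1:5], q[1:5])),
               "few points")
})

test_that("TdT polymerization stoichiometry model", {
  m <- tcepLengthModel(500, 1)
  expect_identical(m$meanDP, 500)
  expect_equal(m$dispersity, 1.002, tolerance = 1e-12)
  expect_equal(sum(m$pmf$p), 1, tolerance = 1e-6)
  # Poisson moment identity: Đ = 1 + 1/DP equals (var + mean^2)/mean^2
  k <- m$pmf$k; p <- m$pmf$p
  mu <- sum(k * p); v <- sum((k - mu)^2 * p)
  expect_equal(1 + 1 / mu, (v + mu^2) / mu^2, tolerance = 1e-4)
  z <- tcepLengthModel(500, 0)
  expect_identical(z$meanDP, 0)
  expect_identical(z$pmf$p[1], 1)
  expect_error(tcepLengthModel(-1), "ratio")
  expect_error(tcepLengthModel(10, 2), "conversion")
})

test_that("CD random-coil rule fires only on the coil signature", {
  fx <- makeFixtures("cd", list(kind2 = "coil"), seed = 1)
  got <- cdRandomCoilCheck(fx$spectrum$wavelength, fx$spectrum$ellipticity)
  expect_true(got$isRandomCoil)
  expect_true(got$minimumNm >= 195 && got$minimumNm <= 200)
  wl <- 190:260
  expect_false(cdRandomCoilCheck(wl, rep(0, length(wl)))$isRandomCoil)
  helix <- makeFixtures("cd", list(kind2 = "helix"), seed = 1)
  expect_false(cdRandomCoilCheck(helix$spectrum$wavelength,
                                 helix$spectrum$ellipticity)$isRandomCoil)
  expect_error(cdRandomCoilCheck(200:260, rep(0, 61)), "190-260")
})

test_that("scattering profiles round-trip through 3-column text", {
  q <- qGrid(n = 40)
  prof <- ScatteringProfile(q, intensity(debyeChain(q, 30)),
                            rep(0.01, 40))
  f <- tempfile(fileext = ".dat")
  writeScatteringProfile(prof, f)
  back <- readScatteringProfile(f)
  expect_equal(profileQ(back), profileQ(prof), tolerance = 1e-6)
  expect_equal(intensity(back), intensity(prof), tolerance = 1e-6)
  expect_equal(length(sigmaUnc(back)), 40L)
  expect_error(ScatteringProfile(c(2, 1), c(1, 1)), "increasing")
  expect_error(ScatteringProfile(c(0, 1), c(1, 1)), "positive")
})
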