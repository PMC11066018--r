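# SynIDPDesign

Computational pipeline for discovering **synthetic intrinsically
disordered protein (SynIDP) solubility tags** from pooled repeat-gene
libraries. SynIDPs are small (10–20 kDa) repeat polypeptides of the form
(PGX₁X₂X₃X₄)ₙ that lack secondary structure; fused to an
inclusion-body-prone protein, a well-chosen SynIDP keeps the fusion
soluble and active. This package implements every computational stage of
the discovery workflow, for protein engineers and synthetic biologists
building or analyzing such libraries:

1. **Motif design** — enumerate hexapeptide repeat motifs P-G-X₁X₂X₃X₄
   (X ∉ {P, C}, ≥1 glycine among the X's, X₄ ≠ G) up to permutation of
   the X residues. With the additional structural requirement that X₄
   own an A-ending codon — needed to complete the junction-split SexAI
   site — the full alphabet enumerates to exactly **1020 motifs**.
2. **Codon engineering** — reverse-translate each 24-residue unit into a
   72-nt oligo carrying exactly one SexAI site (ACCTGGT) split across
   the circular junction, with codons scrambled by seeded simulated
   annealing to minimize direct and inverted nucleotide repeats
   (hairpins are the failure mode of downstream enzymatic steps).
3. **RCA / digestion model** — rolling-circle amplification with a
   fraction f of dCTP replaced by 5-methyl-dCTP protects each SexAI site
   with probability q = 1 − (1 − f)ᶜ; digestion fragments then follow a
   geometric length law P(L = k) = q^(k−1)(1 − q) in 72-bp repeat units.
   Includes gel size selection (360–576 bp = 5–8 units) and the
   closed-form methyl-fraction optimum q\* = 2^(−1/4).
4. **Library QC** — a synthetic read generator plus exact circular
   alignment of reads against the tiled 72-nt references (both
   orientations, all 72 phases) and the verification filters: too
   short, poor alignment, nonsense, large frameshift, <3 perfect
   repeats.
5. **Solubility prediction** — mean residue hydropathy on an
   injectable Urry-type (elastin-derived) scale with integer separation
   thresholds, the Wilkinson–Harrison canonical-variable model,
   composition reports, and average/monoisotopic masses for assembled
   MSKGP-[repeat]ₙ-GENLYFQGHHHHHHG constructs.
6. **SAXS analysis** — Debye, thin-rod and polymer-excluded-volume (PEV)
   form factors, a Monte-Carlo bead-chain oracle, Kratky-plot
   classification, Porod-exponent estimation, and σ-weighted PEV fitting
   (radius of gyration R_g and Flory exponent ν; high-q slope −1/ν),
   plus the TdT polymerization stoichiometry model (mean DP = ratio ×
   conversion, Poisson lengths, dispersity 1 + 1/DP) and the CD
   random-coil rule.

## Worked example

```r
library(SynIDPDesign)

## 1. the design library
lib <- enumerateMotifs(MotifSpec())
lib
#> MotifLibrary with 1020 motifs over alphabet ADEFGHIKLMNQRSTVWY
#>   first: PGAAGA PGADGA PGAAGE ...

## 2. a 72-nt oligo for the PGQSGL motif
d <- reverseTranslateScrambled(buildRepeatUnit("PGQSGL", 4), seed = 7)
d
#> OligoDesign ( 72 nt ) encoding PGQSGLPGQSGLPGQSGLPGQSGL
#>    CCTGGTCAGTCAGGGTTGCCCGGGCAATCCGGGTTACCCGGCCAAAGCGGTCTGCCCGGTCAATCTGGCTTA
#>   repeat score: direct 7 nt, inverted 7 nt, composite 0

## 3. methylation-protected digestion at the protocol's 25% methyl-dCTP
q <- protectionProbability(0.25, 4)
c(q = q, meanUnits = meanFragmentUnits(q))
#>         q meanUnits
#> 0.6835938  3.160494
optimizeProtection(c(5, 8), cBlocking = 4)
#> $q        0.8408964   # 2^(-1/4): best per-site protection for 5-8 units
#> $fraction 0.25        # number fraction retained in the gel window
#> $fMC      0.3684322   # methyl-dCTP fraction achieving q*

## 4. solubility of the [GTHGTP]24 tag as an mTdT fusion
h <- meanHydropathy(strrep("GTHGTP", 24))
c(hydropathy = h)                       # 52.5 on the packaged Urry-type scale
classifySolubility(h, "fusion")         # "soluble"
averageMass(assembleConstruct("GTHGTP", 24))   # 15521.2 Da -- inside 10-20 kDa

## 5. chain state from scattering
qg <- exp(seq(log(1e-3), log(1), length.out = 600))
porodExponent(debyeChain(qg, 42), window = c(4/42, 10/42))$exponent
#> 1.944585   # rounds to 2: ideal random-walk chain
porodExponent(rodFormFactor(qg, 300), window = c(10/300, 60/300))$exponent
#> 0.9720938  # rounds to 1: rigid extended chain
```

The oligo begins with `CCTGGT` and ends in `A`: circularization joins
them into the single SexAI site, so every digestion product re-opens in
the same (GX₁X₂X₃X₄P)ₙ phase. The hydropathy score (higher = more
hydrophilic) is compared against integer thresholds — 42 for a
standalone tag, 47 upon fusion to a hydrophobic cargo.

A command-line front end with `design | rca | qc | predict | saxs |
run | fixtures` subcommands is installed at
`system.file("scripts", "synidp", package = "SynIDPDesign")`.

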