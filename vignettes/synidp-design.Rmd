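---
title: "Designing and verifying synthetic-IDP solubility tags"
author: "SynIDPDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying synthetic-IDP solubility tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynIDPDesign)
```

Synthetic intrinsically disordered proteins (SynIDPs) are small repeat
polypeptides with no secondary structure. Fused to an aggregation-prone
cargo, a well-chosen SynIDP acts as an entropic-bristle solubility tag.
This package implements the computational side of a discovery pipeline for
such tags: combinatorial design of P-G-X~4~ hexapeptide repeat motifs,
codon-level engineering of the repetitive genes, a stochastic model of
rolling-circle amplification (RCA) with methylation-controlled restriction
digestion, sequencing-based library verification, sequence-based
solubility prediction, and polymer small-angle-scattering (SAXS) analysis
of the purified tags.

# Motif design

A motif is the hexapeptide P-G-X~1~X~2~X~3~X~4~. Proline and cysteine are
excluded from the X positions (proline to keep the scaffold periodicity
unambiguous, cysteine because disulfides promote aggregation), glycine
must occur at least once among the X residues, and glycine is banned from
X~4~ so that no aggregation-prone G-P dipeptide forms across the repeat
boundary. Motifs are identified up to permutation of the X residues, so
the library is enumerated over residue *multisets*; each multiset is
realized as one canonical ordered motif (X~1~-X~3~ sorted ascending, X~4~
the largest admissible non-glycine residue), which makes
canonicalization deterministic and reversible.

One further constraint is easy to miss but has a large combinatorial
footprint. Each 72-nt oligo must carry exactly one SexAI recognition site
(ACCTGGT) overlapping the Pro-Gly codons, split across the circular
junction as ...A | CCTGGT. The leading A of the site is the third base of
the X~4~ codon, so X~4~ must own an A-ending codon in the standard
genetic code. Seven otherwise admissible residues (D, F, H, M, N, W, Y)
have none. Multisets whose non-glycine members all come from that set
cannot host the junction and are dropped. Under the full 18-residue
alphabet the count is then

```{r count}
nrow(motifTable(enumerateMotifs(MotifSpec())))
```

which is exactly the size of the design library; without the
junction-codon rule the naive admissible-multiset count is 1139. We treat
this derivation as the package's enumeration rule (it is switchable via
`requireJunctionCodon`, and an explicit `curationExcludes` list can
reconcile against an externally curated catalogue). Because of the same
constraint, `realizeMotif()` places the largest *junction-capable*
residue at X~4~ rather than merely the largest one.

Every enumerated unit has a proline fraction of exactly 1/6 and a glycine
fraction of at least 1/3, matching the composition regime of disordered
elastomeric repeat proteins.

# Codon engineering

`reverseTranslateScrambled()` maps a 24-residue unit to a 72-nt oligo.
Three codons are fixed: the leading Pro and Gly are CCT and GGT, and the
final X~4~ codon is its most frequent A-ending codon, so circularization
creates ACCTGGT exactly once at the junction. All other codons are drawn
from an E. coli K-12 usage table, restricted to synonymous codons with
relative usage at least 0.10 (the junction codons are exempt from the
cutoff, being structural).

Because the gene is highly repetitive, free codons are optimized by
seeded simulated annealing to minimize a repeat-structure score:
`w1 * max(0, direct - k0) + w2 * max(0, inverted - k0)` with defaults
`k0 = 8` nt, `w1 = 1`, `w2 = 2`. Direct repeats are the longest substring
occurring twice (overlaps allowed; a nonempty sequence scores at least 1
by convention); inverted repeats are the longest substring whose reverse
complement occurs disjointly (a hairpin variant requires a loop of at
least 3 nt). Hairpins weigh double because stem-loops are the dominant
failure mode of polymerase and ligase steps on repetitive templates. Any
internal ACCWGGT match (the degenerate SexAI pattern; self-reverse-
complementary under W, so one strand suffices) carries a large penalty,
and a design that cannot shed internal sites is rejected with a
diagnostic. The annealing is restarted up to four times from independent
seeded states; the optimizer never returns a design scoring worse than
the naive most-frequent-codon encoding.

Site positions are reported 1-based, the Bioconductor convention.

# RCA and methylation-protected digestion

RCA around a circularized 72-nt template yields a tandem concatemer with
a SexAI site at every unit junction. Substituting a fraction `fMC` of
dCTP with 5-methyl-dCTP protects a site whenever any of its `cBlocking`
dcm-context cytosines is methylated:

$$q = 1 - (1 - f_{mC})^{c}$$

The default `fMC = 0.25` follows the synthesis protocol (a 10% preset is
also provided, reflecting an alternative figure in the source record of
the protocol); `cBlocking = 4` counts the dcm-context cytosines on both
synthesized strands of CCWGG. Whether hemimethylation alone blocks
cleavage is not settled, so `cBlocking` is configurable. At the defaults,
q = 0.684 and the mean spacing between cuts is 3.2 repeat units, i.e.
roughly one protected site every four repeats.

With independent per-site protection, internal fragment lengths (in
repeat units) follow the geometric law P(L = k) = q^(k-1)(1-q), mean
1/(1-q). The two terminal fragments of a linear concatemer are flagged
and excluded from distributional comparisons: they are boundary
artifacts, not part of the geometric law. The simulator assumes fully
double-stranded product (single-stranded regions are not digestible by
the enzyme and are outside the model).

Gel selection keeps 360-576 bp, i.e. 5-8 repeat units. The number
fraction retained is q^4 - q^8, maximized in closed form at
q* = 2^(-1/4) = 0.841 (retaining exactly 25% of fragments), which maps
back through the protection law to fMC = 0.368 at `cBlocking = 4`. The
closed form is cross-checked against a grid search in the tests.

# Library verification from reads

Synthetic reads are substrings of concatemerized designs (default
concatemer: 8 units, the top of the gel window) with seeded
substitutions, single-base indels, and optional reverse-complement
orientation; ground truth is recorded in read names. The generator
emulates the *content* of a paired-end verification run, not its
technical artifacts: there is no quality model, no adapter or index
handling, no PhiX spike-in, and no polymerase or cloning bias. Passing
tests on these fixtures therefore demonstrates correctness of the
alignment and filtering logic, not robustness to instrument noise.

Each read is aligned against the infinitely tiled 72-nt unit in both
orientations with an exact semi-global edit-distance DP (the read aligned
end-to-end, the tiled reference free at both ends), which covers all 72
phase offsets at once; the tests verify the reported distance against an
independent full-DP oracle. Filters mirror the experimental pipeline:
reads fail when too short (< 100 nt), poorly aligned (> 0.10 edits/bp),
containing an in-frame stop in the repeat reading frame (nonsense), a
frame-disrupting indel region not restored within 24 nt (large
frameshift), or fewer than 3 perfect repeats — a perfect repeat being an
exact 72-nt unit copy, not a hexapeptide. The first two cutoffs are not
stated by the experimental protocol and are package defaults; all are
configurable. Note that with 250-nt reads, even a 0.5% error rate fails
most reads on the perfect-repeat rule (a single error destroys one of
the three available unit copies); this mirrors the heavy attrition seen
in real verification runs and is why the pipeline's recovery metric is
defined over *designs* recovered by passing reads, with per-read mapping
accuracy tracked separately.

# Solubility prediction

The primary score is mean residue hydropathy on an Urry-type scale,
derived from inverse phase-transition temperatures of elastin-like
polypeptides — i.e. measured on disordered repeat proteins rather than on
folded globular ones, which is what makes it appropriate for SynIDPs.
The published scale values are not reproduced here; the package ships a
rank-normalized index (residues ordered from tryptophan, most
hydrophobic, to glutamate, most hydrophilic; value = 5 x rank, range
5-100, ties broken by a fixed documented order). Any named 20-residue
vector can be injected instead. Consequently the package does not claim
the absolute thresholds of the original ranking; what it supports is the
*ordering* claim: `separationThreshold()` returns the smallest integer
strictly separating insoluble from soluble scores, or NA when the
classes overlap. Scores exactly at a threshold are classified
indeterminate, since the decision rule is strictly above/below. The
default thresholds (42 standalone, 47 upon fusion to a hydrophobic
cargo) are configurable integers.

The Wilkinson-Harrison canonical-variable model is included for
comparison: CV = 15.43 x (fraction of N, G, P, S) - 29.56 x |mean charge
- 0.03|, insoluble iff CV - 1.71 > 0, probability of the predicted class
0.4934 + 0.276|CV - CV'| - 0.0392(CV - CV')^2 clipped to [0, 1].
Histidine participates in charge optionally at half weight; the scored
region (tag alone versus whole construct) is the caller's choice. On
glycine/proline-rich repeat tags the turn-former term saturates and the
model calls nearly everything insoluble — the documented failure that
motivates the hydropathy ranking.

Constructs are assembled as leader (MSKGP) + repeat region + tail
(GENLYFQGHHHHHHG, a tev protease site plus His~6~); because the leader
ends in proline, the PGXXXX and GXXXXP phase forms of the repeat region
give identical constructs, and the assembler asserts this. Masses use
standard average or monoisotopic residue masses plus one water; net
charge at neutral pH is the integer count (K + R) - (D + E), with no pKa
model, matching the conventions of the calculators this module mirrors.

# Scattering analysis

Three analytic form factors cover the reference chain states: the Debye
function for an ideal random walk (high-q slope -2), the infinitely thin
rigid rod (slope -1), and the polymer-excluded-volume (PEV) form

$$I(q) = \frac{1}{\nu U^{1/2\nu}}\gamma(1/2\nu, U) -
         \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U),\quad
  U = \frac{q^2 R_g^2 (2\nu+1)(2\nu+2)}{6}$$

with lower incomplete gamma. Several equivalent PEV parameterizations
circulate; this one is pinned by the identity PEV(nu = 1/2) = Debye,
which the tests verify to below 1e-6 relative error, and by its high-q
slope of -1/nu.

`simulateChainScattering()` is the in-package Monte Carlo oracle: freely
jointed bead chains (or a rigid bead rod) scored with the
orientation-averaged Debye double sum. Random-walk ensembles match the
Debye function within Monte Carlo tolerance for qRg < 3; bead rods match
the thin-rod form within discretization error.

`porodExponent()` fits the log-log slope over a q window. The default
window is the mid-q range 0.03-0.2 1/Angstrom used when analyzing
measured profiles; for the analytic asymptotics the tests use qRg in
[4, 10] and qL in [10, 60] instead, because the default window mixes in
Guinier-regime curvature at these sizes (crossover bias).

`fitPev()` performs sigma-weighted Levenberg-Marquardt least squares.
The (Rg, nu) surface is mildly multimodal, so the fit starts from a
seeded Latin hypercube over the bounds plus one data-driven start
(Guinier estimate of Rg from the lowest-q points, 1/slope of the top
half-decade for nu); the data-driven start reliably lands in the
physical basin, and the best of all converged starts by residual sum of
squares is returned with 1-sigma uncertainties from the local Hessian.
On synthetic PEV curves with 2% multiplicative Gaussian noise over
q = 0.012-0.6 1/Angstrom, the fit recovers Rg within 10% and nu within
0.05 across seeds.

Kratky classification computes q^2 I(q): a compact chain shows an
interior maximum exceeding the high-q tail by a peak ratio of 1.3; an
extended chain shows a sustained positive Kratky slope over the top
third of the window (relative rise > 0.2); otherwise the profile is a
flexible disordered chain (plateau). Both thresholds are configurable;
they were chosen once to separate the three analytic reference shapes
and are not tuned per dataset.

The TdT-catalyzed polymerization (TcEP) model treats template-free
nucleotide addition as memoryless single additions, giving mean degree
of polymerization DP = ratio x conversion, a Poisson length law, and
dispersity 1 + 1/DP (1.002 at DP = 500). Poisson is a modeling choice —
the simplest law consistent with the narrow observed dispersity — not a
mechanistic claim. The CD random-coil rule is a window test: global
negative minimum in 195-200 nm plus a positive local maximum in
212-218 nm.

# Orchestration, seeds and problem sizes

`runPipeline()` chains the stages under one master seed fanned out into
per-stage substreams (stage seeds are affine functions of the master
seed, kept below 2^31), so a stage can be reproduced without re-running
its predecessors; every output file is checksummed into a manifest, and
identical configurations yield identical manifests. The packaged test
suite exercises the pipeline at deliberately desk-scale sizes chosen to
keep the full suite fast while leaving Monte Carlo margins comfortable:
4-6 motifs per demo library, 25-80 reads of 230-250 nt, concatemers of
10^3-10^5 units (3.5 x 10^5 for the distributional comparison, giving
about 10^5 internal fragments), 100-250 chain conformers, and 10-seed
sweeps for fit recovery. All of these scale up linearly if heavier runs
are wanted.

# Known limitations

* The enumeration reproduces the curated library size by derivation, but
  the original curated list itself is not shipped; `curationExcludes`
  exists precisely so a supplementary catalogue can be matched when
  available.
* The codon scrambler preserves the objective (minimal direct/inverted
  repeats under fixed junction codons) of the original scrambling
  algorithm, not its internals; scores are comparable, sequences are not
  expected to be identical.
* Per-oligo optimization only: no library-wide cross-member repeat
  minimization.
* The read simulator omits instrument artifacts (see above), and the
  aligner is exact rather than heuristic, so seed-and-extend quirks of
  production aligners are out of scope.
* The solubility thresholds are reproduced as *structure* (integer
  separation, standalone < fusion), not as absolute values, because the
  underlying scale normalization is not public.
* SAXS: no instrument smearing, buffer subtraction, or absolute
  calibration; the PEV model assumes chain flexibility and is not
  applicable to rigid rods (Porod exponent near 1), where only the
  Porod/Kratky route is meaningful.
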