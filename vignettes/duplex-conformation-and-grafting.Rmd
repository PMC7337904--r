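---
title: "Duplex conformation, 2'-OH grafting and RNA/DNA cleavage prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex conformation, 2'-OH grafting and RNA/DNA cleavage prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agraft)
```

## The scientific question

Most Type II restriction endonucleases cut double-stranded DNA only.  A
small minority also cleave RNA/DNA heteroduplexes, which is useful for RNA
biochemistry because a DNA "helper" strand then defines a sequence-specific
RNA cleavage site.  Hybrids are conformationally locked near the A-form, so
a structural argument explains which enzymes can accept them: the enzyme
must already bind its dsDNA target in an A-like conformation, and the 2'-OH
groups that distinguish an RNA strand from a DNA strand must fit into the
complex without steric conflicts that local adaptation cannot absorb.

`agraft` implements both halves of that argument as a reusable pipeline:

1. *Conformational classification* — base-pair step and helical parameters,
   Zp, sugar puckers, and groove geometry of the protein-bound duplex.
2. *In-silico 2'-OH grafting* — an O2' oxygen is added to each
   2'-deoxyribose, one at a time, and its van-der-Waals overlap with the
   protein and the rest of the nucleic acid is scored; enzyme-level scores
   are compared across an ensemble by Z-statistics, and a simple
   conjunction rule predicts cleavage competence.

## Geometry conventions

**Base frames.** Every base is assigned the standard reference frame by
least-squares superposition of an idealized base onto the observed ring
atoms (proper rotations only; mirror fits are rejected by construction).
A base-pair frame averages the two base frames after flipping the
complementary base about its x axis.  Frame fitting, and therefore every
downstream parameter, follows the standard-reference-frame/CEHS convention:
step parameters (shift, slide, rise, tilt, roll, twist) are computed in the
mid-step frame, helical parameters (x-displacement, inclination, tip,
helical rise and twist) from the local screw axis of the step.

**Zp and A/B classification.** Zp is the mean z coordinate of the two step
phosphates in the CEHS mid-step frame, each phosphate measured in its own
strand's frame.  On the package's ideal fiber duplexes Zp is ~2.5 for the
A-form and ~0.3 for the B-form; steps classify A when Zp >= 1.5 A and B
when Zp <= 0.5 A (both thresholds are exposed as arguments, and the
calibration requirement is that every ideal A step classifies A and every
ideal B step classifies B — satisfied for all ten distinct dinucleotide
step types).

**Sugar puckers.** Pseudorotation follows the Altona–Sundaralingam
formulation; conformers are labeled by 36-degree wedges, so C3'-endo covers
phases [0, 36) and C2'-endo [144, 180).

## The fiber generator (synthetic data)

Test structures are built by a fiber model: one nucleotide template per
base and form, placed by the helical symmetry

```
R_n = Rz(n * twist) Rx(inclination),   o_n = Rz(n * twist) (dx, 0, 0) + (0, 0, n * rise)
```

with the complementary strand flipped 180 degrees about the pair x axis.
The templates (`inst/extdata/templates/`) were solved once by linked-atom
least squares: sugar rings built at the form's target pseudorotation phase
(A: P = 16, B: P = 154 degrees, amplitude 38), glycosidic and backbone
torsions restrained to canonical A/B values, and the O3'(n)–P(n+1) bond
constrained to form under the helical symmetry.  The solved torsions come
out canonical (A: chi -155, gamma 48, delta 88, epsilon -159, zeta -79,
alpha -60; B: chi -110, gamma 39, delta 145, epsilon -136, zeta -166,
alpha -41 degrees) and the inter-residue O3'–P distance is 1.59–1.63 A.

Default helical parameters are standard fiber values: twist 32.7 deg /
rise 2.548 A (A-form) and 36.0 deg / 3.375 A (B-form).  The remaining two
parameters are not pinned by convention, so they were fixed once so that
the generator's ideal duplexes reproduce the reference values this package
is calibrated against (below): x-displacement -4.42 A with inclination
+19 deg (A) and +0.56 A with -6 deg (B), all inside the canonical fiber
ranges.  Intra-pair degrees of freedom (propeller, buckle) are zero; the
generator emulates idealized fiber geometry, not sequence-dependent
fine structure, crystal-packing distortions, or protein-induced bending.
Passing tests on generator output therefore validate the *conventions and
algebra* of the analysis stages and the *construction* of the grafting and
clash machinery; they do not by themselves demonstrate accuracy on
experimental coordinates, which carry all of those features.

RNA strands get an O2' atom and U for T.  `interpolate_conformation()`
blends helical parameters and template coordinates linearly between the B
(t = 0) and A (t = 1) endpoints, which reproduces the pure builds exactly
at the endpoints; it exists to provide monotone conformational paths for
property tests (Zp and groove depths change monotonically along it).
`place_probes()` constructs single-atom pseudo-protein probes on the
outward ray through a target sugar's would-be O2' position at distance
`r_O2' + r_probe - clash`, so the clash later reported for that graft
equals the requested value by construction — the oracle used to validate
the scoring stage to 1e-6 A.

## Calibrated operational definitions

Two quantities reported in the structural literature have no unique
operational definition, so this package fixes them by calibration on the
generator's ideal duplexes and records the choice in every report's
provenance block.

**Displacement from the helix axis.** Three candidates are computed per
base pair: |helical x-displacement|, the distance from the fitted global
helix axis to the base-pair frame origin, and the distance from that axis
to the C1'–C1' midpoint.  The reference values for ideal fiber models
(6.9 A for A-form, 1.9 A for B-form) are reproduced essentially exactly by
the C1'–C1' midpoint definition (6.899 / 1.919 A on the 11-mer used
throughout), while the other two return the x-displacement magnitude
instead (~4.4 / ~0.6 A).  The C1'-midpoint distance is therefore the
default, reported as the mean over interior base pairs.

**Groove depths.** The reference depths for ideal duplexes (minor 18.5 A
and major 15.2 A for A-form; 11.7 and 17.2 A for B-form) exceed textbook
conventions, which measure floor-to-rim within one groove.  Depth is
implemented here as the distance from the line joining two groove-flanking
phosphorus atoms (the rim chord) to the floor atom lying deepest (farthest
from the chord), without van-der-Waals correction; the chord offsets and
the floor-atom selection were calibrated per groove against the four
reference values.  The calibrated minor-groove rule reads the depth through
the duplex from a wide rim chord (strand offsets 4/5, floor = all heavy
atoms of the level and its two neighbors) and the major-groove rule
measures to the deepest nearby phosphorus (offsets 1/2).  Residuals on the
four reference values are 0.05, 0.24, 0.07 and 0.13 A.  The rule string is
persisted as `definition_id` on every groove profile.  Groove *widths* are
conventional: closest cross-strand P–P distance minus 5.8 A, which
reproduces the textbook B-form widths (5.4 / 11.9 A here vs 5.7 / 11.7 A).
Because the calibrated minor-depth chord spans four to five levels, depths
are only defined for interior levels; duplexes of ~16 base pairs or more
give a stable mid-duplex mean, and terminal levels are flagged undefined
rather than extrapolated.

## Grafting and clash scoring

`graft_o2prime()` places the O2' oxygen at 1.413 A from C2', completing
ideal tetrahedral geometry on the ribose face (trans to the base, the
natural ribo configuration), *without touching any existing atom* — the
pucker before and after is bit-identical.  Handedness is verified at the
C3' stereocenter by a signed volume whose sign is conformation-independent;
mirror-imaged sugars are rejected.  The hydroxyl hydrogen is not placed: a
rotatable proton would add an unconstrained degree of freedom, so clash
scoring uses the oxygen only.  Stripping the O2' from a generator RNA
nucleotide and regrafting recovers the original position to well under
0.15 A RMS for all four bases in both form templates.

Grafts are evaluated one at a time, so no artificial O2'–O2' contacts
arise.  A graft's clash against the model is `max(0, r_a + r_b - d)` per
partner atom (Bondi radii by default: C 1.70, N 1.55, O 1.52, P 1.80,
S 1.80, H 1.20 A), excluding atoms within two covalent bonds of O2' in the
same nucleotide (C2', C1', C3'), all hydrogens, waters and monoatomic
ions — bonded geometry is not a steric conflict, and solvent is
displaceable.  Both the maximum and the per-partner-atom cumulative overlap
are recorded, split into protein and nucleic partners, and strand-averaged
per base-pair position.  The neighbor search is a coordinate window of
4.8 A, wider than any possible contact (max radius sum 4.27 A), so it is
exactly equivalent to the exhaustive scan — asserted, not assumed, in the
test suite on randomized 5000-atom models.

Overlaps up to 1.1 A are treated as compensable by small adjustments of
protein and nucleic acid; the threshold is an argument everywhere it is
used.  On the package's naked ideal duplexes the largest grafted-O2'
overlap is ~0.6 A in the A-form (compensable) and well above the threshold
in the B-form, which is the structural reason RNA does not form B-type
duplexes.

## Enzyme scores, ensemble statistics, prediction

The enzyme-level score is the maximum per-graft clash over the recognition
site nucleotides of both strands (before strand averaging); the
`exclude_outermost` variant drops the first and last site pair, relevant
for enzymes whose conflicts are driven by the flanking pairs of the
target.  Ensemble Z-scores subtract the mean and divide by the sample
(n - 1) standard deviation — conservative for small ensembles; because the field
uses both sd conventions interchangeably, empirical ranks and the rank
probability r/(n + 1) are reported alongside the normal-theory one- and
two-sided tail probabilities to keep the choice auditable.  The cleavage prediction is the conjunction: at least half of
the recognition-site steps A-like AND site clash score at most 1.1 A; both
knobs are exposed.  The rule is deliberately simple and monotone, and it
is expected to over-predict occasionally (enzymes may fail to cleave
hybrids for reasons beyond binding-site geometry, e.g. blunt-end cutters
whose paired active sites cannot reposition); such cases are reported,
never suppressed.

## Numerical choices and degenerate inputs

* Superposition uses Kabsch with a determinant constraint; fewer than three
  points or collinear points raise a degenerate-fit error, mirror inputs
  return the best *proper* rotation.
* Coincident base-pair frames raise a degenerate-step error; planar sugar
  rings (amplitude ~0) raise an undefined-pucker error.
* Alternate conformations are reduced at parse time to the
  highest-occupancy conformer per atom (ties by altloc identifier); a
  specific altloc letter can be selected instead to analyze the
  conformer-resolved models separately and average their parameters, which
  is how multi-conformer crystal duplexes should be treated.
* Pairing requires a C1'–C1' distance of 10.4 +/- 1.5 A, at least one
  canonical Watson-Crick donor-acceptor contact under 3.5 A, anti-aligned
  base normals, and near-coincident base-frame origins (< 2.5 A); the last
  criterion resolves rare greedy mispairings between neighboring levels in
  strongly compressed duplexes.
* SASA uses Shrake-Rupley sampling with a deterministic golden-spiral point
  set (default 960 points, probe 1.4 A); doubling the point count changes
  results by < 0.5%.

## Problem sizes

The test-suite and acceptance computations run on 11- and 18-mer duplexes
(the 11-mer being the crystallization sequence of the specific complex the
method was developed around, GTAGGACCATC), randomized 5000-atom clash
models, and 1000-draw null simulations for p-value calibration — sizes
chosen so every property is exercised with comfortable margins on a
laptop-class single core.

## Known limitations

* The fiber generator is an idealized model: no propeller, buckle,
  sequence-dependent step variation, or protein-induced deformation.
* The groove-depth and displacement definitions are calibrated operational
  choices (see above), appropriate for comparisons made with this package's
  own conventions; values from other software follow other conventions.
* mmCIF support covers the atom_site/cell/symmetry categories needed here,
  not the full dictionary.
* The cleavage prediction is a geometric screen, not a kinetic model.
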