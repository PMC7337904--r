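# agraft

Structural analysis of protein–DNA complexes for RNA/DNA heteroduplex
cleavage prediction: duplex conformational classification (A-like vs
B-like), in-silico 2′-OH grafting with van-der-Waals clash scoring,
ensemble Z-statistics, and a fiber-model generator for ground-truth test
structures.

## The problem

RNA/DNA heteroduplexes adopt a near-A-form geometry, while hydrated dsDNA
prefers the B-form. A restriction endonuclease can therefore only cleave a
heteroduplex if (i) it already holds its dsDNA target in an A-like
conformation and (ii) the 2′-OH groups of an RNA strand would fit into the
complex without uncompensable steric conflict. `agraft` turns that argument
into a pipeline for structural biologists screening endonucleases (or any
protein–DNA complex) for hybrid-cleavage competence:

* **Conformation**: standard-reference-frame base-pair step parameters
  (CEHS mid-step convention), local helical parameters, Zp with per-step
  A/B/intermediate classification (A: Zp ≥ 1.5 Å; B: Zp ≤ 0.5 Å),
  Altona–Sundaralingam sugar puckers, groove width/depth profiles, and the
  mean base-pair displacement from the helix axis.
* **Grafting + clash**: an O2′ oxygen is placed on each 2′-deoxyribose
  (ideal tetrahedral geometry at C2′, correct ribo chirality, no existing
  atom moved), one at a time, and scored as
  `clash = max(0, r_a + r_b − d)` against protein and nucleic-acid atoms
  (Bondi radii). Per-nucleotide maximal and cumulative clashes are split by
  partner type and strand-averaged per position.
* **Statistics + prediction**: enzyme-level score = maximal site clash;
  ensemble Z-scores `z = (x − mean)/sd` (sample sd) with one-/two-sided
  normal tail probabilities and empirical ranks; predicted cleaver ⇔
  ≥ 50% A-like site steps AND site clash ≤ 1.1 Å (the compensable-overlap
  threshold).
* **Synthetic structures**: idealized A/B/intermediate and RNA/DNA-hybrid
  fiber duplexes with ground truth known by construction, plus probe atoms
  placed at exact, known clash distances — the oracles the test suite is
  built on.

## Worked example

```r
library(agraft)

# idealized A-form duplex of the 11-mer crystallization sequence
model  <- build_fiber_duplex("GTAGGACCATC", fiber_spec("A"))
report <- analyze_structure(model, site_pattern = "GGWCC",
                            enzyme_id = "ideal-A")
report
#> <enzyme_report> ideal-A
#>   duplex: 11 bp, sequence 5'-GTAGGACCATC-3'
#>   site GGWCC at 4-8: 4/4 steps A-like
#>   max site clash: 0.605 A (include_outermost)
#>   mean displacement from helix axis: 6.90 A
#>   predicted RNA/DNA cleaver: YES
```

All four recognition-site steps classify A-like, the base pairs sit 6.9 Å
from the helix axis (the A-form signature; an ideal B-form duplex gives
1.9 Å and 0/4 A-like steps), and the worst grafted 2′-OH overlap in the
site is 0.605 Å — below the 1.1 Å compensable threshold, so the duplex
geometry licenses RNA/DNA cleavage. A B-form build of the same sequence is
predicted a non-cleaver.

Ensemble comparison across enzymes:

```r
scores <- c(AvaII = 0.60, e1 = 1.9, e2 = 2.3, e3 = 1.7, e4 = 2.6)
analyze_ensemble(scores)$table   # z, p_one_sided, p_two_sided, rank
```

A command-line wrapper with verbs `generate`, `analyze`, `score-ensemble`,
`interface` and `shell` is installed at `inst/scripts/agraft-cli.R`.

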