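Package: agraft
Title: Duplex Conformation Analysis and In Silico 2'-Hydroxyl Grafting for
    Protein-Nucleic Acid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether a protein-bound DNA duplex is held in the
    A-like or B-like conformation and whether the complex could accommodate an
    RNA/DNA heteroduplex.  Reads PDB/mmCIF structures, pairs bases into
    duplexes, computes base-pair step and helical parameters (CEHS/standard
    reference frame conventions), Zp-based A/B step classification, sugar
    pseudorotation, and groove width/depth profiles.  Grafts 2'-hydroxyl
    oxygens onto 2'-deoxyriboses one at a time without perturbing the sugar,
    scores van-der-Waals clashes of the grafted atoms against protein and
    nucleic acid, aggregates per-enzyme maximal clash scores into ensemble
    Z-scores and tail probabilities, and predicts RNA/DNA heteroduplex
    cleavage competence.  Includes a fiber-model generator for idealized A-,
    B-, intermediate and RNA/DNA-hybrid duplexes with ground truth known by
    construction, plus solvent-accessible surface, buried-interface and
    metal-coordination utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
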