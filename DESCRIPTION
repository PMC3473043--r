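Package: msacoev
Title: Simulated Evolution of Multiple Sequence Alignments and
    Differential-Binary Coevolution Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evolves protein multiple sequence alignments in silico down a
    copy-tree with point mutations, forced covarion pairs and zone
    recombination, while keeping exact ground-truth bookkeeping of every
    co-segregating change (totCOV, mutCOV, covCOV and recCOV count
    matrices).  Implements a family of coevolution detectors built on a
    differential binary re-encoding of the alignment (dbZPX2, dgbZPX2,
    nbZPX2) together with local baselines (mutual information, OMES,
    average-product and ZPX2 corrections), and the evaluation machinery to
    score any detector against the recorded evolutionary history
    (cumulative covarion-recovery curves) or against a protein structure
    (top-L contact recall with sequence-separation filters, curve merging
    by shape-preserving interpolation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    pracma,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
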