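Package: interqa
Title: Interface-Emphasized Quality Assessment of Protein Complex Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring, ranking and selecting structural models of
    protein complexes with emphasis on the inter-chain interface. Computes
    tessellation-style inter-atomic contact areas by a convergent sampled
    power-diagram estimator, contact-area-difference (CAD) similarity scores
    (global, per-residue, interface and binding-site variants), CASP-style
    interface accuracy metrics (ICS/F1, IPS/Jaccard, QS-score accuracy
    categories), a contact-area statistical potential with global and
    inter-chain interface pseudo-energies, a learned per-residue quality
    predictor whose mean gives a global score, a tolerance-gated tournament
    ranker with interface-similarity clustering for diverse model selection,
    and a coaxial two-ring rigid-body docking enumerator. Includes a synthetic
    fixture generator (idealized helical dimers, cyclic rings, rigid-body
    decoy ensembles with known ground-truth interface similarity) so the whole
    pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: bio3d, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
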