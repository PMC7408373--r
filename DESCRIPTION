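Package: pbneq
Title: Protein Block Ensembles and the Neq Local Flexibility Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of intrinsically-disordered protein conformational
    ensembles in the frame of the protein blocks (PB) structural alphabet.
    Reads multi-model PDB ensembles, computes backbone phi/psi dihedrals,
    assigns one of the 16 PB prototypes to every residue of every model,
    derives the per-position Neq entropy index (equivalent number of protein
    blocks) and classifies positions along the rigid-flexible-disordered
    continuum. Parses per-residue disorder-prediction score tracks (DISOPRED3,
    PrDOS, IUPred2A, ANCHOR2 output dialects) and compares them against Neq
    profiles: Pearson correlations on continuous values, stratified mean
    scores, class-binned averages, two-state agreement decompositions and a
    prediction-rate sweep over Neq thresholds. A synthetic-ensemble generator
    with known per-position PB mixtures (hence known true Neq) and
    controlled-correlation score tracks makes every pipeline stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
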