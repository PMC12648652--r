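Package: focuslib
Title: Focused Combinatorial Library Enumeration, Docking and Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for reaction-based focused virtual screening around a
    pyrazinyl-sulfonamide scaffold. Loads and classifies reactive building
    blocks (amino-azines and aryl sulfonyl chlorides), exhaustively
    enumerates an N-sulfonylation combinatorial library with full
    provenance, expands products into pH-window protonation states and
    tautomers, embeds deterministic single conformers, docks them through a
    pluggable engine (AutoDock-Vina-compatible external backend or an exact
    mock scorer for testing), profiles typed protein-ligand contacts
    (hydrogen bonds, hydrophobic, halogen bonds, pi-stacking, salt bridges)
    with PLIP-like geometric rules, and triages hits by score, required
    contacts, motif frequency and fingerprint novelty. Also implements the
    downstream assay mathematics: displacement/inhibition normalisation,
    four-parameter logistic dose-response fitting, EC80 derivation and
    Cheng-Prusoff Ki conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    minpack.lm,
    jsonlite,
    digest,
    yaml,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (obabel on the PATH); AutoDock Vina
    (optional, only for the external docking engine)
Config/testthat/edition: 3
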