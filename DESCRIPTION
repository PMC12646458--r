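Package: abcscreen
Title: In Silico Pulldown Scoring and Characterization Analytics for ABC
    Transporter Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and characterizing partner complexes of
    Type VII ABC transporters. Scores predicted two-chain complexes by
    interface confidence (pDockQ) and a heavy-atom steric clashscore, ranks
    candidate libraries by Pareto dominance, converts inter-protein
    coevolution coupling matrices into Z-scored residue pairs and maps them
    onto structures, quantifies apo versus ATP-bound conformational changes
    through reporter distances and per-residue displacement fields, analyzes
    membrane trajectories for lipid headgroup residency, vertical extraction
    traces, residue contact propensity, RMSF and RMSD, and fits
    Michaelis-Menten kinetics from absorbance progress curves. A synthetic
    data generator plants known interface contacts, steric clashes,
    coevolving pairs, lipid occupancy schedules and kinetic parameters so
    that every analysis stage can be verified end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
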