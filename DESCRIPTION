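Package: xtalmerge
Title: Assembly of Partial Diffraction Datasets from Microcrystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling a complete X-ray diffraction dataset from
    many partial rotation wedges collected on microcrystals: unit-cell
    variation clustering with non-isomorphism rejection, iterative
    per-crystal scaling (multiplicative scale and isotropic B), symmetry-aware
    merging with standard quality statistics (R_merge, R_meas, R_pim, CC1/2,
    completeness, anomalous CC), a completeness-gated group selection step,
    and greedy iterative crystal-and-frame rejection that maximises a merged
    data-quality objective.  Includes a synthetic-wedge simulator with known
    ground truth for validating every stage, in-silico protease digestion
    utilities (cleavage-site fragment inventories with peptide masses), and
    light-weight PDB coordinate checks (chain counts, catalytic-site
    distances, disordered-region gaps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
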