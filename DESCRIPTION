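Package: hexcycle
Title: Conformational-Cycle Analysis of Hexameric Pilus Motor ATPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the catalytic cycle of hexameric
    PilT/VirB11-like motor ATPases (such as the Tad pilus motor CpaF) from
    multi-chain coordinate models. Reads and writes PDB and mmCIF files,
    applies a configurable domain scheme (3HB, NTD, CAD and their residue
    anchors), assigns active-site nucleotides, clusters chains into
    conformational groups, classifies arginine-finger rotamer states,
    constructs packing units, maps catalytic events between hexamer states by
    symmetry-axis superposition with a one-position chain-register shift,
    decomposes per-domain rigid-body rotations about the hexamer axis,
    measures pore-loop heights, and converts filament extension speeds into
    pilin-assembly and ATP-consumption rates. Ships a seeded synthetic
    hexamer generator with planted ground truth so the whole pipeline is
    testable without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
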