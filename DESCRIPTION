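Package: sahbnet
Title: Surface-Accessibility and Hydrogen-Bond Elastic Networks for
    Coarse-Grained Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds MARTINI-style coarse-grained elastic networks for
    proteins from atomistic structures. Detects backbone hydrogen bonds,
    computes per-residue relative solvent accessibility against extended
    pentapeptide reference values, maps residues to backbone and
    side-chain beads, and generates spring networks (hydrogen-bond,
    surface-accessibility, their merged SAHBNET form, and the ELNEDYN
    comparator) as GROMACS-compatible include topologies. Also provides
    network statistics, parameter sweeps, and a harmonic normal-mode
    flexibility proxy (per-bead RMSF) for desk-scale comparison of
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
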