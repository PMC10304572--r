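Package: dyeaggr
Title: Geometric Analysis of Cationic Dye Aggregation in Counterion Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for counterion-driven aggregation of cationic
    xanthene dyes (rhodamine B ethyl ester and relatives) in molecular
    trajectories. Classifies dye dimers as H, J or crossed-J from the mutual
    orientation of their xanthene long axes (transition-dipole proxies),
    detects pi-stacked pairs from lateral-offset and plane-distance criteria,
    and tracks aggregation through per-frame dimer counts, the sum of
    dye-dye center distances, contact-graph clusters and radial distribution
    functions. Also provides a rigid-dimer Coulomb plus Lennard-Jones
    potential-energy scanner with selective epsilon scaling of the xanthene
    atoms, a cosine-series dihedral refitting routine against reference
    torsional scans, and a seeded rigid-body Monte Carlo generator of
    synthetic aggregation trajectories with a counterion-attraction toggle.
    Reads and writes multi-frame PDB and extended XYZ trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    graphics,
    tools,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
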