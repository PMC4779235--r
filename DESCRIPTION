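Package: alertminer
Title: Automatic Derivation of Structural Alerts from Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines structural alerts (toxicophore-like substructures) from
    categorical (active/inactive) and continuous (e.g. pIC50) bioactivity data
    sets. Substructures are circular Morgan-style atom environments of
    user-chosen bond radii; enrichment of a substructure among active compounds
    is scored with a binomial upper-tail probability, and association with
    continuous activity with a normality-gated two-sample test (Student's t or
    Kolmogorov-Smirnov) plus a signed effect size. Also computes hashed and
    unhashed (keyed) circular fingerprints in binary and count format, projects
    new compounds onto a frozen training basis, renders substructures as SMILES,
    and depicts alerts highlighted within molecules. Includes a synthetic
    molecule-set generator with planted alert fragments for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    optparse,
    methods,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
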