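Package: confmotion
Title: Conformational Ensembles and Linear Motions from Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds protein conformational ensembles from mmCIF structure
    files: extracts polypeptide chains with explicit encoding of unresolved
    residues, clusters sequences at configurable identity and coverage
    levels, aligns each cluster, superimposes conformations onto a
    consensus-scored reference with optional position-wise uncertainty
    weights, and describes the observed variability as linear motions via
    principal component analysis of the Calpha coordinates. Also provides a
    kernel-PCA benchmark for generating unseen conformations, with
    leave-one-cluster-out cross-validation, convex-hull extrapolation
    scoring and interpolation trajectories between conformational states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
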