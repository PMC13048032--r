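Package: sscpe
Title: Structure- and Stability-Constrained Site-Specific Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the structural and stability effects of every point
    mutation of a protein from its native structure, using elastic-network
    linear response (Cartesian and torsional variants) and contact-based
    folding free energies with a random-energy-model misfolded ensemble.
    Converts the predicted effects into site-specific amino-acid stationary
    distributions and substitution models for phylogenetics (mean-field and
    wild-type stability models, RMSD and harmonic-energy structural models,
    and their combinations), with Halpern-Bruno fixation factors, flux
    matching against empirical exchangeability matrices, and ridge-regularized
    fitting of the selection parameters with a specific-heat criterion.
    Includes a small phylogenetic toolkit: Felsenstein pruning likelihood
    under per-site models, branch-length optimization, a regularized
    maximum-likelihood-and-minimum-evolution tree score, and branch-length
    tree comparison scores (K, K2, normalized Robinson-Foulds).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    phangorn,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
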