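Package: ChemProspector
Title: Closed-Loop Novelty Prospecting of Reaction Process Spaces from Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for autonomous exploration of chemical reaction process
    spaces guided by mass-spectral novelty. Scores electrospray-ionization
    mass spectra for serendipity against starting-material references using a
    two-part metric (top-peak divergence plus inverse-frequency-weighted
    counts of non-precursor peaks), directs successive experiment batches by
    Gaussian-process Bayesian optimization with a Matern-plus-white-noise
    kernel and a confidence-bound acquisition (with Latin hypercube
    initialization and uniform-random baselines), and deconvolutes the
    accumulated spectra into product-distribution archetypes by non-negative
    matrix factorization of binary peak barcodes, mapped back onto the
    process space by weighted kernel density estimation. Includes a synthetic
    ground-truth benchmark so the full score-suggest-simulate loop can be
    exercised without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'adduct.R'
    'barcode.R'
    'campaign.R'
    'density.R'
    'gp.R'
    'nmf.R'
    'novelty.R'
    'process-space.R'
    'spectra-io.R'
    'synthetic.R'
    'utils.R'
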