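Package: masSim
Title: Modelling and Simulation of Light-Directed Maskless DNA Microarray
    Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale model and simulator of light-directed maskless
    array synthesis (MAS) of DNA microarrays. Computes coherent and
    incoherent aerial images of digital-micromirror virtual masks
    (diffraction, global flare, back reflection, edge scattering) and
    contrast ratios; models photodeprotection kinetics, dose-response and
    coupling/capping efficiency estimation from labelled-intensity series;
    evaluates the closed-form correct-sequence yield as a function of dose,
    optical contrast and coupling efficiency, with the closed-form optimal
    photodeprotection dose; schedules base-deposition mask series from
    design sequences; runs stochastic per-site synthesis simulations that
    emit error-bearing oligonucleotide product sequences; and analyses
    products by global alignment to recover insertion/deletion statistics
    and the underlying synthesis parameters.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    minpack.lm,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'erroranalysis.R'
    'masSim-package.R'
    'maskgen.R'
    'maskio.R'
    'mc_sim.R'
    'optics.R'
    'photochem.R'
    'workbench.R'
    'yieldmodel.R'
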