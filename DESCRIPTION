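Package: sims34
Title: Dual-Isotope NanoSIMS Quantification of Ligand-Oligonucleotide Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for dual-isotope NanoSIMS imaging of
    ligand-antisense-oligonucleotide conjugates. Reads multi-plane multi-channel
    ion-count stacks, performs rigid drift correction and plane accumulation,
    computes excess-34S drug-signal maps against the natural 34S/32S abundance
    baseline and 127I ligand-signal maps normalised per label and to the 13C12C
    carbon background, bins images to fixed physical size, selects ligand
    regions of interest at a 3-sigma threshold, classifies them as coupled or
    decoupled conjugates by the sign of the excess-34S signal, fits linear
    label-concentration response curves with limit-of-detection estimation, and
    generates synthetic Poisson ion-count scenes with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
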