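Package: trdtrio
Title: Bayesian Transmission-Ratio-Distortion Scans in Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transmission ratio distortion (TRD) in large half-sib
    trio designs such as dairy-cattle pedigrees. Fits allelic (overall and
    parent-specific) and genotypic (additive plus dominance) distortion models
    to offspring genotype counts cross-classified by mating type, with
    flat-prior Bayesian inference by deterministic grid quadrature or
    Metropolis MCMC. Significance is assessed with Bayes factors against the
    point Mendelian null, model choice with the deviance information
    criterion, and inheritance patterns (sire/dam TRD, recessive lethality,
    heterosis excess or deficiency, homozygote advantage or disadvantage) are
    labelled from the selected model. Includes sliding-window biallelic
    haplotype recoding, empirical-null and data-quality filters,
    Gaussian-kernel smoothing of Bayes factors along the genome with
    core-region extraction, and a gene-drop simulator of half-sib trio data
    with known distortion mechanisms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
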