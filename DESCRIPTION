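Package: katadetect
Title: Detection and Visualization of Kataegis (Localized Hypermutation) from Somatic SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A light-weight toolkit for identifying and visualizing genomic
    localized hypermutation (kataegis) from somatic single-nucleotide variants.
    Reads VCF and MAF files, computes inter-mutational distances per
    chromosome, segments the log-scale distance profile with an exact
    penalized least-squares piecewise constant fitting (PCF) dynamic program,
    and calls kataegis foci by mutation-count and mean-distance thresholds
    (six or more mutations with mean inter-mutational distance at or below
    1000 bp). Includes rainfall, substitution-spectrum and nucleotide-content
    plots, a seed-controlled mutation simulator that plants (or deliberately
    avoids) kataegis foci with ground truth, and a sensitivity/specificity
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    data.table,
    grDevices,
    graphics,
    optparse,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
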