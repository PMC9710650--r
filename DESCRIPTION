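Package: lfqpipe
Title: Downstream Analysis Pipeline for Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imports MaxQuant-style proteinGroups intensity tables (raw, LFQ or
    iBAQ flavors), builds a hierarchical analysis design from sample names,
    applies detection thresholding via a sigmoidal required-fraction function
    and one of five normalization strategies, and runs a catalogue of quality
    control, exploratory and differential analyses (detection counts, Venn
    diagrams, PCA, intensity histograms, relative standard deviation, replicate
    and group scatter comparisons, rank plots, pathway and GO term analyses,
    and volcano plots with empirical-Bayes moderated t-statistics). Every
    analysis is written as a PDF figure together with a CSV file of the plotted
    data, and the complete run configuration is saved for reproducibility.
    Includes a synthetic proteinGroups generator with known ground truth for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
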