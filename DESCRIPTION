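Package: SASVtrace
Title: Shared Amplicon Sequence Variants as Tracers of Sinking-Particle Export
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing oceanic particle export with prokaryote 16S
    rRNA amplicon sequence variants (ASVs) shared between suspended
    water-column communities and sinking particles collected in sediment
    traps ("SASVs"). Implements SASV identification by exact sequence
    matching against monthly water-column climatologies (with
    adjacent-month interpolation), depth profiles of SASV relative
    abundance in both the water column and the traps, Martin-curve style
    power-law attenuation fits with R-squared, p-values and two-sigma
    confidence intervals, depth-zone ecotype classification from profile
    maxima with bimodal-retention rules, and detection of taxa enriched in
    deep traps during the summer export pulse via Welch's t-test. Includes
    a synthetic community generator with planted attenuation exponents,
    depth-zone ecotypes and seasonal copiotroph pulses so that every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Sequencing, TimeCourse, Regression
RoxygenNote: 7.3.3
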