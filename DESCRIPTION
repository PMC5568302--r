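Package: opsinadapt
Title: Population Genetics and Spectral Analysis of Opsin Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying depth-related adaptation of visual opsin genes
    in fish populations. Groups haplotypes into amino-acid allele classes,
    tabulates synonymous and nonsynonymous polymorphic sites, computes
    Nei-Gojobori synonymous/nonsynonymous distances, performs the
    Hudson-Kreitman-Aguade (HKA) polymorphism-divergence test between genomic
    regions, screens population differentiation with Hudson's FST, builds
    neighbor-joining allele trees with bootstrap support, and analyses visual
    pigment absorbance spectra, including lambda-max estimation, standard
    template construction, and estimation of the A1/A2 chromophore ratio by
    template mixture fitting. Coalescent-based and template-based simulators
    provide ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
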