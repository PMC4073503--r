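Package: segscan
Title: Bulk Segregant Analysis QTL Mapping for Yeast Fermentation Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) in haploid yeast
    F2 crosses by bulk segregant analysis of allele-specific microarray
    signals. Provides fermentation-curve phenotyping (cumulative CO2 from
    fermenter mass loss, sliding-window polynomial rate estimation, checkpoint
    phenotypes), quantitative-genetics summaries (broad-sense heritability,
    transgressive segregation, phenotype-ranked bulk selection), a full
    allele-frequency scan (per-block log-ratio centering, allelic differences,
    parental-anchor normalization, one-tailed parental probe selection,
    sliding-window t tests with Benjamini-Hochberg correction, and QTL region
    calling with direction of effect), and a synthetic-data generator that
    simulates meiosis under the Haldane map function, F2 segregant
    populations, planted QTL architectures, fermentation kinetics and pooled
    probe signals, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
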