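Package: csslmap
Title: Genotyping, Bin-Map Construction and QTL Mapping for Chromosome
    Segment Substitution Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for chromosome segment substitution line (CSSL)
    populations: simulation of backcross-derived CSSL libraries, graphical
    genotyping from sparse PCR marker panels (DD/DR/RR segment-length
    rule), high-throughput genotyping from low-coverage re-sequencing SNP
    observations by sliding-window origin calling with precise
    recombination-breakpoint placement, population coverage summaries,
    recombination bin-map construction, and QTL mapping of line-mean
    phenotypes by stepwise multiple linear regression on +1/-1 bin codes
    with F-based entry and stay thresholds and sequential partial R-squared
    decomposition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
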