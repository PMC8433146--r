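Package: minichrom
Title: Mini-Chromosome Stability and Copy-Number Analysis for Edited DT40 Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the mitotic stability of engineered
    mini-chromosomes in chicken DT40 cells and to genotype chromosome-edited
    strains from binned sequencing coverage. Provides a branching-process
    model of chromosome segregation (nondisjunction, anaphase-lag loss, and
    reporter silencing), seeded simulators for flow-cytometry time courses,
    limiting-dilution clone assays and whole-genome binned read counts, two
    estimators of the per-division chromosome loss rate with bootstrap
    confidence intervals, and a control-normalized read-depth pipeline that
    infers chromosome copy numbers, truncation breakpoints and
    mini-chromosome geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
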