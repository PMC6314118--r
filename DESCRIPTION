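Package: fadscan
Title: Specificity-Determining Position Analysis for Bifunctional Fatty Acid Desaturases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating and interpreting specificity-determining
    residues in membrane-bound fatty acid desaturases. Implements
    group-consensus classification of alignment columns into a four-category
    Venn scheme (conserved in the delta-12 group, the omega-3 group, or shared
    with a bifunctional query enzyme), paralog-divergence scanning,
    histidine-box motif detection and di-iron coordination-shell analysis of
    structural models, rule-based mutagenesis planning with canonical variant
    naming, GC-FAME phenotype quantification (activity per A600 and
    ALA/(ALA+LA) product ratios), and regiochemistry inference (v+3 versus
    omega-3 double-bond counting). A synthetic-data module generates grouped
    alignments with planted signal columns, toy metal-site structures, and
    peak tables with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
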