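Package: novfams
Title: Curation and Functional Annotation of Novel Prokaryotic Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying, curating and annotating novel gene
    families from catalogues of uncultivated prokaryotic genomes (MAGs and
    SAGs). Implements family-level candidacy filters (complete-gene and
    species counts, conserved alignment domains, purifying-selection
    screening with a Nei-Gojobori dN/dS estimator), species-overlap
    orthology calling on midpoint-rooted gene trees, a calibrated
    genomic-context ("guilt-by-association") KEGG pathway predictor based
    on synteny, functional relatedness, strand and distance conservation,
    clade coverage/specificity synapomorphy scans, taxonomic and ecological
    breadth summaries with mobility association, and stratified (van
    Elteren) Wilcoxon biomarker discovery with Benjamini-Hochberg FDR
    control. Ships a deterministic synthetic pangenome generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
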