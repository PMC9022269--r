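Package: l1promoter
Title: Monomer Census and Reporter Statistics for Mouse L1 Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates the monomeric promoters of mouse LINE-1 (L1)
    retrotransposons and analyses dual-luciferase reporter assays of their
    activity. Builds extended tandem-monomer query sequences from subfamily
    consensus promoter models, aligns candidate L1 loci with an affine-gap
    local aligner (or imports tabular alignment output), filters 3'-tether-
    truncated and chimeric loci, bins each locus by its 5'-truncation point
    into tether/monomer bins, computes fractional monomer counts, per-
    subfamily census tables, start-offset histograms, and the regression of
    average monomer number on subfamily age. A companion module implements
    firefly/Renilla normalization of reporter plates, construct summaries
    with standard errors, pooled-variance pairwise t-tests with Benjamini-
    Hochberg correction, relative-activity percentages, and plasmid-dose
    titration summaries. A synthetic-data generator produces loci with known
    truncation truth and plates with known promoter strengths, so the whole
    pipeline is testable without genome-scale inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    rtracklayer,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
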