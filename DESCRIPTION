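Package: metafold
Title: Cross-Study Meta-Integration of Transcriptome Fold Changes with
    Pathway Overrepresentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates differential-expression results from multiple
    transcriptome studies of the trabecular meshwork response to
    corticosteroids.  Combines per-study log2 fold changes and p-values
    into weighted cross-study summaries (weights are -log10 p), applies a
    measured-in-k-of-n filter, contrasts corticosteroid responders against
    nonresponders via pseudocounted fold changes of mean abundances, tests
    pathway overrepresentation with a finite-population Z-score and
    label-permutation p-values, and builds the shared-gene network that
    links differentially expressed genes to functional pathway clusters.
    Ships a synthetic multi-study data generator with planted pathway
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    limma,
    optparse,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
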