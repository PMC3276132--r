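Package: legumap
Title: Translational Genomics Toolkit for Comparative Legume Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a non-redundant Unigene set from transcript and EST
    sequences, finds best reciprocal homologs in an annotated target genome
    (predicted genes, transcript contigs and genomic pseudo-chromosomes,
    with a flanking-window rule for genomic hits), places unmapped genes in
    silico on a genetic map by interpolating between syntenic anchor
    markers, answers forward (sequence to map position) and reverse (locus
    to candidate genes) queries, and detects and exports synteny blocks.
    Includes a synthetic genome-pair simulator with known orthology,
    rearrangement and map-position ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
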