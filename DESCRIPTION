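Package: gsknet
Title: Building and Mining Genome-Scale Knowledge Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling genome-scale knowledge networks (GSKNs)
    from heterogeneous life-science data. Parses gene models (GFF3 +
    protein FASTA), ontologies (OBO), GO annotations (GAF), tabular
    genetics data (SNPs, QTLs, orthologs, protein domains) and publication
    records into typed, labelled, directed multigraphs; links the parsed
    networks by accession, name, sequence similarity (Smith-Waterman),
    genomic co-location and external2go cross-references; collapses
    equivalent concepts with full provenance tracking; mines abstracts for
    same-sentence gene-trait co-occurrences; and extracts gene-evidence
    subnetworks and shortest evidence paths for candidate-gene discovery.
    Includes a lossless XML exchange format, node-link JSON export,
    declarative reproducible workflows, a command-line interface and a
    deterministic synthetic-data generator with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
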