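Package: multika
Title: Multi-k De Novo Transcriptome Assembly Optimization and Annotation Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing de novo transcriptome assemblies built from
    multiple k-mer lengths. Computes standard assembly metrics (N50, N90,
    length-threshold contig counts, length-frequency distributions), per-contig
    read-mapping fold coverage, and KEGG-ortholog (KOI) set comparisons across
    single-k assemblies. Builds a non-redundant clustered assembly (CA) by
    greedy identity-threshold clustering of pooled multi-k contigs, quantifies
    functional annotations lost during redundancy removal, and recovers contigs
    carrying annotations present in single-k assemblies but missing from the
    CA. Includes a synthetic-data generator with recorded ground truth, an
    end-to-end workflow driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    Rsamtools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'multika-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'assembly-io.R'
    'clustering.R'
    'coverage.R'
    'koi.R'
    'metrics.R'
    'published-counts.R'
    'synthetic.R'
    'workflow.R'
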