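Package: derepool
Title: Decontamination, Pooling and Dereplication of Multi-Sample
    Transcriptome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A consolidation pipeline for redundant, contaminated
    multi-sample transcriptome collections. Samples are size-filtered,
    screened for foreign-phylum contamination with ribosomal protein
    markers, scored for pairwise cross-contamination by re-attributing raw
    reads across the pooled assembly, pooled by genus and
    cross-contamination relatedness, dereplicated with a greedy
    incremental clustering at 95 percent nucleotide identity, and finally
    screened again with a phylum-wise Tukey-fence outlier rule before a
    marker-recovery completeness report. A deterministic synthetic-data
    generator plants cross-contamination, foreign markers and
    near-duplicate sequences with full ground truth so every stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
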