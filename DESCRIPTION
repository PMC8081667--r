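Package: asmqc
Title: Genome Assembly Quality Evaluation and Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates and grades genome assemblies with the metric framework
    used by large vertebrate genome projects: continuity statistics (NGx, gaps
    per Gb), k-mer based consensus quality (QV), k-mer completeness and false
    duplication rates, genome profiling from k-mer histograms (size,
    heterozygosity, repeat content), read-depth analysis (collapsed repeats,
    reliable blocks, duplication candidates), coverage-cutoff purging of false
    duplications, trio hap-mer phasing metrics, and the compact x.y.P.Q.C
    quality notation with per-metric category assignment. Ships a seeded
    diploid genome, read and defect simulator so every metric can be tested
    against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
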