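Package: bilRscreen
Title: Discovery and Metagenomic Profiling of Gut-Microbial Bilirubin Reductase
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for discovering and profiling the
    gut-microbial bilirubin reductase gene bilR. Provides
    phenotype-guided comparative-genomics candidate screening over
    orthogroups, profile hidden Markov model construction and local
    Viterbi search with Gumbel E-value calibration, a four-part
    quality-control classifier for short and long BilR proteins
    (E-value, length, HGDR motif and Pfam domain-architecture filters),
    fluorescence-assay reducer calling, and per-metagenome bilR
    presence and cohort-prevalence profiling from shotgun reads
    (host-read subtraction, k-mer seed-and-extend mapping, counts per
    million and two-proportion testing). Ships synthetic-data
    generators with recorded ground truth so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Metagenomics, Microbiome, SequenceMatching, HiddenMarkovModel,
    Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'bilRscreen-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'config.R'
    'assay.R'
    'hmm.R'
    'classify.R'
    'io.R'
    'profiler.R'
    'screen.R'
    'simulate.R'
    'workflow.R'
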