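Package: tritax
Title: Three-Taxon Analysis of Partitioned DNA Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-taxon analysis (3TA) of multi-locus DNA
    supermatrices: assembly of partitioned supermatrices from per-locus
    alignments, construction of an operational outgroup as a majority-rule
    consensus sequence, Williams-Siebert binary (three-taxon-statement)
    encoding of polarized DNA characters, uniform-weight parsimony scoring
    and heuristic/exhaustive search on both conventional and statement
    matrices with ensemble consistency and retention indices and jackknife
    resampling, and Robinson-Foulds comparison utilities including strict
    and majority-rule consensus, the exact RF median consensus, and RF
    supertree combination of topologies on overlapping leaf sets. A
    synthetic-data generator (pure-birth trees, Jukes-Cantor sequence
    evolution, per-locus taxon dropout and gap injection) supports
    end-to-end testing of the whole workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape (>= 5.0),
    phangorn,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
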