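Package: fusefission
Title: Screening and Classification of Gene Fusion and Fission Protein
    Families in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Rosetta-stone screening pipeline that detects composite
    (fused) proteins and their split (unfused) counterparts from protein
    domain annotations and gene coordinates across a set of genomes.
    Candidate composite proteins carry two or more non-overlapping domain
    tokens; families are retained when a matching, genomically colocalized
    split protein set passes identity, E-value, coverage and overlap
    filters.  Composite proteins are grouped by global-alignment identity
    with an in-house Markov Clustering implementation, and each cluster is
    classified as a fusion or a fission event by a heuristic vote over
    split-set frequency, bacterial distribution, closed-genome
    presence/absence and KEGG Orthology model coverage.  A deterministic
    synthetic-genome generator with planted fusion, fission and
    technical-fission events makes the whole pipeline testable without
    external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
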