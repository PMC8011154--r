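Package: homologpolish
Title: Homolog-Guided Correction of Systematic Indel Errors in Draft Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polishes draft microbial genome assemblies by exploiting sequence
    conservation across closely related genomes rather than re-using the reads.
    Related genomes are retrieved by MinHash sketch screening, aligned onto the
    draft, and stacked into a homologous pileup. Every candidate indel locus is
    encoded as twelve engineered features (allele counts, homologous coverage,
    a one-hot homopolymer-length context and a paired-ambiguity code) and
    classified by a seven-class radial-basis-function support vector machine
    into systematic sequencing errors, which are corrected, versus inter-strain
    variation, which is retained. Includes Phred-Q assembly evaluation,
    coding/non-coding error partitioning, and a seeded synthetic-fixture
    generator producing truth genomes, related strains, error-injected drafts
    and exact ground-truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    jsonlite,
    stats,
    utils,
    methods,
    parallel,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
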