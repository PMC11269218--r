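Package: poolstrat
Title: Comparing Pooled and Individual Genotyping Strategies for Genebank
    Accessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to compare three sampling strategies for genotyping
    genebank accessions with reduced-representation SNP data: individually
    genotyped plants aggregated in silico, pooled-tissue sequencing with
    read-count allele frequencies, and a single random plant per accession.
    Implements DArT-style report readers, the quality-control filter cascade,
    the naive pool-seq allele-frequency estimator, allele frequency difference
    (AFD), modified Rogers distance (MRD), expected heterozygosity with and
    without monomorphic sites, private/fixed-allele counting with a
    quasi-Poisson analysis of deviance, principal coordinate analysis,
    complete-linkage clustering with locus-bootstrap node support, a
    cross-entropy NMF admixture estimator, and a synthetic DArTseq-style data
    generator with truth ledgers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    ape,
    car,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
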