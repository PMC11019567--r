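Package: hlapop
Title: Population Genetics Analyses for Highly Polymorphic Multi-Locus
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for population genetic analysis of highly
    polymorphic, multi-locus genotype data such as HLA typings. Reads
    plaintext population (.pop) files and INI configuration files
    (including custom allele-binning filters), and computes per-locus
    allele and genotype statistics, Hardy-Weinberg conformity tests
    (chi-square with rare-class lumping, and conditional exact tests by
    full enumeration or Monte Carlo), Ewens-Watterson homozygosity tests
    of neutrality under the Ewens sampling formula, EM estimates of
    multi-locus haplotype frequencies, and pairwise linkage
    disequilibrium including the multiallelic D', Wn and the asymmetric
    ALD measures with permutation significance tests. Results are
    written as machine-readable XML plus human-readable text reports,
    and per-population XML documents can be aggregated into
    cross-population tab-separated (TSV) meta-analysis tables. A
    synthetic-data generator with known ground truth supports
    validation end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
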