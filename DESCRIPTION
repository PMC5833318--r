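Package: mamut
Title: Mutation-Accumulation Assay Analysis for Haploid Microbial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing mutation-accumulation (MA)
    experiments in haploid bacteria. Identifies base-pair substitutions
    and indels from dual-aligner per-site read-count pileups with a
    consensus calling scheme, estimates per-site and per-genome mutation
    rates with standard errors, summarises the mutation spectrum
    (transition/transversion, A/T-ward bias, indel size classes, deletion
    bias), tests the genomic context of mutations (coding versus
    noncoding, expected nonsynonymous:synonymous ratio, replication
    terminus enrichment), detects clustered multinucleotide mutations and
    evaluates their Poisson-window expectation, and derives effective
    population size from silent-site diversity. Includes a synthetic-data
    generator with known ground truth for validating the caller and the
    rate estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
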