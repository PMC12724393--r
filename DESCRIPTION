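Package: mtaging
Title: Mitochondrial DNA Deletions, Heteroplasmy and Copy Number in Aging Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for somatic mitochondrial DNA variation in aging
    tissue cohorts profiled by whole-genome sequencing. Annotates large mtDNA
    deletions against the rCRS gene map (respiratory-chain complexes, tRNAs and
    mitochondrial-derived microproteins), computes coverage-normalised deletion
    burden metrics, quantifies the maximal perfect direct repeat at deletion
    junctions and how single-nucleotide alleles modulate repeat length,
    classifies homoplasmic and heteroplasmic variants, estimates mtDNA copy
    number from relative coverage, and provides the statistical models used for
    regional and age comparisons: exponential (log-linear) regression,
    rank-based (Wilcoxon-score) regression, Kruskal-Wallis with Dunn post hoc
    tests, Yates-corrected chi-squared tests and Bonferroni control for a
    mitochondrial genome-wide SNP:deletion association scan. A seeded synthetic
    cohort generator emulating a two-brain-region aging study supports
    end-to-end testing without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    GenomeInfoDb,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
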