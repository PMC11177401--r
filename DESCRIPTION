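Package: mitohet
Title: Mitochondrial Heteroplasmy and Copy-Number Analysis in Snail Matrilines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing SNP and length heteroplasmy of mitochondrial
    genomes in multigenerational matrilines, motivated by land-snail
    whole-genome resequencing studies. Calls heteroplasmic sites from
    per-site allele-count tables, filters multi-sample VCFs, estimates
    mtDNA-copies-per-nuclear-genome ratios from read fractions, measures
    repeat copy number from windowed read depth, tests for selection on
    heteroplasmic sites (codon-position chi-squared, McDonald-Kreitman,
    sliding-window nucleotide diversity), infers the maternal parent of
    offspring from parent-offspring heteroplasmy correlations, and derives a
    pedigree mutation-rate estimate. A forward simulator of a matriline with
    germline-bottleneck transmission, de novo mutation, selection against
    non-synonymous alleles and copy-number-coupled mutation intensity
    provides fully synthetic test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
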