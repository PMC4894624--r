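Package: pedscreen
Title: Family-Based Sequencing Analysis: Variant Prioritization, IBD
    Sharing and Pedigree Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing disease variants in family-based
    sequencing studies. Implements weighted allele-frequency estimation
    combining sample and external-population frequencies, three Mendelian
    disease-model identification strategies (multiplicative segregation
    scores under dominant and recessive models, a per-gene weighted-sum
    burden statistic with permutation p-values, and relaxed
    compound-heterozygosity filtering rules), identity-by-descent sharing
    statistics over a centimorgan grid with threshold-based region
    calling, genetic-map interpolation with informative/independent
    marker selection, and a gene-dropping pedigree simulator with a
    genotyping-error channel and ROC evaluation utilities. Reads and
    writes PLINK text PED/MAP files and Merlin-style pairwise IBD tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
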