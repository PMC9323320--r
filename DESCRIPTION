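Package: hiddenstr
Title: Hidden Microsatellite Mutations in Parent-Child Duos and Trios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how often single-step microsatellite (STR) mutations
    remain Mendelian-compatible ("hidden" or covert) in one-generation
    parent-child duos and parents-child trios, as a function of the marker's
    population allele-frequency distribution. Provides seedable Monte-Carlo
    simulation of familial genotype configurations carrying exactly one
    single-step mutation, an exact enumeration engine for the hidden-mutation
    probability, generators for mock allele-frequency shapes (constant,
    normal, bimodal), the correction R/(1 - h) that converts observed
    Mendelian-incompatibility rates into unbiased per-meiosis mutation-rate
    estimates, and comparison statistics (pairwise Fisher exact tests,
    dispersion summaries, heterozygosity regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
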