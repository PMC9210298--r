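Package: mpphmm
Title: Generic Hidden Markov Model for Genotype Reconstruction in
    Multiparent Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the founder-haplotype mosaic along chromosomes of
    multiparent-population (MPP) individuals from dense SNP genotypes, using
    an approximate hidden Markov model in which the population is treated as
    a set of inbred founders in proportions alpha followed by n generations
    of random mating. Provides closed-form two-point and transition
    probabilities, an error-tolerant emission model, forward-backward
    posterior reconstruction and Viterbi decoding, calibration of the
    effective number of generations by map expansion (closed form and by
    simulation), exact reference formulas for Collaborative Cross and
    Diversity Outbred mice, a meiosis-level population simulator, and
    readers/writers for the CSV/YAML file formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
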