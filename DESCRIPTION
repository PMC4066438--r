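Package: sporedrive
Title: Meiotic Drive and Chromosomal Rearrangement Genetics of Fission Yeast Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time simulation, exact enumeration and likelihood inference for
    transmission-ratio distortion in Schizosaccharomyces pombe x S. kambucha hybrid
    meiosis. Models the chromosome 1 inversion and the chromosome 2/3 reciprocal
    translocation that distinguish the two genomes, spore death from unbalanced or
    essential-gene-deficient chromosome complements, lethal aneuploidy, and
    trans-acting gamete ("spore") killers with carrier rescue. Provides a
    crossover-interference-free (Haldane) meiosis engine, an exact spore-class
    enumeration oracle for recombination-free crosses, descriptive statistics on
    spore genotype tables (viable spore yield, G-test transmission bias, Haldane map
    distances, aneuploids per meiosis), and multinomial maximum-likelihood estimation
    of killer strength and coarse killer position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
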