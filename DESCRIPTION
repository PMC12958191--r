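Package: apycore
Title: Core-Size Effects on Approximated GEBV Reliabilities in Single-Step
    GBLUP with the APY Inverse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how the size of the
    core group in the algorithm for proven and young (APY) sparse inverse of
    the genomic relationship matrix affects approximated reliabilities of
    genomic estimated breeding values in single-step genomic BLUP (ssGBLUP).
    Provides a multi-generation pedigree, gene-dropping genotype and additive
    animal-model phenotype simulator; pedigree (A, A22, A-inverse) and genomic
    (VanRaden) relationship matrices; SVD-based core sizing and nested random
    core selection; the APY block inverse; exact reliabilities from the
    inverse of the mixed model equations; a block-sparse reliability
    approximation driven by reverse-reliability pseudo-record weights with
    propagation to nongenotyped animals; a randomized matrix-multiplication
    (column-sampling) variant of the expensive products; and an orchestrated
    core-reduction experiment with N-core/F-core/R-core comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
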