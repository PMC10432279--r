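Package: pmrkin
Title: Kinship Classification and Pedigree Reconstruction for
    Low-Coverage Pseudo-Haploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise-mismatch-rate (PMR) relatedness estimation for
    low-coverage ancient-DNA data in pseudo-haploid representation:
    binomial posterior classification of relatedness degree,
    parent-offspring versus full-sibling discrimination from
    chromosome-windowed mismatch rates, constraint-based pedigree
    assembly from degree calls combined with genetic sex, age class and
    uniparentally inherited haplogroups, and downstream demographic and
    burial-spatial statistics (exact binomial sex-ratio intervals,
    occupation-duration arithmetic, grave-distance permutation tests,
    Mantel test, haplogroup diversity summaries). Includes a forward
    gene-dropping simulator of patrilineal, female-exogamous burial
    communities that produces EIGENSTRAT pseudo-haploid genotypes with
    per-site coverage and error, haplogroup transmission and
    lineage-clustered grave coordinates, together with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
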