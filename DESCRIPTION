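Package: forensnp
Title: Forensic DNA Intelligence from Genome-Wide SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An all-in-one inference stack for forensic DNA intelligence from
    genome-wide SNP genotype profiles. From a multi-sample genotype matrix over
    a marker panel annotated with chromosome class, the package infers genetic
    sex (two-pronged X-heterozygosity plus Y-marker evidence), categorical and
    quantitative continental biogeographic ancestry (reference PCA with
    nearest-centroid assignment, and supervised admixture proportions by EM),
    Y-chromosomal and mitochondrial haplogroup origin against a marker-annotated
    phylogeny, categorical eye and hair colour (multinomial logistic prediction
    models), and pairwise relatedness (identity-by-state sharing converted to a
    method-of-moments pi-hat with degree-of-relatedness classification). A
    synthetic-data module generates drifted reference populations under the
    Balding-Nichols model, admixed and related individuals, sexed
    sex-chromosome profiles, uniparental lineages, and degraded profiles, so
    that the whole stack is testable without any real chip data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
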