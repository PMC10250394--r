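Package: autozyg
Title: Runs-of-Homozygosity Based Consanguinity Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying consanguinity and endogamy from runs of
    homozygosity (ROH). Implements a block-inheritance simulator of autozygous
    segment distributions for offspring of related parents, a summary-likelihood
    classifier that assigns each individual a degree of parental relatedness
    from the number of long ROHs and the summed length of the ten longest,
    and an observed/expected rare-homozygote excess statistic stratified by
    minor allele frequency and inbreeding class. Includes genetic-map
    interpolation utilities, PLINK .hom readers, and a fully synthetic cohort
    generator (tracts, genotypes, ROH calls) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
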