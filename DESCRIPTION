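Package: pigdiv
Title: Genetic Diversity Analysis of Pig Populations from SNP-Chip and Pedigree Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for within- and between-population genetic
    diversity analysis of livestock SNP-array data. Reads PLINK ped/map and
    bed/bim/fam genotypes and multi-generation pedigrees; performs sample- and
    SNP-level quality control (call rate, heterozygosity outliers, duplicates,
    Hardy-Weinberg exact test, IBD-based pedigree checks, X-homozygosity sex
    checks); estimates inbreeding three ways (Wright's pedigree coefficient,
    runs-of-homozygosity F_ROH, SNP-by-SNP homozygosity F_SNP); detects runs of
    homozygosity and shared/consensus homozygous regions; computes pairwise
    linkage disequilibrium from unphased genotypes by two-locus EM, LD decay,
    between-population correlation of linkage phase, and historical effective
    population size via the Sved relationship. A forward Wright-Fisher
    simulator with recombination, recorded pedigree and founder-haplotype
    tracking provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
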