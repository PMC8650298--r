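Package: herdmix
Title: Sex-Biased Admixture Inference from Autosomal, X-Chromosomal and
    Uniparental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sex-biased admixture in structured
    populations, motivated by the East African pastoralist admixture into
    southern African Khoe-San groups. Implements genotype quality control
    (missingness, exact Hardy-Weinberg, strand-ambiguous marker removal,
    identity-by-state relatedness screening, LD pruning, panel merging and
    ancestral-allele polarization), maximum-likelihood ancestry-fraction
    estimation by EM under the standard admixture model with haploid male-X
    support, the X-chromosome/autosome ancestry-ratio procedure for
    detecting sex bias, admixture dating from local-ancestry tracts via
    pairwise coancestry curves with exponential-decay fitting, and
    mtDNA/Y-chromosome haplogroup ancestry tallies. A forward-time,
    sex-structured admixture simulator with recombination on a genetic map
    provides genotypes, true ancestry tracts and uniparental lineage labels
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
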