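Package: bisonpanel
Title: SNP Panel Design and Population-Genetic Evaluation for North American Bison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating reduced SNP genotyping panels
    for managed North American bison herds. Implements the marker-selection and
    quality-control cascade used to build a species-specific array (minor allele
    frequency, missingness, physical spacing, Hardy-Weinberg exact test, depth
    and call-rate filters), within- and among-population diversity statistics
    (observed and Nei's unbiased expected heterozygosity, rarefied allelic
    richness, individual inbreeding coefficients, FIS with bootstrap confidence
    intervals, Weir-Cockerham pairwise FST), genotype principal component
    analysis, duplicate detection and exclusion-based parentage assignment with
    non-exclusion probabilities, and rule-based mitochondrial species and clade
    assignment from diagnostic SNPs. Includes a herd simulator (Balding-Nichols
    population divergence, Mendelian pedigrees, genotyping error, missingness,
    mitochondrial haplotypes) so every stage can be exercised and validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
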