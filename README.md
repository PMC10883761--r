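# bisonpanel

Tools for building and evaluating reduced SNP genotyping panels for managed
North American bison (*Bison bison*) herds, and for turning panel genotypes
into the quantities herd managers act on: within-herd diversity, among-herd
differentiation, individual identity, parentage, and mitochondrial ancestry.

Plains and wood bison recovered from a severe 19th-century bottleneck
through a handful of founder herds, and most animals today live in small,
isolated, intensively managed populations. Routine genetic monitoring of
such herds needs a marker set that is cheap, consistent across labs, and
informative enough for individual identification and dam–calf verification —
a niche historically filled by microsatellites and increasingly by custom
SNP arrays. This package implements the full analysis chain around such an
array, from marker selection through population-genetic reporting, plus a
herd simulator so every stage can be validated against known truth.

## What it computes

* **Panel design / QC cascade** — candidate selection from whole-genome
  variants (MAF > 0.3, < 50% missingness, ≥ 1.2 Mbp spacing), chip-derived
  candidates (MAF > 0.1, complete data), sequencing-based validation
  filtering (MAF ≥ 0.1, Hardy–Weinberg exact *p* ≥ 0.005, mean depth > 10,
  < 15% missingness, sample call rate ≥ 50%), and production chip QC
  (90% call-rate bounds, duplicate removal, monomorphic removal), each
  stage returning an audit report that conserves locus counts.
* **Diversity statistics** — observed heterozygosity *H*<sub>O</sub>, Nei's
  unbiased gene diversity *H*<sub>S</sub> = n/(n−1) · (1 − p² − q² −
  H<sub>O</sub>/2n), individual inbreeding *F* by homozygosity excess,
  rarefied allelic richness A<sub>R</sub>, and *F*<sub>IS</sub> = 1 −
  ΣH<sub>O</sub>/ΣH<sub>S</sub> with a percentile bootstrap CI over loci.
* **Differentiation** — pairwise Weir–Cockerham (1984) θ as a ratio of sums
  of variance components across loci (a Nei/G<sub>ST</sub>-style variant is
  available behind a flag).
* **Structure** — genotype PCA with mean imputation, 2p̂ centring and
  √(2p̂q̂) scaling.
* **Identity & parentage** — pairwise discordance with a 1% duplicate
  threshold, per-locus and combined non-exclusion probabilities (identity,
  first parent, second parent, parent pair) by exact enumeration under HWE,
  and exclusion-based parentage assignment by opposing-homozygote counts
  with an error-tolerant threshold ⌈2εL⌉.
* **Mitochondrial assignment** — NUMT screening (loci heterozygous in
  ≥ 90% of samples removed), heterozygote-to-missing recoding, then
  rule-based species (≥ 5 of 10 diagnostic alleles, none of the alternative
  species) and clade (≥ 1 Clade I allele and no Clade II, or vice versa)
  calls.
* **Simulator** — Balding–Nichols population divergence, inbreeding-aware
  founder draws, Mendelian pedigrees, a symmetric genotyping-error model,
  missingness, and templated mitochondrial haplotypes, all with truth
  tables.

## Worked example

```r
library(bisonpanel)

cfg  <- sim_config(n_pops = 3, pop_sizes = c(60, 60, 60),
                   bn_F = c(0.02, 0.08, 0.15), n_loci = 300, seed = 11)
herd <- simulate_cohort(cfg)
herd$gm
#> <genotype_matrix> 180 samples x 300 loci
#>   missing calls: 2.05%; depth matrix: absent
#>   populations: pop1, pop2, pop3

clean <- chip_qc_filter(herd$gm)$gm
diversity_table(clean, n_boot = 200, seed = 1)
#>   population_id sample_size mean_ho mean_hs mean_f n_monomorphic mean_ar      fis
#> 1          pop1          60   0.377   0.386 0.0172             0       2  0.02385
#> 2          pop2          60   0.370   0.370 0.0345             0       2  0.00136
#> 3          pop3          60   0.329   0.335 0.1410             1       2  0.01684

round(fst_table(clean), 4)
#>        pop1   pop2   pop3
#> pop1     NA 0.0491 0.0686
#> pop2 0.0491     NA 0.1053
#> pop3 0.0686 0.1053     NA

combined_nonexclusion(compute_locus_qc(clean)$p_alt, "identity")$scientific
#> [1] "1.418E-101"

clade_table(assign_mtdna(herd$gm_mt, default_mt_panel()),
            herd$gm_mt$samples$population_id)
#>   population_id   n cladeI_pct cladeII_pct unassigned_pct
#> 1          pop1  60         88          12              0
#> 2          pop2  60          5          95              0
#> 3          pop3  60         90          10              0
#> 4         Total 180         61          39              0
```

Reading the output: the three simulated herds were generated with
increasing divergence parameters, and the pairwise θ matrix orders them
accordingly (pop2–pop3 most differentiated); `mean_f` tracks the drift-
induced homozygosity excess of the most diverged herd; the combined
identity non-exclusion probability of ~10⁻¹⁰¹ over 300 informative SNPs
means two distinct animals essentially never share a full panel genotype;
and the clade table recovers each herd's simulated mitochondrial mixture.

Real data enter through `read_vcf()` (autosomal + mitochondrial SNPs,
GT/DP), `read_final_report()` (Illumina-style final reports, GC-score
cutoff 0.95), and `read_sample_metadata()`.

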