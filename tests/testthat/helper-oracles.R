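# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Closed-form per-locus non-exclusion probabilities for a biallelic locus
# under HWE, derived once by symbolic enumeration over all parent/offspring/
# candidate genotype configurations and frozen here as polynomials in p.
ne_closed_form <- function(p, mode) {
  switch(mode,
    identity      = 6 * p^4 - 12 * p^3 + 10 * p^2 - 4 * p + 1,
    first_parent  = -2 * p^4 + 4 * p^3 - 2 * p^2 + 1,
    second_parent = p^4 - 2 * p^3 + 2 * p^2 - p + 1,
    parent_pair   = 6 * p^6 - 18 * p^5 + 23 * p^4 - 16 * p^3 + 7 * p^2 -
                    2 * p + 1,
    stop("unknown mode"))
}

# Brute-force HWE exact test: enumerate every genotype table with the
# observed allele counts, computing each table's absolute conditional
# probability from first principles (no recurrence, no shared code path).
hwe_brute_force <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_ref <- 2 * n_hom_ref + n_het
  n_alt <- 2 * n_hom_alt + n_het
  tab_prob <- function(hr, h, ha) {
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(ha) +
          h * log(2) +
          lfactorial(n_ref) + lfactorial(n_alt) - lfactorial(2 * n))
  }
  hets <- seq(min(n_ref, n_alt) %% 2, min(n_ref, n_alt), by = 2)
  probs <- vapply(hets, function(h) {
    hr <- (n_ref - h) / 2
    ha <- (n_alt - h) / 2
    tab_prob(hr, h, ha)
  }, numeric(1))
  obs <- probs[hets == n_het]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Large-sample (infinite-n) limit of the Weir-Cockerham two-population
# theta, evaluated directly on known population allele frequencies: the
# truth-frequency oracle for simulator-based recovery checks.
fst_truth_oracle <- function(p1, p2) {
  s2 <- (p1 - p2)^2 / 2
  pbar <- (p1 + p2) / 2
  sum(s2) / sum(pbar * (1 - pbar) + s2 / 2)
}

# small genotype_matrix from a dosage matrix, autosomal single chromosome
make_gm <- function(dos, pop = "p1", chrom = "chr1", pos = NULL,
                    depth = NULL, sample_ids = NULL) {
  dos <- as.matrix(dos)
  L <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  loci <- data.frame(locus_id = sprintf("L%d", seq_len(L)),
                     chrom = rep_len(chrom, L),
                     pos = pos, ref = rep_len("A", L), alt = rep_len("G", L),
                     source = rep_len("wgs", L), is_mito = rep_len(FALSE, L),
                     stringsAsFactors = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(dos)))
  samples <- data.frame(sample_id = sample_ids,
                        population_id = rep_len(pop, nrow(dos)),
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, loci, samples, depth = depth)
}
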