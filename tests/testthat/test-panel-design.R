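test_that("per-locus QC statistics follow their count arithmetic", {
  g <- make_gm(rbind(c(0L, 2L, 0L, 1L),
                     c(0L, 2L, NA, 1L),
                     c(1L, 2L, 0L, 1L),
                     c(0L, 2L, 0L, NA)))
  qc <- compute_locus_qc(g)
  expect_equal(qc$maf[1], 1 / 8)          # genotypes (0,0,1,0): p_alt = 1/8
  expect_equal(qc$maf[2], 0)
  expect_true(qc$monomorphic[2])
  expect_equal(qc$missing_frac[3], 0.25)
  expect_equal(qc$call_rate[3], 0.75)
  expect_equal(qc$missing_frac + qc$call_rate, rep(1, 4))
  # (0, 0, 1) example on three samples
  q2 <- compute_locus_qc(make_gm(cbind(c(0L, 0L, 1L))))
  expect_equal(q2$p_alt, 1 / 6)
  expect_equal(q2$maf, 1 / 6)
  expect_error(compute_locus_qc(make_gm(matrix(integer(0), 0, 0))), "empty")
})

test_that("mean depth is averaged over called cells only", {
  dos <- cbind(c(0L, NA, 1L))
  depth <- cbind(c(10L, 99L, 20L))
  qc <- compute_locus_qc(make_gm(dos, depth = depth))
  expect_equal(qc$mean_depth, 15)         # the 99 sits under a missing call
})

test_that("HWE exact test equals the brute-force enumeration oracle (n <= 20)", {
  for (n in 1:20) {
    for (n_het in 0:n) {
      for (n_hom_ref in 0:(n - n_het)) {
        n_hom_alt <- n - n_het - n_hom_ref
        expect_equal(hwe_exact_test(n_hom_ref, n_het, n_hom_alt),
                     hwe_brute_force(n_hom_ref, n_het, n_hom_alt),
                     tolerance = 1e-10,
                     label = sprintf("table (%d,%d,%d)", n_hom_ref, n_het,
                                     n_hom_alt))
      }
    }
  }
})

test_that("HWE exact test handles degenerate and modal tables", {
  expect_equal(hwe_exact_test(0, 0, 7), 1)   # monomorphic: only one table
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1)  # modal table under HWE
  expect_equal(hwe_exact_test(1, 0, 1), hwe_brute_force(1, 0, 1))
  # one-sided variants sum the stated tail
  expect_lt(hwe_exact_test(10, 0, 10, one_sided = "het_deficit"),
            hwe_exact_test(10, 0, 10, one_sided = "het_excess"))
})

test_that("distance thinning keeps the greedy left-to-right solution", {
  loci <- data.frame(locus_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(1L, 1000000L, 2500000L), stringsAsFactors = FALSE)
  expect_equal(thin_by_distance(loci, 1200000), c("a", "c"))
  # chromosomes are independent
  loci2 <- data.frame(locus_id = c("a", "b"), chrom = c("chr1", "chr2"),
                      pos = c(1L, 2L), stringsAsFactors = FALSE)
  expect_equal(thin_by_distance(loci2, 1200000), c("a", "b"))
  # vacuous constraint keeps everything
  expect_equal(thin_by_distance(loci, 0), c("a", "b", "c"))
  # unsorted input is a contract violation
  expect_error(thin_by_distance(loci[c(2, 1, 3), ], 100), "sorted")
})

test_that("thinned output satisfies the pairwise spacing bound exhaustively", {
  set.seed(31)
  loci <- data.frame(locus_id = sprintf("L%03d", 1:200),
                     chrom = sample(c("chr1", "chr2", "chr3"), 200, TRUE),
                     pos = sample.int(3e7, 200), stringsAsFactors = FALSE)
  loci <- loci[order(loci$chrom, loci$pos), ]
  kept <- thin_by_distance(loci, 1200000)
  kl <- loci[loci$locus_id %in% kept, ]
  for (ch in unique(kl$chrom)) {
    pos <- sort(kl$pos[kl$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 1200000))
  }
})

test_that("WGS candidate selection applies strict MAF/missingness bounds then spacing", {
  dos <- cbind(c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),  # maf exactly 0.3
               c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 2L, 2L),  # good, pos 1.0e6
               c(1L, 1L, 1L, 1L, 0L, 0L, 2L, 2L, 0L, 1L),  # good, pos 2.0e6
               c(0L, 1L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 1L),  # good, pos 2.3e6
               c(NA, NA, NA, NA, NA, 1L, 1L, 1L, 0L, 2L))  # missing = 0.5
  g <- make_gm(dos, pos = c(1L, 1000000L, 2000000L, 2300000L, 6000000L))
  qc <- compute_locus_qc(g)
  expect_equal(qc$maf[1], 0.3)
  expect_equal(qc$missing_frac[5], 0.5)
  rep_ <- select_wgs_candidates(qc, g$loci)
  # maf exactly 0.3 and missingness exactly 0.5 fall on the dropped side
  expect_equal(rep_$dropped$reason[rep_$dropped$locus_id == "L1"], "low_maf")
  expect_equal(rep_$dropped$reason[rep_$dropped$locus_id == "L5"],
               "high_missing")
  # survivors L2 (1.0e6), L3 (2.0e6), L4 (2.3e6): greedy keeps L2 then L4
  expect_equal(rep_$kept, c("L2", "L4"))
  expect_equal(rep_$dropped$reason[rep_$dropped$locus_id == "L3"], "spacing")
  expect_equal(rep_$n_in, rep_$n_out + nrow(rep_$dropped))
})

test_that("chip candidate selection requires MAF > 0.1 and zero missingness", {
  dos <- cbind(c(rep(0L, 8), 1L, 1L),      # maf 0.1 exactly -> dropped
               c(rep(0L, 7), 1L, 1L, NA),  # one missing call -> dropped
               c(rep(0L, 5), rep(1L, 5)))  # maf 0.25, complete -> kept
  qc <- compute_locus_qc(make_gm(dos))
  expect_equal(qc$maf[1], 0.1)
  rep_ <- select_chip_candidates(qc)
  expect_equal(rep_$kept, "L3")
  expect_setequal(rep_$dropped$reason, c("low_maf", "missing_data"))
})

test_that("GBS validation filter enforces its boundaries and sample pre-filter", {
  set.seed(32)
  n <- 40
  dos <- matrix(sample(c(0L, 1L, 2L), n * 5, TRUE, prob = c(.36, .48, .16)),
                n, 5)
  depth <- matrix(30L, n, 5)
  # locus 2: mean depth exactly 10 -> dropped (strict >)
  depth[, 2] <- 10L
  # locus 3: missingness 20% >= 15% -> dropped
  dos[1:8, 3] <- NA
  # locus 4: monomorphic -> maf below 0.1
  dos[, 4] <- 0L
  # sample 1: called at fewer than half the loci -> removed first
  dos[1, c(1, 2, 4)] <- NA
  g <- make_gm(dos, depth = depth)
  out <- gbs_validation_filter(g)
  expect_equal(out$removed_samples, "S1")
  reasons <- out$report$dropped
  expect_equal(reasons$reason[reasons$locus_id == "L2"], "low_depth")
  expect_equal(reasons$reason[reasons$locus_id == "L3"], "high_missing")
  expect_equal(reasons$reason[reasons$locus_id == "L4"], "low_maf")
  expect_true(all(c("L1", "L5") %in% out$report$kept))
  expect_equal(out$report$n_in, out$report$n_out + nrow(reasons))
  # a locus at HWE p just below the threshold is dropped
  dos2 <- cbind(c(rep(0L, 20), rep(2L, 20)))   # extreme het deficit
  g2 <- make_gm(dos2, depth = matrix(30L, 40, 1))
  expect_lt(compute_locus_qc(g2)$hwe_p, 0.005)
  out2 <- gbs_validation_filter(g2)
  expect_equal(out2$report$dropped$reason, "hwe_fail")
  # depth is mandatory for this filter
  expect_error(gbs_validation_filter(make_gm(dos)), "depth")
})

test_that("chip QC filter removes low-call-rate members, duplicates and monomorphics", {
  set.seed(33)
  n <- 20; L <- 100
  dos <- matrix(sample(c(0L, 1L, 2L), n * L, TRUE), n, L)
  dos[1, 1:12] <- NA                       # sample call rate 88% < 90%
  dos[, 1] <- 1L; dos[1, 1] <- NA          # keep locus 1 polymorphic
  dos[, 2] <- 0L                           # monomorphic locus
  dos[3:20, 3] <- NA                       # locus call rate too low
  dos[4, ] <- dos[3, ]                     # duplicate pair S3/S4
  g <- make_gm(dos)
  dup <- data.frame(id1 = "S3", id2 = "S4", stringsAsFactors = FALSE)
  out <- chip_qc_filter(g, duplicates = dup)
  expect_true("S1" %in% out$removed_samples$sample_id)
  expect_equal(out$removed_samples$reason[out$removed_samples$sample_id == "S1"],
               "low_call_rate")
  # duplicate survivor: equal call rates, lexicographic tie-break keeps S3
  expect_true("S4" %in% out$removed_samples$sample_id)
  expect_false("S4" %in% out$gm$samples$sample_id)
  expect_false("L2" %in% out$gm$loci$locus_id)   # monomorphic removed
  expect_false("L3" %in% out$gm$loci$locus_id)   # low call rate removed
  # no locus in the cleaned matrix is all-missing
  expect_true(all(colSums(!is.na(out$gm$dosage)) > 0))
  for (r in out$reports) expect_equal(r$n_in, r$n_out + nrow(r$dropped))
})

test_that("on a clean well-powered cohort the cascade only loses spacing casualties", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 120, bn_F = 0, n_loci = 300,
                    ancestral_freq_range = c(0.35, 0.5),
                    error_rate = 0, missing_rate = 0, seed = 34)
  g <- simulate_genotypes(simulate_frequencies(cfg), cfg)$gm
  qc <- compute_locus_qc(g)
  rep_ <- select_wgs_candidates(qc, g$loci)
  non_spacing <- rep_$dropped[rep_$dropped$reason != "spacing", ]
  # ancestral MAF well above 0.3 and n = 120: sampling rarely crosses 0.3
  expect_lt(nrow(non_spacing) / 300, 0.05)
  expect_equal(rep_$n_in, rep_$n_out + nrow(rep_$dropped))
})
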