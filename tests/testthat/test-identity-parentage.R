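test_that("enumeration-based non-exclusion equals the frozen closed forms", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    for (mode in c("identity", "first_parent", "second_parent",
                   "parent_pair")) {
      expect_equal(locus_nonexclusion(p, mode), ne_closed_form(p, mode),
                   tolerance = 1e-12,
                   label = sprintf("%s at p=%.1f", mode, p))
    }
  }
  # spec'd spot values at p = 0.5
  expect_equal(locus_nonexclusion(0.5, "identity"), 0.375)
  expect_equal(locus_nonexclusion(0.5, "first_parent"), 0.875)
  expect_error(locus_nonexclusion(0, "identity"), "uninformative")
  expect_error(locus_nonexclusion(1, "parent_pair"), "uninformative")
})

test_that("non-exclusion modes are ordered by how much information they use", {
  for (p in c(0.1, 0.3, 0.5)) {
    ne <- vapply(c("identity", "first_parent", "second_parent",
                   "parent_pair"), locus_nonexclusion, numeric(1), p = p)
    # knowing one parent, or testing a pair, excludes more candidates than
    # the single-parent test
    expect_lt(ne[["second_parent"]], ne[["first_parent"]])
    expect_lt(ne[["parent_pair"]], ne[["second_parent"]])
  }
})

test_that("combined non-exclusion accumulates in log10 and never increases", {
  one <- combined_nonexclusion(0.4, "identity")
  expect_equal(one$prob, locus_nonexclusion(0.4, "identity"))
  # 734 loci at p = 0.5, identity: 0.375^734, log10 about -312.66
  many <- combined_nonexclusion(rep(0.5, 734), "identity")
  expect_equal(many$log10, 734 * log10(0.375), tolerance = 1e-9)
  expect_match(many$scientific, "E-31[0-9]$")
  # adding a locus never increases the combined value
  fewer <- combined_nonexclusion(rep(0.5, 733), "identity")
  expect_lt(many$log10, fewer$log10)
  expect_error(combined_nonexclusion(numeric(0), "identity"), "no loci")
  expect_error(combined_nonexclusion(c(0.5, 1), "identity"), "strictly")
})

test_that("opposing homozygotes are counted only at doubly-called opposite loci", {
  oh <- opposing_homozygotes(c(0L, 2L, 1L, NA, 0L), c(2L, 0L, 2L, 0L, NA))
  expect_equal(oh$oh_count, 2)
  expect_equal(oh$n_compared, 3)
  # an all-heterozygous offspring opposes nobody
  expect_equal(opposing_homozygotes(rep(1L, 10),
                                    sample(c(0L, 2L), 10, TRUE))$oh_count, 0)
  expect_error(opposing_homozygotes(c(NA, 1L), c(1L, NA)), "shared")
})

test_that("pairwise discordance flags duplicates and respects missing overlap", {
  set.seed(71)
  dos <- matrix(sample(c(0L, 1L, 2L), 6 * 734, TRUE), 6, 734)
  dos[2, ] <- dos[1, ]                         # exact duplicate
  dos[4, ] <- dos[3, ]
  dos[4, 1:2] <- (dos[4, 1:2] + 1L) %% 3L    # exactly 2/734 mismatches
  g <- make_gm(dos)
  d <- pairwise_discordance(g)
  r12 <- d[d$id1 == "S1" & d$id2 == "S2", ]
  expect_equal(r12$discordance, 0); expect_true(r12$is_duplicate)
  r34 <- d[d$id1 == "S3" & d$id2 == "S4", ]
  expect_equal(r34$discordance, 2 / 734, tolerance = 1e-12)
  expect_true(r34$is_duplicate)                # 0.0027 < 0.01
  # unrelated pairs sit far above the threshold
  r56 <- d[d$id1 == "S5" & d$id2 == "S6", ]
  expect_gt(r56$discordance, 0.1)
  expect_false(r56$is_duplicate)
  # zero shared called loci: undefined, never flagged
  g0 <- make_gm(rbind(c(0L, NA), c(NA, 2L)))
  d0 <- pairwise_discordance(g0)
  expect_true(is.na(d0$discordance))
  expect_false(d0$is_duplicate)
  # duplicate groups are connected components
  grp <- attr(d, "duplicate_groups")
  expect_equal(sort(vapply(grp, length, integer(1))), c(2L, 2L))
})

test_that("duplicate grouping merges transitive chains", {
  disc <- data.frame(id1 = c("a", "b", "x"), id2 = c("b", "c", "y"),
                     is_duplicate = TRUE, stringsAsFactors = FALSE)
  grp <- duplicate_groups(disc)
  sizes <- sort(vapply(grp, length, integer(1)))
  expect_equal(sizes, c(2L, 3L))
})

test_that("exclusion-based assignment finds the true parent and honours ties", {
  set.seed(72)
  cfg <- sim_config(n_pops = 1, pop_sizes = 30, bn_F = 0, n_loci = 400,
                    ancestral_freq_range = c(0.2, 0.5),
                    error_rate = 0, missing_rate = 0, seed = 73)
  g <- simulate_genotypes(simulate_frequencies(cfg), cfg)$gm
  ped <- simulate_pedigree(g, 5, 5, 5, seed = 74)
  cands <- g$samples$sample_id[c(1:5, 11:30)]   # dams + unrelated, no sires
  res <- assign_parent(ped$gm, ped$truth$offspring_id[1], cands,
                       error_rate = 0.01)
  expect_equal(attr(res, "status"), "assigned")
  expect_equal(attr(res, "assigned_id"), ped$truth$dam_id[1])
  expect_equal(res$mismatch_rate, res$oh_count / res$n_compared)
  # unrelated candidates are excluded with large margins
  unrel <- res[!res$candidate_id %in% ped$truth$dam_id[1], ]
  expect_true(all(unrel$oh_count > ceiling(2 * 0.01 * unrel$n_compared)))
  # a duplicated dam produces an ambiguous call
  g2 <- ped$gm
  dup <- g2$dosage[ped$truth$dam_id[1], , drop = FALSE]
  rownames(dup) <- NULL
  g2 <- rbind_samples(g2, genotype_matrix(
    dup, g2$loci,
    data.frame(sample_id = "dam_copy", population_id = "pop1",
               stringsAsFactors = FALSE)))
  res2 <- assign_parent(g2, ped$truth$offspring_id[1],
                        c(cands, "dam_copy"), error_rate = 0.01)
  expect_equal(attr(res2, "status"), "ambiguous")
  expect_error(assign_parent(g, "pop1_f001", character(0)), "empty")
})

test_that("error-free Mendelian data always assigns the true dam (many seeds)", {
  for (seed in 1:20) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 24, bn_F = 0, n_loci = 300,
                      ancestral_freq_range = c(0.2, 0.5),
                      error_rate = 0, missing_rate = 0, seed = 100 + seed)
    g <- simulate_genotypes(simulate_frequencies(cfg), cfg)$gm
    ped <- simulate_pedigree(g, 3, 3, 3, seed = 200 + seed)
    cands <- g$samples$sample_id[c(1:3, 7:24)]
    out <- assign_parentage(ped$gm, ped$truth$offspring_id, cands,
                            error_rate = 0.01)
    expect_equal(concordance(out, ped$truth), 1,
                 label = sprintf("seed %d", seed))
  }
})

test_that("within-herd MAF subset applies the strict 0.3 bound", {
  # 10 samples: locus 1 at maf exactly 0.30, locus 2 at 0.45, locus 3 at 0.25
  dos <- cbind(c(rep(1L, 6), rep(0L, 4)),
               c(rep(1L, 9), 0L),
               c(rep(1L, 5), rep(0L, 5)))
  g <- make_gm(dos)
  qc <- compute_locus_qc(g)
  expect_equal(qc$maf, c(0.30, 0.45, 0.25))
  kept <- within_herd_maf_subset(g, g$samples$sample_id, maf_min = 0.3)
  expect_equal(kept, "L2")
  expect_lte(length(kept), n_loci(g))
  expect_error(within_herd_maf_subset(g, "S1"), "at least two")
})

test_that("concordance arithmetic counts ambiguous and unassigned as discordant", {
  truth <- data.frame(offspring_id = paste0("o", 1:4),
                      dam_id = paste0("d", 1:4), stringsAsFactors = FALSE)
  asg <- data.frame(offspring_id = paste0("o", 1:4),
                    assigned_id = c("d1", "d2", "dX", NA),
                    status = c("assigned", "assigned", "assigned",
                               "ambiguous"), stringsAsFactors = FALSE)
  expect_equal(concordance(asg, truth), 0.5)
  asg$assigned_id <- truth$dam_id; asg$status <- "assigned"
  expect_equal(concordance(asg, truth), 1)
  expect_error(concordance(asg, truth[0, ]), "empty")
})
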