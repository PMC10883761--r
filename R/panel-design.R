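#' Per-locus quality-control statistics
#'
#' Computes, for every locus: called-genotype count, ALT allele frequency,
#' minor allele frequency, missing fraction, call rate, mean read depth over
#' called cells (when a depth matrix exists), Hardy-Weinberg exact-test
#' p-value, and a monomorphic flag. Loci with zero called genotypes get
#' \code{NA} frequencies and are flagged in \code{no_calls}.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @return data frame with one row per locus
#' @export
compute_locus_qc <- function(g) {
  if (n_samples(g) < 1 || n_loci(g) < 1) stop("empty genotype matrix")
  dos <- g$dosage
  n_called <- colSums(!is.na(dos))
  alt_count <- colSums(dos, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  missing_frac <- 1 - n_called / nrow(dos)
  n_het <- colSums(dos == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(dos == 2L, na.rm = TRUE)
  n_hom_ref <- n_called - n_het - n_hom_alt
  hwe_p <- rep(NA_real_, ncol(dos))
  ok <- n_called > 0
  hwe_p[ok] <- mapply(hwe_exact_test, n_hom_ref[ok], n_het[ok], n_hom_alt[ok])
  mean_depth <- rep(NA_real_, ncol(dos))
  if (!is.null(g$depth)) {
    dp <- g$depth
    dp[is.na(dos)] <- NA
    mean_depth <- colMeans(dp, na.rm = TRUE)
    mean_depth[n_called == 0] <- NA_real_
  }
  data.frame(locus_id = g$loci$locus_id, n_called = n_called,
             p_alt = p_alt, maf = maf, missing_frac = missing_frac,
             call_rate = 1 - missing_frac, mean_depth = mean_depth,
             hwe_p = hwe_p,
             monomorphic = !is.na(maf) & maf == 0,
             no_calls = n_called == 0,
             n_het = n_het, n_hom_ref = n_hom_ref, n_hom_alt = n_hom_alt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Exact conditional test of Hardy-Weinberg proportions from genotype counts
#' (the Wigginton-Cutler-Abecasis algorithm): conditioning on the observed
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' table. Two-sided by this minimum-likelihood criterion, no mid-p
#' correction. \code{one_sided = "het_deficit"} or \code{"het_excess"}
#' instead sums the corresponding tail.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts
#' @param one_sided \code{"two_sided"} (default), \code{"het_deficit"} or
#'   \code{"het_excess"}
#' @return p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt,
                           one_sided = c("two_sided", "het_deficit",
                                         "het_excess")) {
  one_sided <- match.arg(one_sided)
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype is required")
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0) return(1)                       # monomorphic: one table only
  hets <- seq(rare %% 2, rare, by = 2)           # feasible het counts
  # unnormalized conditional probabilities via the standard recurrence
  lp <- numeric(length(hets))
  for (i in seq_along(hets)) {
    h <- hets[i]
    hr <- (rare - h) / 2                         # homozygotes of the rare allele
    hc <- n - h - hr
    lp[i] <- lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  p <- switch(one_sided,
              two_sided = sum(pr[pr <= pr[obs] * (1 + 1e-9)]),
              het_deficit = sum(pr[hets <= n_het]),
              het_excess = sum(pr[hets >= n_het]))
  min(1, p)
}

# stage_report constructor: audits one filtering stage
stage_report <- function(stage, kept, dropped, reasons) {
  stopifnot(length(dropped) == length(reasons))
  structure(list(stage = stage, n_in = length(kept) + length(dropped),
                 n_out = length(kept), kept = kept,
                 dropped = data.frame(locus_id = dropped, reason = reasons,
                                      stringsAsFactors = FALSE)),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> %s: %d -> %d loci\n", x$stage, x$n_in, x$n_out))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) cat(sprintf("  dropped %-18s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Thin loci by physical distance
#'
#' Greedy left-to-right per chromosome: the first locus on each chromosome is
#' kept, then each subsequent locus is kept iff its position is at least
#' \code{min_bp} beyond the last kept position. Chromosomes are independent.
#'
#' @param loci locus data frame sorted by (\code{chrom}, \code{pos});
#'   unsorted input is a contract error
#' @param min_bp minimum spacing in bp
#' @return character vector of kept locus ids
#' @export
thin_by_distance <- function(loci, min_bp) {
  # contract: chromosomes form contiguous blocks, positions non-decreasing
  # within each block (any chromosome ordering is acceptable)
  blocks <- rle(loci$chrom)$values
  if (anyDuplicated(blocks) ||
      any(unlist(tapply(loci$pos, factor(loci$chrom, levels = blocks),
                        function(p) diff(p) < 0))))
    stop("loci must be sorted by (chrom, pos) before distance thinning")
  kept <- character(0)
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, , drop = FALSE]
    last <- -Inf
    for (i in seq_len(nrow(sub))) {
      if (sub$pos[i] - last >= min_bp) {
        kept <- c(kept, sub$locus_id[i])
        last <- sub$pos[i]
      }
    }
  }
  kept
}

#' Select whole-genome-sequence candidate SNPs
#'
#' The discovery filter applied to WGS-derived variants: keep biallelic
#' autosomal loci with MAF strictly above \code{wgs_maf_min} and missingness
#' strictly below \code{wgs_missing_max}, then thin to a minimum physical
#' spacing of \code{spacing_bp}.
#'
#' @param qc output of \code{\link{compute_locus_qc}}
#' @param loci locus data frame, sorted by (\code{chrom}, \code{pos})
#' @param cfg a \code{\link{panel_config}}
#' @return a \code{stage_report}
#' @export
select_wgs_candidates <- function(qc, loci, cfg = panel_config()) {
  qc <- qc[match(loci$locus_id, qc$locus_id), ]
  reason <- rep(NA_character_, nrow(loci))
  reason[loci$is_mito] <- "mitochondrial"
  reason[is.na(reason) & (is.na(qc$maf) | qc$maf <= cfg$wgs_maf_min)] <- "low_maf"
  reason[is.na(reason) & qc$missing_frac >= cfg$wgs_missing_max] <- "high_missing"
  pass1 <- is.na(reason)
  kept_ids <- thin_by_distance(loci[pass1, , drop = FALSE], cfg$spacing_bp)
  reason[pass1 & !(loci$locus_id %in% kept_ids)] <- "spacing"
  stage_report("wgs_candidates", kept_ids,
               loci$locus_id[!is.na(reason)], reason[!is.na(reason)])
}

#' Select bovine-chip candidate SNPs
#'
#' Keep loci with MAF strictly above \code{chip_maf_min} and no missing data
#' in the genotyped discovery cohort.
#'
#' @inheritParams select_wgs_candidates
#' @return a \code{stage_report}
#' @export
select_chip_candidates <- function(qc, cfg = panel_config()) {
  reason <- rep(NA_character_, nrow(qc))
  reason[is.na(qc$maf) | qc$maf <= cfg$chip_maf_min] <- "low_maf"
  reason[is.na(reason) & qc$missing_frac > 0] <- "missing_data"
  stage_report("chip_candidates", qc$locus_id[is.na(reason)],
               qc$locus_id[!is.na(reason)], reason[!is.na(reason)])
}

#' Genotyping-by-sequencing validation filter
#'
#' The validation-stage filter applied to GBS genotypes of the candidate
#' panel. Samples with an overall call rate below
#' \code{sample_precall_min} are removed first; then loci are kept iff
#' MAF >= \code{gbs_maf_min}, Hardy-Weinberg exact p >= \code{hwe_p_min},
#' mean depth strictly above \code{depth_min}, and missingness strictly
#' below \code{gbs_missing_max}. Requires a depth matrix: this filter is
#' specific to sequence-based genotyping.
#'
#' @param g a \code{\link{genotype_matrix}} with depth
#' @param cfg a \code{\link{panel_config}}
#' @return list with \code{report} (a \code{stage_report}),
#'   \code{removed_samples}, and the filtered \code{gm}
#' @export
gbs_validation_filter <- function(g, cfg = panel_config()) {
  if (is.null(g$depth))
    stop("gbs_validation_filter requires a read-depth matrix ",
         "(sequencing-depth filter cannot run on chip data)")
  cr <- sample_call_rate(g)
  removed_samples <- g$samples$sample_id[cr < cfg$sample_precall_min]
  g2 <- g[cr >= cfg$sample_precall_min, ]
  qc <- compute_locus_qc(g2)
  reason <- rep(NA_character_, nrow(qc))
  reason[is.na(qc$maf) | qc$maf < cfg$gbs_maf_min] <- "low_maf"
  reason[is.na(reason) & qc$hwe_p < cfg$hwe_p_min] <- "hwe_fail"
  reason[is.na(reason) &
           (is.na(qc$mean_depth) | qc$mean_depth <= cfg$depth_min)] <- "low_depth"
  reason[is.na(reason) & qc$missing_frac >= cfg$gbs_missing_max] <- "high_missing"
  keep <- is.na(reason)
  rep_ <- stage_report("gbs_validation", qc$locus_id[keep],
                       qc$locus_id[!keep], reason[!keep])
  list(report = rep_, removed_samples = removed_samples,
       gm = g2[, qc$locus_id[keep]])
}

#' Chip evaluation-stage quality-control filter
#'
#' The QC applied to production chip genotypes: drop samples with call rate
#' below \code{call_rate_min}, drop loci with call rate below
#' \code{call_rate_min} (recomputed after sample removal), remove one member
#' of each confirmed duplicate pair (the survivor is the member with the
#' higher call rate, ties broken lexicographically by id), then recompute
#' allele frequencies and drop loci monomorphic in the surviving cohort.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param duplicates data frame of confirmed duplicate pairs with columns
#'   \code{id1}, \code{id2} (e.g. flagged rows of
#'   \code{\link{pairwise_discordance}}), or \code{NULL}
#' @param cfg a \code{\link{panel_config}}
#' @return list with the cleaned \code{gm}, \code{removed_samples} (with
#'   reasons), and \code{reports}, a list of per-stage
#'   \code{stage_report}s for the locus filters
#' @export
chip_qc_filter <- function(g, duplicates = NULL, cfg = panel_config()) {
  cr_s <- sample_call_rate(g)
  low_samples <- g$samples$sample_id[cr_s < cfg$call_rate_min]
  g2 <- g[cr_s >= cfg$call_rate_min, ]

  dup_removed <- character(0)
  if (!is.null(duplicates) && nrow(duplicates)) {
    cr2 <- stats::setNames(sample_call_rate(g2), g2$samples$sample_id)
    for (k in seq_len(nrow(duplicates))) {
      a <- duplicates$id1[k]; b <- duplicates$id2[k]
      if (!(a %in% names(cr2)) || !(b %in% names(cr2))) next
      drop <- if (cr2[a] > cr2[b]) b
              else if (cr2[b] > cr2[a]) a
              else max(a, b)                     # tie: lexicographic survivor
      dup_removed <- union(dup_removed, drop)
    }
    g2 <- g2[setdiff(g2$samples$sample_id, dup_removed), ]
  }

  cr_l <- locus_call_rate(g2)
  low_loci <- g2$loci$locus_id[cr_l < cfg$call_rate_min]
  rep_cr <- stage_report("locus_call_rate",
                         g2$loci$locus_id[cr_l >= cfg$call_rate_min],
                         low_loci, rep("low_call_rate", length(low_loci)))
  g3 <- g2[, cr_l >= cfg$call_rate_min]

  qc <- compute_locus_qc(g3)
  mono <- qc$monomorphic | qc$no_calls
  rep_mono <- stage_report("monomorphic", qc$locus_id[!mono],
                           qc$locus_id[mono], rep("monomorphic", sum(mono)))
  g4 <- g3[, !mono]

  removed <- rbind(
    data.frame(sample_id = low_samples,
               reason = rep("low_call_rate", length(low_samples)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = dup_removed,
               reason = rep("duplicate", length(dup_removed)),
               stringsAsFactors = FALSE))
  list(gm = g4, removed_samples = removed,
       reports = list(locus_call_rate = rep_cr, monomorphic = rep_mono))
}
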