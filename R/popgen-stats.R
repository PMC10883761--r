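#' Observed heterozygosity at a locus
#'
#' Fraction of called genotypes that are heterozygous.
#'
#' @param dos integer dosage vector for one locus (one population)
#' @return fraction in [0, 1], or \code{NA} if no genotype is called
#' @export
ho_locus <- function(dos) {
  called <- !is.na(dos)
  if (!any(called)) return(NA_real_)
  mean(dos[called] == 1L)
}

#' Nei's unbiased expected heterozygosity (gene diversity) at a locus
#'
#' \deqn{H_S = \frac{n}{n-1}\left(1 - \hat p^2 - \hat q^2 - \frac{H_O}{2n}\right)}
#' with \eqn{n} the called-genotype count, \eqn{\hat p} the ALT frequency and
#' \eqn{H_O} the observed heterozygosity — the small-sample-corrected
#' within-population gene diversity.
#'
#' @param dos integer dosage vector for one locus (one population)
#' @return fraction in [0, 1], or \code{NA} when fewer than 2 genotypes are
#'   called
#' @export
hs_locus <- function(dos) {
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  if (n < 2) return(NA_real_)
  p <- sum(dos) / (2 * n)
  ho <- mean(dos == 1L)
  (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
}

#' Individual inbreeding coefficient (homozygosity excess)
#'
#' Method-of-moments estimator comparing a sample's observed homozygote
#' count with its expectation under Hardy-Weinberg at the cohort allele
#' frequencies:
#' \deqn{F = \frac{O_{hom} - E_{hom}}{L - E_{hom}}}
#' where, over the sample's non-missing loci,
#' \eqn{E_{hom} = \sum_l [1 - 2 p_l (1-p_l) \cdot 2N_l/(2N_l-1)]} with
#' \eqn{p_l} the cohort ALT frequency and \eqn{N_l} the cohort
#' called-genotype count at locus \eqn{l}.
#'
#' @param dos the sample's dosage vector
#' @param p cohort ALT frequencies per locus
#' @param n_called cohort called-genotype counts per locus
#' @return the inbreeding coefficient, or \code{NA} when the denominator is
#'   numerically zero
#' @export
individual_f <- function(dos, p, n_called) {
  use <- !is.na(dos) & !is.na(p) & n_called > 0
  if (!any(use)) stop("sample has no called loci")
  L <- sum(use)
  o_hom <- sum(dos[use] != 1L)
  e_hom <- sum(1 - 2 * p[use] * (1 - p[use]) *
                 (2 * n_called[use] / (2 * n_called[use] - 1)))
  denom <- L - e_hom
  if (abs(denom) < 1e-12) return(NA_real_)
  (o_hom - e_hom) / denom
}

#' Rarefied allelic richness at a locus
#'
#' Expected number of distinct alleles in a random subsample of \code{g}
#' gene copies:
#' \deqn{A_R = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' with \eqn{N} the called gene copies in the population at the locus and
#' \eqn{N_a} the copies of allele \eqn{a}.
#'
#' @param counts vector of allele copy counts (for a biallelic locus,
#'   \code{c(ref_copies, alt_copies)})
#' @param g rarefaction depth in gene copies; must not exceed \code{sum(counts)}
#' @return expected allele count in [1, length(counts)]
#' @export
allelic_richness <- function(counts, g) {
  N <- sum(counts)
  if (g < 1) stop("g must be at least 1")
  if (g > N) stop("rarefaction depth g exceeds available gene copies")
  counts <- counts[counts > 0]
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Within-population inbreeding coefficient FIS with bootstrap CI
#'
#' Ratio-of-sums estimator over loci, \eqn{F_{IS} = 1 - \sum_l H_{O,l} /
#' \sum_l H_{S,l}}, restricted to loci where \eqn{H_S} is defined. The
#' confidence interval is the percentile interval of the statistic over
#' \code{n_boot} resamples of loci with replacement.
#'
#' @param g a \code{\link{genotype_matrix}} holding one population
#' @param n_boot bootstrap replicates (default 1000)
#' @param conf confidence level (default 0.95)
#' @param seed optional RNG seed for the bootstrap
#' @return list with \code{fis}, \code{ci} = c(lo, hi), \code{n_loci},
#'   \code{n_boot}, \code{seed}
#' @export
fis_estimate <- function(g, n_boot = 1000, conf = 0.95, seed = NULL) {
  ho <- apply(g$dosage, 2, ho_locus)
  hs <- apply(g$dosage, 2, hs_locus)
  use <- !is.na(hs) & !is.na(ho)
  ho <- ho[use]; hs <- hs[use]
  if (sum(hs) <= 0) stop("sum of gene diversities is zero; FIS undefined")
  fis <- 1 - sum(ho) / sum(hs)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    L <- length(ho)
    stat <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      s_hs <- sum(hs[idx])
      stat[b] <- if (s_hs > 0) 1 - sum(ho[idx]) / s_hs else NA_real_
    }
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), na.rm = TRUE,
                                 names = FALSE))
  }
  list(fis = fis, ci = ci, n_loci = length(ho), n_boot = n_boot, seed = seed)
}

# Weir-Cockerham (1984) variance components for one biallelic locus,
# two populations. n = called genotype counts, p = ALT frequencies,
# h = observed heterozygote fractions. Returns c(a, b, c).
wc_components <- function(n, p, h) {
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise FST between two populations (Weir-Cockerham theta)
#'
#' The 1984 moment estimator for two populations and biallelic loci, as the
#' ratio of sums across loci of the among-population variance component to
#' the total: \eqn{\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)}.
#' Loci with fewer than two called genotypes in either population, or with a
#' zero total component, are skipped. \code{method = "nei"} instead returns
#' the Nei (1987) style \eqn{1 - \sum H_S / \sum H_T} variant for
#' sensitivity checks.
#'
#' @param gA,gB \code{\link{genotype_matrix}} objects over identical loci,
#'   one population each
#' @param method \code{"wc84"} (default) or \code{"nei"}
#' @return the differentiation estimate (can be slightly negative)
#' @export
pairwise_fst <- function(gA, gB, method = c("wc84", "nei")) {
  method <- match.arg(method)
  stopifnot(identical(gA$loci$locus_id, gB$loci$locus_id))
  L <- n_loci(gA)
  nA <- colSums(!is.na(gA$dosage)); nB <- colSums(!is.na(gB$dosage))
  pA <- ifelse(nA > 0, colSums(gA$dosage, na.rm = TRUE) / (2 * nA), NA)
  pB <- ifelse(nB > 0, colSums(gB$dosage, na.rm = TRUE) / (2 * nB), NA)
  usable <- nA >= 2 & nB >= 2
  if (!any(usable)) stop("no loci with >= 2 called genotypes in both populations")
  if (method == "nei") {
    hs <- (mapply(function(j) hs_locus(gA$dosage[, j]), which(usable)) +
           mapply(function(j) hs_locus(gB$dosage[, j]), which(usable))) / 2
    pb <- (pA[usable] + pB[usable]) / 2
    ht <- 2 * pb * (1 - pb)
    if (sum(ht) <= 0) stop("no polymorphic loci shared by the pair")
    return(1 - sum(hs) / sum(ht))
  }
  hA <- colMeans(gA$dosage == 1L, na.rm = TRUE)
  hB <- colMeans(gB$dosage == 1L, na.rm = TRUE)
  num <- 0; den <- 0
  for (j in which(usable)) {
    comp <- wc_components(c(nA[j], nB[j]), c(pA[j], pB[j]), c(hA[j], hB[j]))
    tot <- sum(comp)
    if (is.finite(tot) && tot != 0) {
      num <- num + comp["a"]
      den <- den + tot
    }
  }
  if (den == 0) stop("no usable loci for the FST ratio of sums")
  unname(num / den)
}

#' Per-population diversity table
#'
#' Computes, per population: sample size, mean observed heterozygosity,
#' mean gene diversity, mean individual inbreeding coefficient (individuals
#' measured against whole-cohort frequencies), count of loci monomorphic
#' within the population, mean rarefied allelic richness (rarefaction depth
#' = the minimum called gene copies across populations, per locus), and FIS
#' with a bootstrap confidence interval. Per-population averages include
#' population-monomorphic loci (contributing Ho = Hs = 0 and AR = 1).
#'
#' @param g a cleaned \code{\link{genotype_matrix}} holding all populations
#' @param n_boot bootstrap replicates for the FIS interval
#' @param seed optional RNG seed for the bootstrap
#' @return data frame with one row per population
#' @export
diversity_table <- function(g, n_boot = 1000, seed = NULL) {
  pops <- unique(g$samples$population_id)
  qc_all <- compute_locus_qc(g)
  # per-locus rarefaction depth: minimum called gene copies across populations
  copies <- sapply(pops, function(pp)
    colSums(!is.na(g$dosage[g$samples$population_id == pp, , drop = FALSE])) * 2)
  g_rar <- apply(copies, 1, min)
  rows <- lapply(seq_along(pops), function(i) {
    gi <- g[g$samples$population_id == pops[i], ]
    ho <- apply(gi$dosage, 2, ho_locus)
    hs <- apply(gi$dosage, 2, hs_locus)
    nc <- colSums(!is.na(gi$dosage))
    alt <- colSums(gi$dosage, na.rm = TRUE)
    mono <- nc > 0 & (alt == 0 | alt == 2 * nc)
    ar <- rep(NA_real_, n_loci(gi))
    for (j in seq_len(n_loci(gi))) {
      if (nc[j] > 0 && g_rar[j] >= 2)
        ar[j] <- allelic_richness(c(2 * nc[j] - alt[j], alt[j]), g_rar[j])
    }
    f_ind <- apply(gi$dosage, 1, individual_f,
                   p = qc_all$p_alt, n_called = qc_all$n_called)
    fis <- if (n_samples(gi) >= 2 && sum(hs, na.rm = TRUE) > 0)
      fis_estimate(gi, n_boot = n_boot, seed = seed)
    else list(fis = NA_real_, ci = c(NA_real_, NA_real_))
    data.frame(population_id = pops[i], sample_size = n_samples(gi),
               mean_ho = mean(ho, na.rm = TRUE),
               mean_hs = mean(hs, na.rm = TRUE),
               mean_f = mean(f_ind, na.rm = TRUE),
               n_monomorphic = sum(mono),
               mean_ar = mean(ar, na.rm = TRUE),
               fis = fis$fis, fis_lo = fis$ci[1], fis_hi = fis$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise FST matrix across populations
#'
#' @param g a \code{\link{genotype_matrix}} holding all populations
#' @param method estimator passed to \code{\link{pairwise_fst}}
#' @return symmetric numeric matrix (diagonal \code{NA}) with population ids
#'   as dimnames
#' @export
fst_table <- function(g, method = "wc84") {
  pops <- unique(g$samples$population_id)
  k <- length(pops)
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    gi <- g[g$samples$population_id == pops[i], ]
    for (j in (i + 1):k) {
      gj <- g[g$samples$population_id == pops[j], ]
      m[i, j] <- m[j, i] <- pairwise_fst(gi, gj, method = method)
    }
  }
  m
}
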