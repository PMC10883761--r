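#' Simulation configuration for synthetic bison herds
#'
#' Describes a cohort of differentiated populations for the simulator:
#' ancestral allele frequencies, per-population Balding-Nichols divergence,
#' optional within-population inbreeding, genotyping error and missingness.
#' Defaults emulate a managed-bison study cohort: ten herds of the sampled
#' sizes, 734 informative autosomal SNPs with ancestral minor allele
#' frequencies above 0.1, divergence parameters spanning the observed range
#' of pairwise differentiation, 1\% genotyping error and 2\% missing calls.
#'
#' @param n_pops number of populations
#' @param pop_sizes integer vector of founder counts per population
#' @param bn_F per-population Balding-Nichols differentiation parameters,
#'   each in [0, 1)
#' @param n_loci number of autosomal loci
#' @param ancestral_freq_range ancestral ALT frequency range \code{c(lo, hi)}
#' @param chromosomes data frame with columns \code{name} and \code{length}
#'   (bp) on which loci are placed
#' @param error_rate per-genotype error probability
#' @param missing_rate per-genotype missing probability
#' @param inbreeding_f per-population inbreeding coefficient(s) in [0, 1]
#' @param seed RNG seed making the whole simulation reproducible
#' @return a list of class \code{sim_config}
#' @export
sim_config <- function(n_pops = 10,
                       pop_sizes = c(177, 68, 66, 123, 68, 66, 272, 57, 50, 48),
                       bn_F = c(0.14, 0.06, 0.06, 0.07, 0.04, 0.08, 0.07,
                                0.10, 0.11, 0.16),
                       n_loci = 734,
                       ancestral_freq_range = c(0.1, 0.5),
                       chromosomes = data.frame(
                         name = paste0("chr", 1:29),
                         length = rep(9e7, 29)),
                       error_rate = 0.01, missing_rate = 0.02,
                       inbreeding_f = 0, seed = 1L) {
  if (length(pop_sizes) != n_pops || length(bn_F) != n_pops)
    stop("pop_sizes and bn_F must each have n_pops entries")
  if (any(bn_F < 0) || any(bn_F >= 1))
    stop("bn_F parameters must lie in [0, 1)")
  lo <- ancestral_freq_range[1]; hi <- ancestral_freq_range[2]
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("ancestral_freq_range must satisfy 0 <= lo < hi <= 1")
  if (length(inbreeding_f) == 1) inbreeding_f <- rep(inbreeding_f, n_pops)
  if (any(inbreeding_f < 0 | inbreeding_f > 1))
    stop("inbreeding_f must lie in [0, 1]")
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes, bn_F = bn_F,
                 n_loci = n_loci, ancestral_freq_range = ancestral_freq_range,
                 chromosomes = chromosomes, error_rate = error_rate,
                 missing_rate = missing_rate, inbreeding_f = inbreeding_f,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate ancestral and population allele frequencies
#'
#' Draws ancestral ALT frequencies uniformly on the configured range, then
#' per-population frequencies from the Balding-Nichols model:
#' \eqn{p_k \sim Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)}. A population with
#' \eqn{F_k = 0} keeps the ancestral frequency exactly.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with \code{ancestral} (length n_loci) and \code{pop_freq}
#'   (n_loci x n_pops matrix)
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  p <- stats::runif(cfg$n_loci, cfg$ancestral_freq_range[1],
                    cfg$ancestral_freq_range[2])
  pf <- matrix(0, cfg$n_loci, cfg$n_pops,
               dimnames = list(NULL, paste0("pop", seq_len(cfg$n_pops))))
  for (k in seq_len(cfg$n_pops)) {
    Fk <- cfg$bn_F[k]
    pf[, k] <- if (Fk == 0) p else
      stats::rbeta(cfg$n_loci, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  list(ancestral = p, pop_freq = pf)
}

# place n loci at strictly increasing random positions across chromosomes
place_loci <- function(n, chromosomes) {
  chrom_idx <- sort(sample.int(nrow(chromosomes), n, replace = TRUE))
  pos <- integer(n)
  for (ci in unique(chrom_idx)) {
    sel <- chrom_idx == ci
    p <- sort(sample.int(chromosomes$length[ci], sum(sel), replace = TRUE))
    while (anyDuplicated(p)) {          # collisions shifted by +1 bp
      p[duplicated(p)] <- p[duplicated(p)] + 1L
      p <- sort(p)
    }
    pos[sel] <- p
  }
  data.frame(locus_id = sprintf("snp%04d", seq_len(n)),
             chrom = chromosomes$name[chrom_idx], pos = pos,
             ref = "A", alt = "G", source = "wgs", is_mito = FALSE,
             stringsAsFactors = FALSE)
}

# genotype draw with inbreeding: P(2) = p^2 + f p q, P(1) = 2pq(1-f),
# P(0) = q^2 + f p q
draw_genotypes <- function(p, f, n) {
  q <- 1 - p
  pr2 <- p^2 + f * p * q
  pr1 <- 2 * p * q * (1 - f)
  u <- matrix(stats::runif(n * length(p)), n, length(p), byrow = FALSE)
  P2 <- matrix(pr2, n, length(p), byrow = TRUE)
  P21 <- matrix(pr2 + pr1, n, length(p), byrow = TRUE)
  d <- matrix(0L, n, length(p))
  d[u < P21] <- 1L
  d[u < P2] <- 2L
  d
}

#' Simulate founder genotypes for every population
#'
#' Founders are drawn independently per locus under the population's allele
#' frequency with optional inbreeding. Loci are placed at strictly
#' increasing random positions on the configured chromosomes.
#'
#' @param freqs output of \code{\link{simulate_frequencies}}
#' @param cfg the \code{\link{sim_config}} used to generate \code{freqs}
#' @return list with \code{gm} (a \code{\link{genotype_matrix}}) and
#'   \code{truth} (list with the frequency table and per-sample truth rows)
#' @export
simulate_genotypes <- function(freqs, cfg) {
  set.seed(cfg$seed + 1L)
  loci <- place_loci(cfg$n_loci, cfg$chromosomes)
  dos <- NULL
  samples <- NULL
  for (k in seq_len(cfg$n_pops)) {
    nk <- cfg$pop_sizes[k]
    dk <- draw_genotypes(freqs$pop_freq[, k], cfg$inbreeding_f[k], nk)
    dos <- rbind(dos, dk)
    samples <- rbind(samples, data.frame(
      sample_id = sprintf("pop%d_f%03d", k, seq_len(nk)),
      population_id = paste0("pop", k),
      dam_id = NA_character_, sire_id = NA_character_,
      stringsAsFactors = FALSE))
  }
  gm <- genotype_matrix(dos, loci, samples)
  truth <- list(ancestral = freqs$ancestral, pop_freq = freqs$pop_freq,
                samples = cbind(samples, role = "founder",
                                stringsAsFactors = FALSE))
  list(gm = gm, truth = truth)
}

#' Extend a founder cohort with a Mendelian pedigree
#'
#' Designates dams and sires among one population's founders and creates
#' offspring, each drawing one allele from its dam's genotype and one from
#' its sire's, independently per locus. True dam and sire ids are recorded
#' both in the sample table and the returned truth rows.
#'
#' @param gm founder \code{\link{genotype_matrix}}
#' @param n_dams,n_sires,n_offspring pedigree sizes; each offspring pairs a
#'   distinct dam (recycled if \code{n_offspring > n_dams}) with a random sire
#' @param population population whose founders supply parents (default first)
#' @param seed optional RNG seed
#' @return list with the extended \code{gm} and a \code{truth} data frame of
#'   offspring ids with true \code{dam_id} and \code{sire_id}
#' @export
simulate_pedigree <- function(gm, n_dams, n_sires, n_offspring = n_dams,
                              population = gm$samples$population_id[1],
                              seed = NULL) {
  if (n_dams < 1 || n_sires < 1) stop("need at least one dam and one sire")
  if (!is.null(seed)) set.seed(seed)
  pool <- gm$samples$sample_id[gm$samples$population_id == population]
  if (length(pool) < n_dams + n_sires)
    stop("population has too few founders for the requested pedigree")
  dams <- pool[seq_len(n_dams)]
  sires <- pool[n_dams + seq_len(n_sires)]
  dam_of <- rep_len(dams, n_offspring)
  sire_of <- sample(sires, n_offspring, replace = TRUE)

  L <- n_loci(gm)
  transmit <- function(parent_dos) {
    # allele contributed by a parent: hom passes its allele, het flips a coin
    al <- integer(L)
    al[parent_dos == 2L] <- 1L
    het <- which(parent_dos == 1L)
    al[het] <- stats::rbinom(length(het), 1L, 0.5)
    al
  }
  off_dos <- matrix(0L, n_offspring, L)
  for (i in seq_len(n_offspring)) {
    d <- gm$dosage[dam_of[i], ]
    s <- gm$dosage[sire_of[i], ]
    off_dos[i, ] <- transmit(d) + transmit(s)
  }
  off_samples <- data.frame(
    sample_id = sprintf("%s_calf%03d", population, seq_len(n_offspring)),
    population_id = population, dam_id = dam_of, sire_id = sire_of,
    stringsAsFactors = FALSE)
  off_gm <- genotype_matrix(off_dos, gm$loci, off_samples)
  list(gm = rbind_samples(gm, off_gm),
       truth = data.frame(offspring_id = off_samples$sample_id,
                          dam_id = dam_of, sire_id = sire_of,
                          stringsAsFactors = FALSE))
}

#' Inject genotyping error and missingness
#'
#' Each non-missing cell independently becomes missing with probability
#' \code{missing_rate}; otherwise, with probability \code{error_rate}, it is
#' replaced by one of the two other dosage codes chosen uniformly. Cells
#' already missing are never touched.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param error_rate,missing_rate probabilities in [0, 1]
#' @param seed optional RNG seed
#' @return list with the perturbed \code{gm} and \code{flags}, a logical
#'   matrix pair (\code{errored}, \code{masked}) recording every change
#' @export
inject_noise <- function(gm, error_rate, missing_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  dos <- gm$dosage
  callable <- !is.na(dos)
  u <- matrix(stats::runif(length(dos)), nrow(dos))
  masked <- callable & u < missing_rate
  errored <- callable & !masked & u >= missing_rate &
    u < missing_rate + (1 - missing_rate) * error_rate
  if (any(errored)) {
    old <- dos[errored]
    pick <- stats::runif(length(old)) < 0.5
    # the two codes other than `old`, chosen uniformly
    others <- cbind((old + 1L) %% 3L, (old + 2L) %% 3L)
    dos[errored] <- ifelse(pick, others[, 1], others[, 2])
  }
  dos[masked] <- NA_integer_
  out <- gm
  out$dosage <- dos
  list(gm = out, flags = list(errored = errored, masked = masked))
}

#' Synthetic mitochondrial diagnostic panel definition
#'
#' A stand-in panel of 10 species-diagnostic loci (bison vs. domestic cattle
#' allele) and 3 clade loci (Clade I vs. Clade II allele). The real
#' diagnostic sites come from prior mitogenome work and are supplied as
#' configuration when analysing real data; this synthetic table exists so the
#' classifier and simulator can be exercised end to end.
#'
#' @return a list of class \code{mt_panel_def} with data frames
#'   \code{species_loci} and \code{clade_loci}
#' @export
default_mt_panel <- function() {
  species <- data.frame(
    locus_id = sprintf("mt_sp%02d", 1:10),
    pos = seq(1000L, by = 500L, length.out = 10),
    bison_allele = c("A", "G", "T", "C", "A", "G", "T", "C", "A", "G"),
    cattle_allele = c("G", "A", "C", "T", "G", "A", "C", "T", "G", "A"),
    stringsAsFactors = FALSE)
  clade <- data.frame(
    locus_id = sprintf("mt_cl%02d", 1:3),
    pos = seq(9000L, by = 500L, length.out = 3),
    cladeI_allele = c("C", "T", "A"),
    cladeII_allele = c("T", "C", "G"),
    stringsAsFactors = FALSE)
  mt_panel_def(species, clade)
}

#' Construct a mitochondrial panel definition
#'
#' @param species_loci data frame with columns \code{locus_id},
#'   \code{bison_allele}, \code{cattle_allele} (exactly 10 rows)
#' @param clade_loci data frame with columns \code{locus_id},
#'   \code{cladeI_allele}, \code{cladeII_allele} (exactly 3 rows)
#' @return a list of class \code{mt_panel_def}
#' @export
mt_panel_def <- function(species_loci, clade_loci) {
  if (nrow(species_loci) != 10)
    stop("the species panel is defined by exactly 10 diagnostic loci")
  if (nrow(clade_loci) != 3)
    stop("the clade panel is defined by exactly 3 diagnostic loci")
  if (any(species_loci$bison_allele == species_loci$cattle_allele) ||
      any(clade_loci$cladeI_allele == clade_loci$cladeII_allele))
    stop("diagnostic alleles must differ within each locus")
  structure(list(species_loci = species_loci, clade_loci = clade_loci),
            class = "mt_panel_def")
}

#' Simulate mitochondrial genotypes for labelled samples
#'
#' Each sample receives homozygous calls matching its haplotype template
#' (\code{bisonI}, \code{bisonII} or \code{cattle}); maternal inheritance is
#' the caller's responsibility (give offspring their dam's label). With
#' probability \code{het_noise} a call is rendered heterozygous, emulating
#' NUMT co-amplification or genotyping error on a diploid-calling chip.
#'
#' Encoding: at species loci the chip reference allele is the cattle allele
#' and the alternate is the bison allele; at clade loci reference is Clade II
#' and alternate Clade I. A cattle-template sample carries Clade II alleles
#' at clade loci (they are ignored by the classifier anyway).
#'
#' @param samples sample data frame (as in \code{\link{genotype_matrix}})
#' @param labels character vector (one per sample) in
#'   \code{c("bisonI", "bisonII", "cattle")}
#' @param het_noise probability a call is rendered heterozygous
#' @param panel an \code{\link{mt_panel_def}}
#' @param seed optional RNG seed
#' @return a \code{\link{genotype_matrix}} over the 13 mitochondrial loci
#' @export
simulate_mt <- function(samples, labels, het_noise = 0,
                        panel = default_mt_panel(), seed = NULL) {
  if (!all(labels %in% c("bisonI", "bisonII", "cattle")))
    stop("unknown mitochondrial haplotype label")
  if (length(labels) != nrow(samples))
    stop("one label per sample required")
  if (!is.null(seed)) set.seed(seed)
  sp <- panel$species_loci; cl <- panel$clade_loci
  loci <- data.frame(
    locus_id = c(sp$locus_id, cl$locus_id),
    chrom = "MT",
    pos = c(if ("pos" %in% names(sp)) sp$pos else seq_len(nrow(sp)),
            if ("pos" %in% names(cl)) cl$pos else 5000L + seq_len(nrow(cl))),
    ref = c(sp$cattle_allele, cl$cladeII_allele),
    alt = c(sp$bison_allele, cl$cladeI_allele),
    source = "mito", is_mito = TRUE, stringsAsFactors = FALSE)
  n <- nrow(samples)
  is_bison <- labels != "cattle"
  is_cladeI <- labels == "bisonI"
  dos <- cbind(matrix(ifelse(is_bison, 2L, 0L), n, 10),
               matrix(ifelse(is_cladeI, 2L, 0L), n, 3))
  if (het_noise > 0) {
    het <- matrix(stats::runif(n * 13) < het_noise, n, 13)
    dos[het] <- 1L
  }
  genotype_matrix(dos, loci, samples)
}

#' Simulate a complete multi-population cohort
#'
#' Convenience wrapper chaining \code{\link{simulate_frequencies}},
#' \code{\link{simulate_genotypes}} and \code{\link{inject_noise}}, and
#' attaching maternally inherited mitochondrial haplotypes (populations are
#' assigned alternating Clade I / Clade II majorities).
#'
#' @param cfg a \code{\link{sim_config}}
#' @param mt logical; also simulate the 13-locus mitochondrial panel
#' @return list with \code{gm} (autosomal), \code{gm_mt} (or \code{NULL}),
#'   \code{truth}, and \code{flags} from noise injection
#' @export
simulate_cohort <- function(cfg, mt = TRUE) {
  freqs <- simulate_frequencies(cfg)
  sim <- simulate_genotypes(freqs, cfg)
  noisy <- inject_noise(sim$gm, cfg$error_rate, cfg$missing_rate,
                        seed = cfg$seed + 2L)
  gm_mt <- NULL
  mt_labels <- NULL
  if (mt) {
    set.seed(cfg$seed + 3L)
    pop <- sim$gm$samples$population_id
    pops <- unique(pop)
    major <- ifelse(seq_along(pops) %% 2 == 1, "bisonI", "bisonII")
    mt_labels <- character(length(pop))
    for (i in seq_along(pops)) {
      sel <- pop == pops[i]
      maj <- major[i]
      minr <- setdiff(c("bisonI", "bisonII"), maj)
      mt_labels[sel] <- ifelse(stats::runif(sum(sel)) < 0.9, maj, minr)
    }
    gm_mt <- simulate_mt(sim$gm$samples, mt_labels, het_noise = 0.01)
  }
  truth <- sim$truth
  truth$mt_labels <- mt_labels
  list(gm = noisy$gm, gm_mt = gm_mt, truth = truth, flags = noisy$flags)
}
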