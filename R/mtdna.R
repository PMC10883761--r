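#' Read a mitochondrial diagnostic panel definition from TSV
#'
#' Tab-delimited table with columns \code{locus_id}, \code{class}
#' (\code{species} or \code{clade}), \code{allele_A}, \code{allele_B}.
#' For species rows allele A is the bison allele and allele B the domestic
#' cattle allele; for clade rows allele A is Clade I and allele B Clade II.
#'
#' @param path path to the TSV file
#' @return an \code{\link{mt_panel_def}}
#' @export
read_mt_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "class", "allele_A", "allele_B")
  if (!all(need %in% names(tab)))
    stop("mt panel file must contain columns: ", paste(need, collapse = ", "))
  if (!all(tab$class %in% c("species", "clade")))
    stop("mt panel class must be 'species' or 'clade'")
  sp <- tab[tab$class == "species", ]
  cl <- tab[tab$class == "clade", ]
  mt_panel_def(
    data.frame(locus_id = sp$locus_id, bison_allele = sp$allele_A,
               cattle_allele = sp$allele_B, stringsAsFactors = FALSE),
    data.frame(locus_id = cl$locus_id, cladeI_allele = cl$allele_A,
               cladeII_allele = cl$allele_B, stringsAsFactors = FALSE))
}

#' NUMT-suspect filter for mitochondrial loci
#'
#' Mitochondria are haploid, so genuinely mitochondrial SNPs should never be
#' heterozygous on a diploid-calling chip; loci heterozygous across a large
#' fraction of samples are treated as nuclear-mitochondrial (NUMT) artifacts
#' and removed. The boundary is inclusive: a locus heterozygous in exactly
#' \code{het_frac_max} of called samples is removed (\code{strict = TRUE}
#' switches to a strict inequality).
#'
#' @param g_mt a \code{\link{genotype_matrix}} of mitochondrial loci
#' @param het_frac_max removal boundary (default 0.90)
#' @param strict logical; require strictly greater than the boundary
#' @return character vector of surviving locus ids
#' @export
numt_filter <- function(g_mt, het_frac_max = 0.90, strict = FALSE) {
  het_frac <- apply(g_mt$dosage, 2, function(d) {
    called <- !is.na(d)
    if (!any(called)) return(0)
    mean(d[called] == 1L)
  })
  drop <- if (strict) het_frac > het_frac_max else het_frac >= het_frac_max
  g_mt$loci$locus_id[!drop]
}

#' Recode heterozygous mitochondrial calls as missing
#'
#' Any heterozygous call at a mitochondrial locus is treated as missing data
#' and ignored by the assignment rules; homozygous calls are unchanged and
#' map to the locus's two defined alleles.
#'
#' @param g_mt a \code{\link{genotype_matrix}} of mitochondrial loci
#' @return the recoded \code{\link{genotype_matrix}}
#' @export
recode_het_missing <- function(g_mt) {
  g_mt$dosage[g_mt$dosage == 1L] <- NA_integer_
  g_mt
}

# map a sample's dosages at given loci to allele letters (NA where missing)
.mt_alleles <- function(dos, loci) {
  ifelse(is.na(dos), NA_character_, ifelse(dos == 0L, loci$ref, loci$alt))
}

#' Assign mitochondrial species and clade haplotypes
#'
#' Rule-based classification from the diagnostic panel, applied after the
#' NUMT filter and heterozygote recoding:
#' \itemize{
#'   \item Species: with \eqn{b} species loci carrying the bison allele and
#'     \eqn{c} carrying the cattle allele, a sample is \code{bison} iff
#'     \eqn{b \ge 5} and \eqn{c = 0}, \code{cattle} iff \eqn{c \ge 5} and
#'     \eqn{b = 0}, otherwise \code{unassigned}. Missing loci are ignored.
#'   \item Clade: only samples with a bison species call are classified;
#'     \code{cladeI} iff at least one Clade I allele and no Clade II allele
#'     is present, \code{cladeII} vice versa, otherwise (including every
#'     cattle or species-unassigned sample) \code{unassigned}.
#' }
#'
#' @param g_mt a \code{\link{genotype_matrix}} of mitochondrial loci
#' @param panel an \code{\link{mt_panel_def}}
#' @param numt_het_frac boundary passed to \code{\link{numt_filter}}
#' @return data frame with one row per sample: \code{sample_id},
#'   \code{species}, \code{clade} and the allele counts
#'   \code{n_bison}, \code{n_cattle}, \code{n_cladeI}, \code{n_cladeII},
#'   \code{n_missing}
#' @export
assign_mtdna <- function(g_mt, panel, numt_het_frac = 0.90) {
  surviving <- numt_filter(g_mt, het_frac_max = numt_het_frac)
  g2 <- recode_het_missing(g_mt[, surviving])
  sp_ids <- intersect(panel$species_loci$locus_id, surviving)
  cl_ids <- intersect(panel$clade_loci$locus_id, surviving)
  sp_panel <- panel$species_loci[match(sp_ids, panel$species_loci$locus_id), ]
  cl_panel <- panel$clade_loci[match(cl_ids, panel$clade_loci$locus_id), ]
  sp_loci <- g2$loci[match(sp_ids, g2$loci$locus_id), ]
  cl_loci <- g2$loci[match(cl_ids, g2$loci$locus_id), ]

  rows <- lapply(seq_len(n_samples(g2)), function(i) {
    sp_al <- .mt_alleles(g2$dosage[i, sp_ids], sp_loci)
    cl_al <- .mt_alleles(g2$dosage[i, cl_ids], cl_loci)
    b <- sum(sp_al == sp_panel$bison_allele, na.rm = TRUE)
    cc <- sum(sp_al == sp_panel$cattle_allele, na.rm = TRUE)
    n1 <- sum(cl_al == cl_panel$cladeI_allele, na.rm = TRUE)
    n2 <- sum(cl_al == cl_panel$cladeII_allele, na.rm = TRUE)
    nm <- sum(is.na(sp_al)) + sum(is.na(cl_al)) +
      (13 - length(sp_ids) - length(cl_ids))   # NUMT-removed loci are missing
    species <- if (b >= 5 && cc == 0) "bison"
               else if (cc >= 5 && b == 0) "cattle"
               else "unassigned"
    clade <- if (species != "bison") "unassigned"
             else if (n1 >= 1 && n2 == 0) "cladeI"
             else if (n2 >= 1 && n1 == 0) "cladeII"
             else "unassigned"
    data.frame(sample_id = g2$samples$sample_id[i], species = species,
               clade = clade, n_bison = b, n_cattle = cc,
               n_cladeI = n1, n_cladeII = n2, n_missing = nm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-population mitochondrial clade percentages
#'
#' @param calls output of \code{\link{assign_mtdna}}
#' @param populations character vector of population ids, one per row of
#'   \code{calls}
#' @param digits rounding for the percentage columns (default 0, matching
#'   conventional reporting; rows may deviate from 100 by rounding)
#' @return data frame with columns \code{population_id}, \code{n},
#'   \code{cladeI_pct}, \code{cladeII_pct}, \code{unassigned_pct}, plus a
#'   \code{Total} row
#' @export
clade_table <- function(calls, populations, digits = 0) {
  stopifnot(length(populations) == nrow(calls))
  mk <- function(cl, label) {
    n <- length(cl)
    data.frame(population_id = label, n = n,
               cladeI_pct = round(100 * mean(cl == "cladeI"), digits),
               cladeII_pct = round(100 * mean(cl == "cladeII"), digits),
               unassigned_pct = round(100 * mean(cl == "unassigned"), digits),
               stringsAsFactors = FALSE)
  }
  pops <- unique(populations)
  out <- do.call(rbind, lapply(pops, function(pp)
    mk(calls$clade[populations == pp], pp)))
  rbind(out, mk(calls$clade, "Total"))
}
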