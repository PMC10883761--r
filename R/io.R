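#' Read diploid biallelic SNP genotypes from a VCF file
#'
#' Ingests VCF 4.x records carrying a GT field. Only biallelic SNP records
#' (single-base REF, single-base ALT) are kept; multi-allelic and non-SNP
#' records are skipped and counted. Genotypes are encoded as ALT-allele
#' dosage: \code{0/0} -> 0, \code{0/1} or \code{1/0} -> 1, \code{1/1} -> 2,
#' \code{./.} -> \code{NA}. Phased separators are accepted. Per-call read
#' depth (FORMAT DP) is captured when present.
#'
#' @param path path to a VCF (plain or gzipped) file.
#' @param meta optional sample metadata data frame (see
#'   \code{\link{read_sample_metadata}}); matched to VCF sample names by
#'   \code{sample_id}. Samples without metadata get \code{NA} population.
#' @param mito_contigs contig names treated as mitochondrial
#'   (default \code{c("MT", "chrM", "M", "chrMT")}).
#' @return a \code{\link{genotype_matrix}}; the number of skipped
#'   (non-biallelic-SNP) records is available as attribute
#'   \code{"n_skipped"}.
#' @export
read_vcf <- function(path, meta = NULL,
                     mito_contigs = c("MT", "chrM", "M", "chrMT")) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nrec <- nrow(fix)
  if (nrec == 0) stop("no records in VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  usable <- !is.na(alt) & ref %in% bases & alt %in% bases
  n_skipped <- sum(!usable)
  if (!any(usable)) stop("no usable biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[usable, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  core <- gsub("\\|", "/", gt)
  dos[core %in% "0/0"] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core %in% "1/1"] <- 2L
  bad <- !is.na(core) & !(core %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable GT '%s' at record %d sample %d", gt[bad][1],
                 w[1], w[2]))
  }

  depth <- NULL
  fmt <- v@gt[usable, 1, drop = TRUE]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- t(dp[usable, , drop = FALSE])
  }

  chrom <- fix[usable, "CHROM"]
  is_mito <- chrom %in% mito_contigs
  ids <- fix[usable, "ID"]
  fallback <- paste0(chrom, "_", fix[usable, "POS"])
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  loci <- data.frame(locus_id = ids, chrom = chrom,
                     pos = as.integer(fix[usable, "POS"]),
                     ref = ref[usable], alt = alt[usable],
                     source = ifelse(is_mito, "mito", "wgs"),
                     is_mito = is_mito, stringsAsFactors = FALSE)

  sample_ids <- colnames(gt)
  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- match(sample_ids, meta$sample_id)
    samples$population_id <- meta$population_id[m]
    samples$dam_id <- if ("dam_id" %in% names(meta)) meta$dam_id[m] else NA_character_
    samples$sire_id <- if ("sire_id" %in% names(meta)) meta$sire_id[m] else NA_character_
  }
  g <- genotype_matrix(t(dos), loci, samples, depth = depth)
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Plain-text writer; missing calls serialize as \code{./.}. Read depth, when
#' present, is written as FORMAT DP. \code{read_vcf(write_vcf(g))} reproduces
#' the dosage matrix and locus coordinates exactly.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(g, path) {
  loci <- g$loci
  has_dp <- !is.null(g$depth)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bisonpanel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (has_dp)
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$sample_id), collapse = "\t")),
             con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L], nrow = nrow(g$dosage))
  gt_str[is.na(g$dosage)] <- "./."
  if (has_dp) {
    dp <- g$depth
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str[] <- paste(gt_str, dp_str, sep = ":")
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  for (j in seq_len(nrow(loci))) {
    writeLines(paste(c(loci$chrom[j], loci$pos[j], loci$locus_id[j],
                       loci$ref[j], loci$alt[j], ".", "PASS", ".",
                       fmt, gt_str[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited table with columns \code{sample_id}, \code{population_id}
#' and optional \code{dam_id} / \code{sire_id}.
#'
#' @param path path to a TSV file
#' @return a data frame
#' @export
read_sample_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population_id")
  if (!all(need %in% names(m)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (!"dam_id" %in% names(m)) m$dam_id <- NA_character_
  if (!"sire_id" %in% names(m)) m$sire_id <- NA_character_
  m$dam_id[m$dam_id %in% c("", ".")] <- NA_character_
  m$sire_id[m$sire_id %in% c("", ".")] <- NA_character_
  m
}

#' Read an Illumina-style final report into a genotype matrix
#'
#' Tab-delimited table with header columns \code{Sample ID}, \code{SNP Name},
#' \code{Allele1}, \code{Allele2} and optional \code{GC Score}. Allele pairs
#' are mapped to ALT dosage against the supplied locus definitions. Calls
#' with GC score below \code{gc_min} or a \code{-} allele become missing.
#' Rows naming SNPs absent from \code{loci} are dropped (count in attribute
#' \code{"n_unknown_snps"}). Allele letters that match neither the reference
#' nor the alternate allele of their locus raise an error listing the
#' offending rows: strand mismatches must be resolved upstream, not silently
#' miscoded.
#'
#' @param path path to the final report file
#' @param loci locus definition data frame (as in
#'   \code{\link{genotype_matrix}}) giving \code{locus_id}, \code{ref},
#'   \code{alt}
#' @param gc_min GenCall score cutoff below which a call is set missing
#'   (default 0.95)
#' @param meta optional sample metadata data frame
#' @return a \code{\link{genotype_matrix}} over the report's samples and the
#'   loci present in both report and \code{loci}
#' @export
read_final_report <- function(path, loci, gc_min = 0.95, meta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Sample ID", "SNP Name", "Allele1", "Allele2")
  if (!all(need %in% names(tab)))
    stop("final report must contain columns: ", paste(need, collapse = ", "))
  has_gc <- "GC Score" %in% names(tab)

  known <- tab[["SNP Name"]] %in% loci$locus_id
  n_unknown <- sum(!known)
  tab <- tab[known, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows in final report match the locus map")

  li <- match(tab[["SNP Name"]], loci$locus_id)
  ref <- loci$ref[li]; alt <- loci$alt[li]
  a1 <- tab$Allele1; a2 <- tab$Allele2
  nocall <- a1 == "-" | a2 == "-"
  if (has_gc) nocall <- nocall | (as.numeric(tab[["GC Score"]]) < gc_min)

  valid <- nocall | ((a1 == ref | a1 == alt) & (a2 == ref | a2 == alt))
  if (!all(valid)) {
    bad <- which(!valid)
    stop("allele calls match neither ref nor alt at rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...",
         " (strand dialect mismatch?)")
  }
  dosage_val <- (a1 == alt) + (a2 == alt)
  dosage_val[nocall] <- NA_integer_

  sample_ids <- unique(tab[["Sample ID"]])
  locus_ids <- unique(tab[["SNP Name"]])
  dos <- matrix(NA_integer_, length(sample_ids), length(locus_ids),
                dimnames = list(sample_ids, locus_ids))
  dos[cbind(match(tab[["Sample ID"]], sample_ids),
            match(tab[["SNP Name"]], locus_ids))] <- dosage_val

  loci_out <- loci[match(locus_ids, loci$locus_id), , drop = FALSE]
  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- match(sample_ids, meta$sample_id)
    samples$population_id <- meta$population_id[m]
    samples$dam_id <- if ("dam_id" %in% names(meta)) meta$dam_id[m] else NA_character_
    samples$sire_id <- if ("sire_id" %in% names(meta)) meta$sire_id[m] else NA_character_
  }
  g <- genotype_matrix(dos, loci_out, samples)
  attr(g, "n_unknown_snps") <- n_unknown
  g
}

#' Default panel-design and analysis thresholds
#'
#' Bundles the filtering thresholds of the marker-selection cascade and the
#' downstream analyses. Every value can be overridden by name.
#'
#' @param ... named overrides of the defaults, e.g.
#'   \code{panel_config(call_rate_min = 0.95)}
#' @return a named list of class \code{panel_config}:
#' \describe{
#'   \item{wgs_maf_min}{candidate MAF lower bound, strict (default 0.3)}
#'   \item{wgs_missing_max}{candidate missingness upper bound, strict (0.5)}
#'   \item{spacing_bp}{minimum physical distance between kept candidates
#'     (1,200,000 bp)}
#'   \item{chip_maf_min}{chip-candidate MAF lower bound, strict (0.1)}
#'   \item{gbs_maf_min}{validation MAF lower bound, inclusive (0.1)}
#'   \item{hwe_p_min}{Hardy-Weinberg exact p-value lower bound, inclusive
#'     (0.005)}
#'   \item{depth_min}{mean read depth lower bound, strict (10)}
#'   \item{gbs_missing_max}{validation missingness upper bound, strict (0.15)}
#'   \item{sample_precall_min}{sample call-rate pre-filter (0.5)}
#'   \item{call_rate_min}{chip sample/locus call-rate bound (0.90)}
#'   \item{dup_discordance_max}{pairwise discordance below which a pair is a
#'     duplicate (0.01)}
#'   \item{numt_het_frac}{heterozygous-sample fraction at which a mitochondrial
#'     locus is treated as a NUMT artifact (0.90)}
#'   \item{genotype_error_rate}{assumed per-genotype error rate used by
#'     parentage assignment (0.01)}
#' }
#' @export
panel_config <- function(...) {
  cfg <- list(wgs_maf_min = 0.3, wgs_missing_max = 0.5, spacing_bp = 1200000L,
              chip_maf_min = 0.1, gbs_maf_min = 0.1, hwe_p_min = 0.005,
              depth_min = 10, gbs_missing_max = 0.15, sample_precall_min = 0.5,
              call_rate_min = 0.90, dup_discordance_max = 0.01,
              numt_het_frac = 0.90, genotype_error_rate = 0.01)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown panel_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  fracs <- setdiff(names(cfg), c("spacing_bp", "depth_min"))
  if (any(unlist(cfg[fracs]) < 0 | unlist(cfg[fracs]) > 1))
    stop("panel_config fractions must lie in [0, 1]")
  if (cfg$spacing_bp <= 0) stop("spacing_bp must be positive")
  structure(cfg, class = "panel_config")
}
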