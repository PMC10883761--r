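#' Construct a genotype matrix object
#'
#' The central container every analysis stage consumes: a samples x loci
#' matrix of diploid allele-dosage codes (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, \code{NA} = missing call),
#' together with locus and sample annotation and an optional per-call read
#' depth matrix.
#'
#' @param dosage integer matrix, samples in rows and loci in columns; entries
#'   must be 0, 1, 2 or \code{NA}.
#' @param loci data frame with one row per locus and columns \code{locus_id},
#'   \code{chrom}, \code{pos} (1-based bp), \code{ref}, \code{alt},
#'   \code{source} (one of \code{"wgs"}, \code{"bovine_chip"}, \code{"mito"})
#'   and \code{is_mito}.
#' @param samples data frame with one row per sample and columns
#'   \code{sample_id}, \code{population_id}, and optionally \code{dam_id} and
#'   \code{sire_id} (\code{NA} when unknown).
#' @param depth optional non-negative integer matrix of per-call read depth,
#'   same dimensions as \code{dosage}.
#'
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosage}, \code{loci}, \code{samples} and \code{depth}.
#' @export
genotype_matrix <- function(dosage, loci, samples, depth = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)))
    stop("dosage entries must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_l <- c("locus_id", "chrom", "pos", "ref", "alt", "source", "is_mito")
  missing_l <- setdiff(need_l, names(loci))
  if (length(missing_l))
    stop("loci is missing columns: ", paste(missing_l, collapse = ", "))
  if (!"sample_id" %in% names(samples))
    stop("samples needs a sample_id column")
  ns <- nrow(samples)
  if (!"population_id" %in% names(samples))
    samples$population_id <- rep(NA_character_, ns)
  if (!"dam_id" %in% names(samples)) samples$dam_id <- rep(NA_character_, ns)
  if (!"sire_id" %in% names(samples)) samples$sire_id <- rep(NA_character_, ns)
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(loci))
    stop("dosage dimensions must be n_samples x n_loci")
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique")
  if (anyDuplicated(loci$locus_id))
    stop("locus ids must be unique")
  if (any(loci$pos < 1L))
    stop("locus positions are 1-based and must be >= 1")
  if (any(loci$ref == loci$alt))
    stop("ref and alt alleles must differ at every locus")
  if (!all(loci$source %in% c("wgs", "bovine_chip", "mito")))
    stop("locus source must be wgs, bovine_chip or mito")
  if (any(loci$is_mito != (loci$source == "mito")))
    stop("is_mito must agree with source == 'mito'")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- loci$locus_id
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(dosage)))
      stop("depth must have the same dimensions as dosage")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
    dimnames(depth) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, loci = loci, samples = samples, depth = depth),
            class = "genotype_matrix")
}

#' Number of samples / loci in a genotype matrix
#' @param g a \code{genotype_matrix}
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosage)

#' Subset a genotype matrix by sample and/or locus
#'
#' @param x a \code{genotype_matrix}
#' @param i sample index, logical mask or character vector of sample ids
#' @param j locus index, logical mask or character vector of locus ids
#' @param ... ignored
#' @return a \code{genotype_matrix}
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$loci[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE],
                  depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " loci", if (any(x$loci$is_mito)) sprintf(" (%d mito)", sum(x$loci$is_mito)),
      "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%; depth matrix: %s\n", 100 * miss,
              if (is.null(x$depth)) "absent" else "present"))
  pops <- unique(x$samples$population_id)
  cat("  populations: ", paste(utils::head(pops, 8), collapse = ", "),
      if (length(pops) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

#' Combine two genotype matrices over the same loci (row bind samples)
#' @param a,b \code{genotype_matrix} objects sharing identical loci
#' @return a \code{genotype_matrix}
#' @export
rbind_samples <- function(a, b) {
  stopifnot(identical(a$loci$locus_id, b$loci$locus_id))
  depth <- NULL
  if (!is.null(a$depth) && !is.null(b$depth)) depth <- rbind(a$depth, b$depth)
  genotype_matrix(rbind(a$dosage, b$dosage), a$loci,
                  rbind(a$samples, b$samples), depth = depth)
}

# per-sample fraction of loci with a non-missing call
sample_call_rate <- function(g) rowMeans(!is.na(g$dosage))

# per-locus fraction of samples with a non-missing call
locus_call_rate <- function(g) colMeans(!is.na(g$dosage))
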