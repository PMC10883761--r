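#' Principal component analysis of a genotype matrix
#'
#' Standard genotype PCA for population-structure visualisation: missing
#' calls are imputed with the locus mean dosage, each locus is centred by
#' twice its ALT frequency and (by default) scaled by
#' \eqn{\sqrt{2\hat p(1-\hat p)}}; loci fixed in the cohort are dropped.
#' Eigendecomposition is of the samples x samples covariance of the
#' standardized matrix; sample coordinates are the eigenvectors scaled by
#' the square root of their eigenvalues. For reproducible output the
#' largest-magnitude loading of each component is made positive.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param n_components number of components to return (default 10, capped at
#'   the available rank)
#' @param scale logical; divide by \eqn{\sqrt{2\hat p \hat q}}
#'   (variance standardization, the default) or centre only
#' @return object of class \code{genotype_pca}: list with \code{eigenvalues}
#'   (non-increasing), \code{coordinates} (samples x components),
#'   \code{n_loci_used}, \code{total_variance}
#' @export
genotype_pca <- function(g, n_components = 10, scale = TRUE) {
  if (n_samples(g) < 2) stop("PCA needs at least two samples")
  dos <- g$dosage
  nc <- colSums(!is.na(dos))
  p <- ifelse(nc > 0, colSums(dos, na.rm = TRUE) / (2 * nc), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci: PCA undefined")
  X <- dos[, poly, drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]  # mean imputation
  Z <- sweep(X, 2, mu)
  if (scale) Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  L <- ncol(Z)
  K <- tcrossprod(Z) / L
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(n_components, n_samples(g) - 1)
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  coords <- sweep(vecs, 2, sqrt(vals[seq_len(k)]), "*")
  rownames(coords) <- g$samples$sample_id
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = vals, coordinates = coords,
                 n_loci_used = L, total_variance = sum(Z^2) / L,
                 populations = g$samples$population_id),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- ncol(x$coordinates)
  pct <- 100 * x$eigenvalues[seq_len(min(k, 5))] / sum(x$eigenvalues)
  cat(sprintf("<genotype_pca> %d samples, %d loci used\n",
              nrow(x$coordinates), x$n_loci_used))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(pct), pct), collapse = ", "),
      "\n")
  invisible(x)
}

#' Scatter plot of the first two principal components
#'
#' @param x a \code{genotype_pca}
#' @param ... passed to \code{plot}
#' @export
plot.genotype_pca <- function(x, ...) {
  pops <- x$populations
  col <- if (is.null(pops) || all(is.na(pops))) 1
         else as.integer(factor(pops))
  pct <- 100 * x$eigenvalues[1:2] / sum(x$eigenvalues)
  plot(x$coordinates[, 1], x$coordinates[, 2], col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", pct[1]),
       ylab = sprintf("PC2 (%.1f%%)", pct[2]), ...)
  if (!is.null(pops) && !all(is.na(pops)))
    graphics::legend("topright", legend = levels(factor(pops)),
                     col = seq_along(levels(factor(pops))), pch = 19,
                     cex = 0.7)
  invisible(x)
}
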