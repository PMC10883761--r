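#' Pairwise genotype discordance and duplicate flagging
#'
#' For every sample pair, the fraction of shared non-missing autosomal loci
#' at which the two dosage codes differ. Pairs whose discordance is strictly
#' below \code{max_discordance} are flagged as duplicates (the discordance
#' between true duplicates reflects only genotyping error). Pairs sharing no
#' called loci have undefined discordance and are never flagged.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param max_discordance duplicate threshold (default 0.01)
#' @param pairs optional 2-column matrix/data frame of sample-id pairs to
#'   restrict the comparison to (all pairs otherwise)
#' @return data frame with columns \code{id1}, \code{id2}, \code{n_shared},
#'   \code{n_discordant}, \code{discordance}, \code{is_duplicate};
#'   duplicate connected components are attached as attribute
#'   \code{"duplicate_groups"}
#' @export
pairwise_discordance <- function(g, max_discordance = 0.01, pairs = NULL) {
  if (n_samples(g) < 2) stop("need at least two samples")
  auto <- !g$loci$is_mito
  dos <- g$dosage[, auto, drop = FALSE]
  ids <- g$samples$sample_id
  if (is.null(pairs)) {
    idx <- utils::combn(length(ids), 2)
    pairs <- cbind(ids[idx[1, ]], ids[idx[2, ]])
  } else {
    pairs <- as.matrix(pairs)
  }
  n <- nrow(pairs)
  n_shared <- integer(n); n_disc <- integer(n)
  for (k in seq_len(n)) {
    x <- dos[pairs[k, 1], ]; y <- dos[pairs[k, 2], ]
    sh <- !is.na(x) & !is.na(y)
    n_shared[k] <- sum(sh)
    n_disc[k] <- sum(x[sh] != y[sh])
  }
  disc <- ifelse(n_shared > 0, n_disc / n_shared, NA_real_)
  out <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                    n_shared = n_shared, n_discordant = n_disc,
                    discordance = disc,
                    is_duplicate = !is.na(disc) & disc < max_discordance,
                    stringsAsFactors = FALSE)
  attr(out, "duplicate_groups") <- duplicate_groups(out)
  out
}

#' Connected components of flagged duplicate pairs
#'
#' Duplicate flagging is pairwise; this groups flagged pairs into connected
#' components so near-transitive clusters (A~B, B~C) surface as one group.
#'
#' @param disc output of \code{\link{pairwise_discordance}}
#' @return list of character vectors, one per component of size >= 2
#' @export
duplicate_groups <- function(disc) {
  dup <- disc[disc$is_duplicate, , drop = FALSE]
  if (nrow(dup) == 0) return(list())
  ids <- unique(c(dup$id1, dup$id2))
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(dup)))
    parent[[find(dup$id1[k])]] <- find(dup$id2[k])
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

# unordered diploid genotypes over alleles {0 = ref, 1 = alt} with HWE probs
.genos <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
.geno_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
# can parent genotype `par` + some allele y form offspring genotype `off`?
.mendel_ok <- function(par, y, off) {
  any(vapply(par, function(x) setequal_multiset(c(x, y), off), logical(1)))
}
setequal_multiset <- function(a, b) identical(sort(a), sort(b))

#' Per-locus non-exclusion probability
#'
#' The probability that a random unrelated individual (or pair) is NOT
#' excluded by this locus, computed by exhaustive enumeration over genotype
#' configurations under Hardy-Weinberg proportions at ALT frequency \code{p}:
#' \describe{
#'   \item{identity}{probability two independent individuals share a
#'     genotype, \eqn{\sum_g P(g)^2}}
#'   \item{first_parent}{probability a random candidate shares at least one
#'     allele with a random offspring (no other parent known)}
#'   \item{second_parent}{probability a random candidate is compatible as
#'     the second parent of a random offspring given its true first parent
#'     (expectation over the joint parent-offspring distribution under
#'     Mendelian transmission)}
#'   \item{parent_pair}{probability a random candidate pair could jointly
#'     have produced a random offspring}
#' }
#'
#' @param p ALT allele frequency, strictly inside (0, 1)
#' @param mode one of \code{"identity"}, \code{"first_parent"},
#'   \code{"second_parent"}, \code{"parent_pair"}
#' @return probability in (0, 1]
#' @export
locus_nonexclusion <- function(p, mode = c("identity", "first_parent",
                                           "second_parent", "parent_pair")) {
  mode <- match.arg(mode)
  if (p <= 0 || p >= 1)
    stop("locus is uninformative at p = 0 or 1; non-exclusion undefined")
  G <- .genos
  P <- .geno_probs(p)
  share <- function(a, b) length(intersect(a, b)) > 0
  if (mode == "identity")
    return(sum(P^2))
  if (mode == "first_parent") {
    tot <- 0
    for (o in 1:3) for (cd in 1:3)
      if (share(G[[o]], G[[cd]])) tot <- tot + P[o] * P[cd]
    return(tot)
  }
  # joint distribution of (known parent M, offspring O) via a random true
  # second parent and Mendelian transmission
  joint <- matrix(0, 3, 3)  # rows M, cols O
  for (m in 1:3) for (f in 1:3) {
    for (am in .genos[[m]]) for (af in .genos[[f]]) {
      o <- sort(c(am, af))
      oi <- which(vapply(G, function(gg) identical(gg, o), logical(1)))
      joint[m, oi] <- joint[m, oi] + P[m] * P[f] * 0.25
    }
  }
  if (mode == "second_parent") {
    tot <- 0
    for (m in 1:3) for (o in 1:3) {
      if (joint[m, o] == 0) next
      pc <- 0
      for (cd in 1:3) {
        ok <- any(vapply(G[[cd]], function(y) .mendel_ok(G[[m]], y, G[[o]]),
                         logical(1)))
        if (ok) pc <- pc + P[cd]
      }
      tot <- tot + joint[m, o] * pc
    }
    return(tot)
  }
  # parent_pair: offspring marginal from joint; candidate pair both random
  po <- colSums(joint)
  tot <- 0
  for (o in 1:3) {
    pc <- 0
    for (c1 in 1:3) for (c2 in 1:3) {
      ok <- FALSE
      for (y1 in G[[c1]]) for (y2 in G[[c2]])
        if (setequal_multiset(c(y1, y2), G[[o]])) ok <- TRUE
      if (ok) pc <- pc + P[c1] * P[c2]
    }
    tot <- tot + po[o] * pc
  }
  tot
}

#' Combined non-exclusion probability across loci
#'
#' Product over loci of \code{\link{locus_nonexclusion}}, accumulated in
#' log10 so panel-scale products (hundreds of loci) do not underflow.
#'
#' @param p vector of ALT frequencies, all strictly inside (0, 1)
#' @param mode passed to \code{\link{locus_nonexclusion}}
#' @return list with \code{log10} (exact), \code{prob} (may denormalize for
#'   very small values) and \code{scientific}, a formatted string
#' @export
combined_nonexclusion <- function(p, mode) {
  if (length(p) == 0) stop("no loci supplied")
  if (any(p <= 0 | p >= 1)) stop("all frequencies must lie strictly in (0,1)")
  l10 <- sum(log10(vapply(p, locus_nonexclusion, numeric(1), mode = mode)))
  mant <- 10^(l10 - floor(l10))
  list(log10 = l10, prob = 10^l10,
       scientific = sprintf("%.3fE%+04d", mant, as.integer(floor(l10))))
}

#' Opposing-homozygote count between two samples
#'
#' Loci where one sample is homozygous reference and the other homozygous
#' alternate — a Mendelian impossibility for a true parent-offspring pair
#' barring genotyping error.
#'
#' @param off,cand dosage vectors over the same loci
#' @return list with \code{oh_count} and \code{n_compared} (shared called
#'   loci)
#' @export
opposing_homozygotes <- function(off, cand) {
  sh <- !is.na(off) & !is.na(cand)
  if (!any(sh)) stop("no shared called loci between the pair")
  oh <- sum((off[sh] == 0L & cand[sh] == 2L) |
              (off[sh] == 2L & cand[sh] == 0L))
  list(oh_count = oh, n_compared = sum(sh))
}

#' Exclusion-based single-parent assignment
#'
#' Screens every candidate against the offspring by opposing-homozygote
#' count. A candidate passes iff
#' \code{oh_count <= ceiling(2 * error_rate * n_compared)} (an error in
#' either member of the pair can create an opposing homozygote, hence the
#' factor 2); \code{threshold = "binomial"} instead uses the 99.9th
#' percentile of Binomial(n_compared, 2 * error_rate / 3), the expected
#' opposing-homozygote rate when errors flip uniformly to one of the two
#' other codes. The final call is the unique passer with minimal
#' \code{oh_count}; two or more passers tied at the minimum give
#' \code{ambiguous}; no passer gives \code{unassigned}.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param offspring_id sample id of the offspring
#' @param candidate_ids sample ids of the candidate parents (non-empty)
#' @param error_rate assumed per-genotype error rate (default 0.01)
#' @param threshold \code{"ceiling"} (default) or \code{"binomial"}
#' @return data frame (one row per candidate) with \code{oh_count},
#'   \code{n_compared}, \code{mismatch_rate}, \code{pass}; the final call is
#'   attached as attributes \code{"status"} (\code{assigned},
#'   \code{ambiguous} or \code{unassigned}) and \code{"assigned_id"}
#' @export
assign_parent <- function(g, offspring_id, candidate_ids,
                          error_rate = 0.01,
                          threshold = c("ceiling", "binomial")) {
  threshold <- match.arg(threshold)
  if (length(candidate_ids) == 0) stop("candidate set is empty")
  off <- g$dosage[offspring_id, ]
  res <- lapply(candidate_ids, function(cid) {
    oh <- opposing_homozygotes(off, g$dosage[cid, ])
    thr <- if (threshold == "ceiling") ceiling(2 * error_rate * oh$n_compared)
           else stats::qbinom(0.999, oh$n_compared, 2 * error_rate / 3)
    data.frame(offspring_id = offspring_id, candidate_id = cid,
               oh_count = oh$oh_count, n_compared = oh$n_compared,
               mismatch_rate = oh$oh_count / oh$n_compared,
               pass = oh$oh_count <= thr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  passers <- res[res$pass, , drop = FALSE]
  if (nrow(passers) == 0) {
    status <- "unassigned"; assigned <- NA_character_
  } else {
    best <- passers[passers$oh_count == min(passers$oh_count), , drop = FALSE]
    if (nrow(best) == 1) {
      status <- "assigned"; assigned <- best$candidate_id
    } else {
      status <- "ambiguous"; assigned <- NA_character_
    }
  }
  attr(res, "status") <- status
  attr(res, "assigned_id") <- assigned
  res
}

#' Assign a parent to each of several offspring
#'
#' @inheritParams assign_parent
#' @param offspring_ids vector of offspring sample ids
#' @return data frame with one row per offspring: \code{offspring_id},
#'   \code{assigned_id}, \code{status}, \code{oh_count} of the assignment
#' @export
assign_parentage <- function(g, offspring_ids, candidate_ids,
                             error_rate = 0.01) {
  rows <- lapply(offspring_ids, function(oid) {
    r <- assign_parent(g, oid, candidate_ids, error_rate = error_rate)
    aid <- attr(r, "assigned_id")
    data.frame(offspring_id = oid, assigned_id = aid,
               status = attr(r, "status"),
               oh_count = if (!is.na(aid))
                 r$oh_count[r$candidate_id == aid] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict to highly informative loci within a herd
#'
#' Loci with within-herd minor allele frequency strictly above
#' \code{maf_min} (default 0.3) — the informative subset used when assigning
#' parentage inside a single herd.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param herd_ids sample ids of the herd (at least 2)
#' @param maf_min strict MAF lower bound
#' @return character vector of kept locus ids
#' @export
within_herd_maf_subset <- function(g, herd_ids, maf_min = 0.3) {
  if (length(herd_ids) < 2) stop("a herd needs at least two samples")
  qc <- compute_locus_qc(g[herd_ids, ])
  qc$locus_id[!is.na(qc$maf) & qc$maf > maf_min]
}

#' Concordance of assignments with known truth
#'
#' Fraction of offspring whose assigned parent equals the true parent;
#' ambiguous and unassigned offspring count as discordant.
#'
#' @param assignments output of \code{\link{assign_parentage}}
#' @param truth data frame with columns \code{offspring_id} and
#'   \code{dam_id} (the true parent)
#' @return fraction in [0, 1]
#' @export
concordance <- function(assignments, truth) {
  if (is.null(truth) || nrow(truth) == 0) stop("truth table is empty")
  m <- match(assignments$offspring_id, truth$offspring_id)
  if (any(is.na(m))) stop("truth table lacks some offspring")
  mean(assignments$status == "assigned" &
         !is.na(assignments$assigned_id) &
         assignments$assigned_id == truth$dam_id[m])
}
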