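# 16S ASV community operations: taxonomic filtering, rarefaction,
# dominant-phylum relative abundances, richness, dissimilarity, ordination
# and compositional transforms.

#' Remove undefined and archaeal ASVs
#'
#' Drops ASV columns whose taxonomy is undefined (missing, blank,
#' "undefined", "unclassified" or NA at kingdom or phylum rank) or assigned
#' to Archaea. Counts of the surviving ASVs are untouched.
#'
#' @param counts integer matrix, samples x ASVs (column names are ASV ids).
#' @param taxonomy data.frame with columns \code{asv}, \code{kingdom},
#'   \code{phylum}.
#' @return list with \code{counts} (filtered matrix), \code{taxonomy}
#'   (matching rows) and \code{removed} (dropped ASV ids).
#' @export
filter_taxa <- function(counts, taxonomy) {
  stopifnot(all(colnames(counts) %in% taxonomy$asv))
  tax <- taxonomy[match(colnames(counts), taxonomy$asv), ]
  undef <- function(x) is.na(x) | trimws(x) == "" |
    tolower(x) %in% c("undefined", "unclassified")
  drop <- undef(tax$kingdom) | undef(tax$phylum) |
    tolower(tax$kingdom) == "archaea"
  drop[is.na(drop)] <- TRUE
  list(counts = counts[, !drop, drop = FALSE],
       taxonomy = tax[!drop, , drop = FALSE],
       removed = colnames(counts)[drop])
}

#' Rarefy ASV counts to a common depth
#'
#' Samples with fewer than \code{depth} total reads are removed; the rest
#' are subsampled without replacement to exactly \code{depth} reads
#' (multivariate-hypergeometric draw, via \code{vegan::rrarefy} under a
#' private seeded RNG stream so results are reproducible).
#'
#' @param counts integer matrix, samples x ASVs.
#' @param depth target reads per sample (default 5000).
#' @param seed integer seed controlling the subsampling.
#' @return list with \code{counts} (rarefied survivors, every row summing to
#'   \code{depth}) and \code{dropped} (ids of samples below depth).
#' @export
rarefy_counts <- function(counts, depth = 5000, seed = 1) {
  stopifnot(depth >= 1)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) warning("all samples fall below the rarefaction depth")
  kept <- counts[keep, , drop = FALSE]
  rare <- with_seed(seed, vegan::rrarefy(kept, depth))
  storage.mode(rare) <- "integer"
  list(counts = rare, dropped = rownames(counts)[!keep])
}

#' Dominant-phylum relative abundance table
#'
#' Aggregates ASV counts to phylum level and expresses them as per-sample
#' relative abundances (each phylum's reads divided by the sample's total
#' reads). The dominant set comprises phyla that occur in every sample AND
#' rank in the top 10% of phyla by mean relative abundance
#' (\code{ceiling(0.10 * P)} phyla, ties broken by total reads then name);
#' all remaining phyla are summed into \code{"Other"}.
#'
#' @param counts integer matrix, samples x ASVs (taxa-filtered, rarefied).
#' @param taxonomy data.frame with \code{asv} and \code{phylum} columns.
#' @param top_fraction fraction of phyla deemed rankable as dominant
#'   (default 0.10).
#' @return list with \code{rel_abund} (samples x (dominant + "Other"),
#'   rows summing to 1) and \code{dominant} (character vector).
#' @export
dominant_phyla <- function(counts, taxonomy, top_fraction = 0.10) {
  tax <- taxonomy[match(colnames(counts), taxonomy$asv), ]
  phy <- t(rowsum(t(counts), tax$phylum))  # samples x phyla
  totals <- rowSums(phy)
  if (any(totals == 0)) stop("sample(s) with zero reads: ",
                             paste(rownames(phy)[totals == 0], collapse = ", "))
  rel <- phy / totals
  ubiquitous <- colSums(phy > 0) == nrow(phy)
  p_total <- ncol(phy)
  n_top <- ceiling(top_fraction * p_total)
  ord <- order(-colMeans(rel), -colSums(phy), colnames(phy))
  top <- colnames(phy)[ord[seq_len(min(n_top, p_total))]]
  dominant <- sort(intersect(top, colnames(phy)[ubiquitous]))
  if (!length(dominant))
    warning("no phylum is present in every sample; all mass in 'Other'")
  other <- 1 - rowSums(rel[, dominant, drop = FALSE])
  out <- cbind(rel[, dominant, drop = FALSE], Other = other)
  list(rel_abund = out, dominant = dominant)
}

#' ASV richness per sample
#'
#' Number of ASVs with a positive count in each (rarefied) sample.
#'
#' @param counts integer matrix, samples x ASVs.
#' @return named integer vector.
#' @export
asv_richness <- function(counts) {
  setNames(as.integer(rowSums(counts > 0)), rownames(counts))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)}; bounded in [0, 1],
#' symmetric, zero on the diagonal. Computed via \code{vegan::vegdist}.
#'
#' @param counts non-negative matrix, samples x taxa, no all-zero rows.
#' @return a symmetric matrix of class \code{matrix} with zero diagonal
#'   (sample ids as dimnames).
#' @export
bray_curtis <- function(counts) {
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(counts)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (monotone regression of fitted on observed
#' dissimilarities) via \code{vegan::metaMDS} on a precomputed matrix, with
#' random restarts under a seeded private RNG stream. Axes are centred,
#' rotated to principal axes, and signed so the first nonzero loading of
#' each axis is positive; the first two axes are the standard
#' community-composition responses.
#'
#' @param d symmetric dissimilarity matrix (e.g. \code{\link{bray_curtis}}).
#' @param k number of axes (default 2).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 20).
#' @return list with \code{scores} (samples x k), \code{stress} (Kruskal
#'   stress-1, 0-1 scale), \code{converged}, and \code{seed}.
#' @export
nmds_ordination <- function(d, k = 2, seed = 1, n_restarts = 20) {
  stopifnot(k >= 1)
  dd <- stats::as.dist(d)
  fit <- with_seed(seed, vegan::metaMDS(
    dd, k = k, trymax = n_restarts, trace = 0, autotransform = FALSE,
    wascores = FALSE))
  sc <- scale(fit$points, center = TRUE, scale = FALSE)
  pr <- prcomp(sc, center = FALSE)
  sc <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(sc))) {
    nz <- which(abs(sc[, j]) > 1e-12)
    if (length(nz) && sc[nz[1L], j] < 0) sc[, j] <- -sc[, j]
  }
  colnames(sc) <- paste0("NMDS", seq_len(k))
  list(scores = sc, stress = fit$stress, converged = isTRUE(fit$converged),
       seed = seed)
}

#' Hellinger transform
#'
#' Square root of relative abundances: entry \code{sqrt(x_ij / rowsum_i)}.
#' Each transformed row has unit Euclidean norm, which makes community
#' matrices suitable for Euclidean-based redundancy analysis.
#'
#' @param counts non-negative matrix with positive row sums.
#' @return transformed numeric matrix of the same shape.
#' @export
hellinger_transform <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs <= 0)) stop("row(s) with non-positive sum")
  sqrt(counts / rs)
}

#' Centred log-ratio transform
#'
#' Per row: \code{ln(x_i) - mean(ln(x))} after multiplicative replacement of
#' zeros. Transformed rows sum to zero. The default pseudocount is half the
#' smallest nonzero relative abundance in the matrix; zeros are replaced by
#' it and nonzero parts rescaled so rows still sum to one before logging.
#'
#' @param x non-negative matrix, samples x parts.
#' @param pseudocount replacement value on the relative-abundance scale;
#'   \code{NULL} (default) uses half the smallest nonzero relative abundance.
#' @return CLR-transformed matrix (rows sum to 0).
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  rel <- x / rowSums(x)
  if (any(rel == 0)) {
    delta <- pseudocount %||% (0.5 * min(rel[rel > 0]))
    rel <- t(apply(rel, 1L, function(r) {
      z <- r == 0
      r[!z] <- r[!z] * (1 - sum(z) * delta)
      r[z] <- delta
      r
    }))
  }
  lx <- log(rel)
  sweep(lx, 1L, rowMeans(lx))
}
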