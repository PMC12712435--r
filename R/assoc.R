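# Association statistics on the joined plot frame: PCA axis selection,
# Spearman and partial Spearman correlation tables, collinearity screening.

#' Leading principal-component scores of a variable block
#'
#' Centres and unit-scales the variables, runs PCA, and returns the scores
#' of the smallest number of leading axes whose cumulative explained
#' variance exceeds \code{variance_threshold} (default 0.8). Constant
#' variables are dropped with a warning. Used to collapse collinear
#' predictor groups before variation partitioning.
#'
#' @param block numeric matrix or data.frame, plots x variables, no missing
#'   values.
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @return list with \code{scores} (plots x n_axes), \code{n_axes},
#'   \code{variance_share} (per retained axis) and \code{loadings}.
#' @export
pca_leading_axes <- function(block, variance_threshold = 0.8) {
  x <- as.matrix(block)
  stopifnot(ncol(x) >= 2)
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- which(cumsum(share) > variance_threshold)[1L]
  if (is.na(n_axes)) n_axes <- length(share)
  list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
       n_axes = n_axes,
       variance_share = share[seq_len(n_axes)],
       loadings = pc$rotation[, seq_len(n_axes), drop = FALSE])
}

# Spearman rho and its two-sided p (t approximation, mid-ranks for ties).
spearman_one <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- suppressWarnings(cor(rank(x[ok]), rank(y[ok])))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_, n = n))
  p <- two_sided_t_p(rho, n - 2L)
  c(rho = rho, p = p, n = n)
}

# Guarantee usable, unique column names (missing or blank names are
# replaced positionally).
ensure_colnames <- function(m, prefix) {
  cn <- colnames(m)
  if (is.null(cn)) cn <- rep("", ncol(m))
  blank <- is.na(cn) | cn == ""
  cn[blank] <- paste0(prefix, which(blank))
  colnames(m) <- make.unique(cn)
  m
}

two_sided_t_p <- function(r, df) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tval), df)
}

#' Spearman correlation table with Bonferroni correction
#'
#' All pairwise Spearman rank correlations between columns of \code{X} and
#' columns of \code{Y}, with mid-ranks for ties, two-sided p-values from the
#' t approximation, and a Bonferroni significance flag at level
#' \code{alpha / m} where \code{m} is the number of emitted pairs.
#'
#' @param X,Y numeric matrices or data.frames sharing row order.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns \code{x}, \code{y}, \code{rho}, \code{p},
#'   \code{n}, \code{significant} (Bonferroni-adjusted flag) and attribute
#'   \code{"m"} (number of tests).
#' @export
spearman_matrix <- function(X, Y, alpha = 0.05) {
  X <- ensure_colnames(as.matrix(X), "x")
  Y <- ensure_colnames(as.matrix(Y), "y")
  pairs <- expand.grid(x = colnames(X), y = colnames(Y),
                       stringsAsFactors = FALSE)
  res <- t(mapply(function(i, j) spearman_one(X[, i], Y[, j]),
                  pairs$x, pairs$y))
  m <- nrow(pairs)
  out <- data.frame(pairs, rho = res[, "rho"], p = res[, "p"],
                    n = as.integer(res[, "n"]),
                    significant = !is.na(res[, "p"]) & res[, "p"] <= alpha / m,
                    row.names = NULL)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Partial Spearman correlation controlling for confounders
#'
#' Rank-transforms every variable (mid-ranks), then computes the partial
#' correlation of each X/Y pair given the confounder block \code{Z} by
#' inversion of the rank-Pearson correlation matrix; p-values use the t
#' distribution with \code{n - 2 - ncol(Z)} degrees of freedom. With an
#' empty \code{Z} this reduces exactly to the ordinary Spearman correlation.
#' The canonical confounder set in cross-biome soil work is pH, soil
#' moisture, mean annual temperature, mean annual precipitation and the soil
#' C:N ratio.
#'
#' @param X,Y numeric matrices or data.frames sharing row order.
#' @param Z confounder matrix/data.frame (may have zero columns).
#' @param alpha family-wise significance level for the Bonferroni flag.
#' @return data.frame like \code{\link{spearman_matrix}} with an extra
#'   \code{df} column.
#' @export
partial_spearman <- function(X, Y, Z, alpha = 0.05) {
  X <- ensure_colnames(as.matrix(X), "x")
  Y <- ensure_colnames(as.matrix(Y), "y")
  Z <- as.matrix(Z)
  ok <- stats::complete.cases(X, Y, Z)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  Z <- Z[ok, , drop = FALSE]
  n <- nrow(X); k <- ncol(Z)
  rz <- apply(Z, 2L, rank)
  pairs <- expand.grid(x = colnames(X) %||% seq_len(ncol(X)),
                       y = colnames(Y) %||% seq_len(ncol(Y)),
                       stringsAsFactors = FALSE)
  m <- nrow(pairs)
  rows <- lapply(seq_len(m), function(idx) {
    rx <- rank(X[, pairs$x[idx]]); ry <- rank(Y[, pairs$y[idx]])
    if (k == 0) {
      rho <- suppressWarnings(cor(rx, ry))
      return(c(rho = rho, p = two_sided_t_p(rho, n - 2L), df = n - 2L))
    }
    R <- suppressWarnings(cor(cbind(rx, ry, rz)))
    if (any(is.na(R))) return(c(rho = NA_real_, p = NA_real_, df = n - 2 - k))
    P <- tryCatch(solve(R), error = function(e) {
      # distinguish collinear confounders (caller error) from a pair that
      # is perfectly explained by Z (degenerate mediation -> flagged NA)
      zz_singular <- inherits(tryCatch(solve(R[-(1:2), -(1:2),
                                               drop = FALSE]),
                                       error = function(e2) e2), "error")
      if (zz_singular)
        stop("singular rank-correlation matrix; collinear confounders ",
             "among: ", paste(colnames(Z), collapse = ", "), call. = FALSE)
      NULL
    })
    if (is.null(P))
      return(c(rho = NA_real_, p = NA_real_, df = n - 2 - k))
    rho <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
    df <- n - 2L - k
    c(rho = rho, p = two_sided_t_p(rho, df), df = df)
  })
  res <- do.call(rbind, rows)
  out <- data.frame(pairs, rho = res[, "rho"], p = res[, "p"],
                    n = n, df = as.integer(res[, "df"]),
                    significant = !is.na(res[, "p"]) & res[, "p"] <= alpha / m,
                    row.names = NULL)
  attr(out, "m") <- m
  attr(out, "confounders") <- colnames(Z)
  out
}

#' Greedy collinearity screen
#'
#' Repeatedly finds the variable pair with the largest absolute (Spearman)
#' correlation at or above \code{cutoff} and drops the member of the pair
#' with the larger mean absolute correlation to all other variables, until
#' no pair reaches the cutoff. Deterministic given column order; mirrors the
#' pairwise-elimination heuristic popularised by caret's
#' \code{findCorrelation}.
#'
#' @param X numeric matrix or data.frame, >= 2 columns.
#' @param cutoff absolute correlation threshold (default 0.7).
#' @param method correlation type passed to \code{cor} (default
#'   \code{"spearman"}).
#' @return list with \code{kept} and \code{dropped} column names.
#' @export
collinearity_screen <- function(X, cutoff = 0.7, method = "spearman") {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  R <- abs(suppressWarnings(cor(X, method = method)))
  dimnames(R) <- list(nm, nm)
  diag(R) <- 0
  alive <- rep(TRUE, ncol(X))
  repeat {
    Ra <- R[alive, alive, drop = FALSE]
    if (max(Ra) < cutoff || sum(alive) < 2) break
    ij <- which(Ra == max(Ra), arr.ind = TRUE)[1L, ]
    cand <- rownames(Ra)[ij]
    mean_abs <- rowMeans(R[cand, alive, drop = FALSE])
    drop_nm <- cand[which.max(mean_abs)]
    alive[match(drop_nm, nm)] <- FALSE
  }
  list(kept = nm[alive], dropped = nm[!alive])
}
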