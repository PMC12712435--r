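# Variation partitioning across predictor groups via redundancy analysis,
# with permutation tests of each group's unique contribution by partial RDA.

# Column-centre a response matrix.
centre_mat <- function(Y) {
  Y <- as.matrix(Y)
  sweep(Y, 2L, colMeans(Y))
}

# Redundancy-analysis R^2 of (possibly multivariate) centred response on a
# predictor matrix: trace of fitted sums of squares over total.
rda_r2 <- function(Yc, X) {
  qx <- qr(cbind(1, as.matrix(X)))
  fit <- qr.fitted(qx, Yc)
  sum(fit^2) / sum(Yc^2)
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Variation partitioning across predictor groups
#'
#' Decomposes the redundancy-analysis explained variance of a (multivariate)
#' response into the unique and shared fractions attributable to each
#' predictor group by inclusion-exclusion over all non-empty group subsets.
#' Community responses should be Hellinger-transformed beforehand
#' (\code{\link{hellinger_transform}}) so that the Euclidean geometry of RDA
#' is appropriate. Fractions are computed both from raw R-squared (for
#' which the 2^g - 1 Venn fractions plus the residual sum exactly to 1) and
#' from Ezekiel-adjusted R-squared (standard practice; fractions may be
#' slightly negative and are reported as-is, with a zero-floored display
#' column).
#'
#' @param response numeric matrix/data.frame, plots x responses (complete
#'   cases only).
#' @param groups named list of predictor blocks (plots x variables each),
#'   sharing row order with \code{response}; land cover should be supplied
#'   one-hot encoded with a reference level dropped.
#' @return list with:
#'   \item{fractions}{data.frame: one row per Venn atom (named by the
#'     groups it belongs to), raw and adjusted fraction, zero-floored
#'     adjusted fraction.}
#'   \item{unique}{named vector of each group's unique adjusted fraction
#'     (= adjR2(all) - adjR2(all minus group)).}
#'   \item{residual}{raw residual fraction 1 - R2(all groups).}
#'   \item{r2_subsets}{raw and adjusted R2 for every non-empty subset.}
#' @export
varpart_groups <- function(response, groups) {
  Yc <- centre_mat(response)
  g <- length(groups)
  stopifnot(g >= 1, !is.null(names(groups)))
  Xs <- lapply(groups, as.matrix)
  n <- nrow(Yc)
  p_tot <- sum(vapply(Xs, ncol, integer(1)))
  if (n <= p_tot + 1)
    stop("too few rows (", n, ") for ", p_tot, " predictors: rank deficiency")
  subsets <- unlist(lapply(seq_len(g), function(k)
    combn(g, k, simplify = FALSE)), recursive = FALSE)
  sub_key <- vapply(subsets, function(s)
    paste(names(groups)[s], collapse = "+"), character(1))
  r2_raw <- vapply(subsets, function(s)
    rda_r2(Yc, do.call(cbind, Xs[s])), numeric(1))
  p_sub <- vapply(subsets, function(s)
    sum(vapply(Xs[s], ncol, integer(1))), numeric(1))
  r2_adj <- adj_r2(r2_raw, n, p_sub)
  names(r2_raw) <- names(r2_adj) <- sub_key

  # union measure m(U_{i in S}) = R2(S); intersection measure by Moebius:
  # m(Int_S) = sum over non-empty U subset S of (-1)^(|U|+1) R2(U)
  # combn(x, k) misreads a length-1 numeric x as seq_len(x); always
  # enumerate positions and map back
  subsets_of <- function(x, k) lapply(
    combn(seq_along(x), k, simplify = FALSE), function(i) x[i])
  inter <- function(S, r2) {
    us <- unlist(lapply(seq_along(S), function(k)
      subsets_of(S, k)), recursive = FALSE)
    sum(vapply(us, function(U) {
      key <- paste(names(groups)[U], collapse = "+")
      (-1)^(length(U) + 1) * r2[key]
    }, numeric(1)))
  }
  # atom "exactly the groups in C": sum over T subset of complement of C of
  # (-1)^|T| m(Int_{C union T})
  atom <- function(C, r2) {
    rest <- setdiff(seq_len(g), C)
    ts <- c(list(integer(0)), unlist(lapply(seq_along(rest), function(k)
      subsets_of(rest, k)), recursive = FALSE))
    sum(vapply(ts, function(T)
      (-1)^length(T) * inter(sort(c(C, T)), r2), numeric(1)))
  }
  atoms_raw <- vapply(subsets, atom, numeric(1), r2 = r2_raw)
  atoms_adj <- vapply(subsets, atom, numeric(1), r2 = r2_adj)
  all_key <- sub_key[length(sub_key)]
  uniq <- vapply(seq_len(g), function(i) {
    if (g == 1) return(unname(r2_adj[all_key]))
    rest_key <- paste(names(groups)[setdiff(seq_len(g), i)], collapse = "+")
    unname(r2_adj[all_key] - r2_adj[rest_key])
  }, numeric(1))
  names(uniq) <- names(groups)
  list(
    fractions = data.frame(
      atom = sub_key,
      raw = atoms_raw,
      adjusted = atoms_adj,
      adjusted_display = pmax(atoms_adj, 0),
      row.names = NULL),
    unique = uniq,
    residual = 1 - unname(r2_raw[all_key]),
    r2_subsets = data.frame(subset = sub_key, raw = unname(r2_raw),
                            adjusted = unname(r2_adj), n_pred = p_sub,
                            row.names = NULL))
}

#' Permutation test of a predictor group by partial redundancy analysis
#'
#' Tests whether \code{group} explains response variation beyond the
#' \code{conditioners} block. Response and group are residualised on the
#' conditioners; the pseudo-F statistic compares constrained to residual
#' variance, and significance comes from permuting the residuals of the
#' reduced (conditioner-only) model (Freedman-Lane scheme):
#' \code{p = (1 + #{F* >= F}) / (1 + n_perm)}, so p can never be zero.
#'
#' @param response numeric matrix/data.frame, plots x responses.
#' @param group predictor block under test (plots x variables).
#' @param conditioners covariate block to condition on; may be \code{NULL}
#'   or have zero columns for an unconditioned test.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with \code{F}, \code{p}, \code{df} (numerator,
#'   denominator), \code{n_perm}, \code{seed}.
#' @export
partial_rda_test <- function(response, group, conditioners = NULL,
                             n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 1)
  Yc <- centre_mat(response)
  X <- as.matrix(group)
  n <- nrow(Yc)
  Z <- if (is.null(conditioners) || NCOL(conditioners) == 0)
    matrix(numeric(0), n, 0) else as.matrix(conditioners)
  qz <- qr(cbind(rep(1, n), Z))
  Yr <- qr.resid(qz, Yc)       # residuals of the reduced model
  Xr <- qr.resid(qz, X)
  qx <- qr(Xr)
  df1 <- qx$rank
  df2 <- n - ncol(Z) - df1 - 1L  # residual df of the full model
  fstat <- function(Ymat) {
    fit <- qr.fitted(qx, Ymat)
    ss_exp <- sum(fit^2)
    ss_res <- sum(Ymat^2) - ss_exp
    if (ss_res <= 0) return(NA_real_)
    (ss_exp / df1) / (ss_res / df2)
  }
  f_obs <- fstat(Yr)
  if (is.na(f_obs)) stop("zero residual variance; p-value undefined")
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      # permute reduced-model residuals, then re-partial the conditioners
      # out of the permuted response before forming the statistic
      Yp <- qr.resid(qz, Yr[sample.int(n), , drop = FALSE])
      fp <- fstat(Yp)
      if (!is.na(fp) && fp >= f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm),
       df = c(df1, df2), n_perm = n_perm, seed = seed)
}
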