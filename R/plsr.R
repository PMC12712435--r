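# Ensemble partial least squares regression for spectra-to-trait retrieval:
# NIPALS fitting, PRESS-based component selection, MAE outlier screening,
# ensembles with predictive uncertainty, evaluation metrics, VIP scores and
# vegetation-index baselines.

#' Fit a single-response PLSR model
#'
#' NIPALS partial least squares regression of one response on a (typically
#' wide, collinear) predictor matrix. Predictors and response are
#' mean-centred but not variance-scaled: vector-normalised spectra are
#' already on a comparable scale, and scaling would re-weight absorption
#' features. Regression coefficients are returned on the original predictor
#' scale together with per-predictor VIP scores.
#'
#' @param X numeric matrix, observations x predictors (e.g. plots x
#'   wavelengths), all finite.
#' @param y numeric response vector with positive variance.
#' @param n_components number of latent components; at most
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return An object of class \code{plsr_model}: list with
#'   \code{n_components}, \code{coef} (length p), \code{intercept},
#'   \code{weights} / \code{loadings} / \code{y_loadings} / \code{score_ss}
#'   (per component), \code{vip} (length p), \code{x_mean}, \code{y_mean}.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, all(is.finite(X)), all(is.finite(y)))
  if (stats::var(y) == 0) stop("zero-variance response")
  a_max <- min(n - 1L, p)
  if (n_components > a_max)
    stop("n_components (", n_components, ") exceeds min(n-1, p) = ", a_max)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  W <- P <- matrix(0, p, n_components)
  qv <- tt <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {  # response fully deflated; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      qv <- qv[seq_len(a - 1L)]; tt <- tt[seq_len(a - 1L)]
      n_components <- a - 1L
      break
    }
    w <- w / nw
    t_s <- as.numeric(E %*% w)
    tts <- sum(t_s^2)
    p_l <- crossprod(E, t_s) / tts
    q_l <- sum(f * t_s) / tts
    E <- E - tcrossprod(t_s, p_l)
    f <- f - q_l * t_s
    W[, a] <- w; P[, a] <- p_l; qv[a] <- q_l; tt[a] <- tts
    Tm[, a] <- t_s
  }
  beta <- plsr_coef_path(W, P, qv, n_components)[, n_components]
  ssy <- qv^2 * tt                       # y-variance captured per component
  vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  structure(list(
    n_components = n_components, coef = beta,
    intercept = y_mean - sum(x_mean * beta),
    weights = W, loadings = P, y_loadings = qv, score_ss = tt,
    scores = Tm, vip = vip, x_mean = x_mean, y_mean = y_mean,
    wavelengths = numeric_colnames(X)), class = "plsr_model")
}

# Wavelength grid recovered from numeric column names, if present.
numeric_colnames <- function(X) {
  cn <- colnames(X)
  if (is.null(cn)) return(NULL)
  wl <- suppressWarnings(as.numeric(cn))
  if (anyNA(wl)) NULL else wl
}

# Coefficient vectors for every component count 1..A (p x A matrix); the
# PRESS search needs held-out predictions at each truncation in one pass.
plsr_coef_path <- function(W, P, qv, A) {
  out <- matrix(0, nrow(W), A)
  for (a in seq_len(A)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    M <- crossprod(P[, seq_len(a), drop = FALSE], Wa)  # a x a, unit lower-tri
    out[, a] <- Wa %*% solve(M, qv[seq_len(a)])
  }
  out
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$coef))
    stop("newdata has ", ncol(Xn), " predictors; model expects ",
         length(object$coef))
  as.numeric(Xn %*% object$coef) + object$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d predictors\n",
              x$n_components, length(x$coef)))
  invisible(x)
}

#' Select the number of PLSR components by permuted PRESS
#'
#' Jackknife-style data permutation: for each of \code{n_perm} draws, a
#' random \code{split_fraction} subset is fitted with up to
#' \code{max_components} components and the prediction residual error sum of
#' squares (PRESS) of the held-out remainder is recorded for every component
#' count. Selection rule (default \code{"onese"}): the smallest component
#' count whose mean PRESS lies within one standard error of the global
#' minimum; \code{"min"} takes the arg-min instead.
#'
#' @param X,y calibration predictors and response.
#' @param max_components largest component count to scan (capped to the
#'   subset size); default 15.
#' @param n_perm number of random splits (default 200).
#' @param split_fraction fraction fitted per draw (default 0.7).
#' @param seed integer seed.
#' @param rule \code{"onese"} or \code{"min"}.
#' @return list with \code{n_components}, \code{press_mean},
#'   \code{press_se} (per component), \code{rule}, \code{seed}.
#' @export
press_select <- function(X, y, max_components = 15, n_perm = 200,
                         split_fraction = 0.7, seed = 1,
                         rule = c("onese", "min")) {
  rule <- match.arg(rule)
  stopifnot(n_perm >= 2, max_components >= 1)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_train <- floor(split_fraction * n)
  A <- min(max_components, n_train - 1L, ncol(X))
  if (A < max_components)
    warning("max_components capped at ", A, " by subset size")
  press <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, A)
    for (b in seq_len(n_perm)) {
      tr <- sample.int(n, n_train)
      fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], A)
      a_fit <- fit$n_components
      Bp <- plsr_coef_path(fit$weights, fit$loadings, fit$y_loadings, a_fit)
      Xh <- X[-tr, , drop = FALSE]
      pred <- Xh %*% Bp  # n_held x a_fit
      ints <- fit$y_mean - as.numeric(fit$x_mean %*% Bp)
      pred <- sweep(pred, 2L, ints, `+`)
      err2 <- (pred - y[-tr])^2
      sse <- colSums(err2)
      out[b, seq_len(a_fit)] <- sse
      if (a_fit < A) out[b, (a_fit + 1L):A] <- sse[a_fit]
    }
    out
  })
  m <- colMeans(press)
  se <- apply(press, 2L, stats::sd) / sqrt(n_perm)
  a_min <- which.min(m)
  a_sel <- if (rule == "min") a_min else
    which(m <= m[a_min] + se[a_min])[1L]
  list(n_components = as.integer(a_sel), press_mean = m, press_se = se,
       rule = rule, seed = seed)
}

#' Screen observations with consistently large prediction errors
#'
#' Repeats a random 70/30 fit-predict cycle \code{n_runs} times, accumulates
#' each observation's held-out absolute errors, and removes the
#' \code{floor(remove_fraction * n)} observations with the highest mean
#' absolute error (ties broken by larger MAE value then index). An
#' observation never held out would fall back to in-sample errors with a
#' warning (practically impossible at the default 200 runs).
#'
#' @param X,y full dataset before the calibration/validation split.
#' @param n_runs number of random fit-predict cycles (default 200).
#' @param remove_fraction fraction of observations to drop (default 0.05).
#' @param n_components components per screening fit; default
#'   \code{min(10, feasible)}.
#' @param split_fraction training fraction per cycle (default 0.7).
#' @param seed integer seed.
#' @return list with \code{kept}, \code{removed} (row indices) and
#'   \code{mae} (per-observation mean absolute held-out error).
#' @export
outlier_screen <- function(X, y, n_runs = 200, remove_fraction = 0.05,
                           n_components = NULL, split_fraction = 0.7,
                           seed = 1) {
  stopifnot(remove_fraction >= 0, remove_fraction < 1, n_runs >= 1)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_train <- floor(split_fraction * n)
  A <- n_components %||% min(10L, n_train - 1L, ncol(X))
  acc <- with_seed(seed, {
    err_sum <- cnt <- numeric(n)
    for (b in seq_len(n_runs)) {
      tr <- sample.int(n, n_train)
      fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], A)
      held <- setdiff(seq_len(n), tr)
      pred <- predict(fit, X[held, , drop = FALSE])
      err_sum[held] <- err_sum[held] + abs(pred - y[held])
      cnt[held] <- cnt[held] + 1
    }
    list(err_sum = err_sum, cnt = cnt)
  })
  mae <- acc$err_sum / acc$cnt
  if (any(acc$cnt == 0)) {
    warning("observation(s) never held out; using in-sample errors")
    fit_all <- fit_plsr(X, y, A)
    res <- abs(predict(fit_all, X) - y)
    mae[acc$cnt == 0] <- res[acc$cnt == 0]
  }
  n_drop <- floor(remove_fraction * n)
  ord <- order(-mae, seq_len(n))
  removed <- sort(ord[seq_len(n_drop)])
  list(kept = setdiff(seq_len(n), removed), removed = removed, mae = mae)
}

#' Split plots into calibration and validation sets
#'
#' Random disjoint partition with \code{floor(calibration_fraction * n)}
#' calibration rows; the validation remainder must not be touched by any
#' fitting, selection or screening step.
#'
#' @param n number of observations (or a vector whose length is used).
#' @param calibration_fraction fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with integer index vectors \code{calibration} and
#'   \code{validation}.
#' @export
split_calibration <- function(n, calibration_fraction = 0.7, seed = 1) {
  if (length(n) > 1) n <- length(n)
  stopifnot(calibration_fraction > 0, calibration_fraction < 1)
  if (n < 10) warning("fewer than 10 observations; split will be unstable")
  cal <- with_seed(seed, sort(sample.int(n, floor(calibration_fraction * n))))
  list(calibration = cal, validation = setdiff(seq_len(n), cal))
}

#' Fit a PLSR ensemble on random calibration subsets
#'
#' Builds \code{n_models} members (default 200), each fitted with a shared,
#' pre-selected component count on an independent random
#' \code{subset_fraction} draw of the calibration rows. Member sub-seeds are
#' derived from the master seed and recorded.
#'
#' @param X_cal,y_cal calibration data.
#' @param n_components shared component count (from
#'   \code{\link{press_select}}).
#' @param n_models ensemble size (default 200).
#' @param subset_fraction fraction of calibration rows per member
#'   (default 0.7).
#' @param seed integer master seed.
#' @return An object of class \code{plsr_ensemble}: list with
#'   \code{members}, \code{subsets}, \code{n_components}, \code{seed}.
#' @export
ensemble_fit <- function(X_cal, y_cal, n_components, n_models = 200,
                         subset_fraction = 0.7, seed = 1) {
  X_cal <- as.matrix(X_cal); y_cal <- as.numeric(y_cal)
  n <- nrow(X_cal)
  n_sub <- floor(subset_fraction * n)
  if (n_sub <= n_components)
    stop("subset size ", n_sub, " too small for ", n_components,
         " components")
  members <- vector("list", n_models)
  subsets <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    idx <- with_seed(derive_seed(seed, "member", i), sample.int(n, n_sub))
    subsets[[i]] <- sort(idx)
    members[[i]] <- fit_plsr(X_cal[idx, , drop = FALSE], y_cal[idx],
                             n_components)
  }
  structure(list(members = members, subsets = subsets,
                 n_components = n_components, seed = seed),
            class = "plsr_ensemble")
}

#' @export
print.plsr_ensemble <- function(x, ...) {
  cat(sprintf("<plsr_ensemble> %d members, %d components\n",
              length(x$members), x$n_components))
  invisible(x)
}

#' Ensemble predictions with uncertainty
#'
#' Applies every ensemble member to new spectra and returns the per-plot
#' mean and sample standard deviation of the member predictions; the SD is
#' the model's predictive uncertainty. Negative predictions are returned
#' as-is.
#'
#' @param ensemble a \code{\link{ensemble_fit}} result.
#' @param X_new matrix on the training wavelength grid.
#' @return data.frame with \code{mean}, \code{sd} and \code{n_models}.
#' @export
ensemble_predict <- function(ensemble, X_new) {
  X_new <- as.matrix(X_new)
  p <- length(ensemble$members[[1L]]$coef)
  if (ncol(X_new) != p)
    stop("spectra have ", ncol(X_new), " bands; ensemble trained on ", p)
  preds <- vapply(ensemble$members, predict, numeric(nrow(X_new)),
                  newdata = X_new)
  preds <- matrix(preds, nrow = nrow(X_new))
  data.frame(mean = rowMeans(preds), sd = apply(preds, 1L, stats::sd),
             n_models = length(ensemble$members))
}

#' Prediction-accuracy metrics
#'
#' \code{r2} is the squared Pearson correlation between observed and
#' predicted (the convention used with a fitted line in prediction plots);
#' \code{r2_nse} is the one-to-one (Nash-Sutcliffe) variant reported for
#' transparency. \code{nrmse = rmse / (max(obs) - min(obs))};
#' \code{bias = mean(predicted - observed)}.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return list with \code{r2}, \code{r2_nse}, \code{rmse}, \code{nrmse},
#'   \code{bias}, \code{n}.
#' @export
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  rng <- max(observed) - min(observed)
  rmse <- sqrt(mean((predicted - observed)^2))
  r2 <- suppressWarnings(cor(observed, predicted))^2
  list(r2 = unname(r2),
       r2_nse = 1 - sum((predicted - observed)^2) /
         sum((observed - mean(observed))^2),
       rmse = rmse,
       nrmse = if (rng > 0) rmse / rng else NA_real_,
       bias = mean(predicted - observed),
       n = length(observed))
}

#' VIP scores, informative-wavelength mask and coefficient summary
#'
#' For an ensemble, the VIP score per wavelength is the mean of the member
#' VIPs and the coefficient summary is the member mean and SD; for a single
#' model the member set has size one. Wavelengths with VIP > 1 are flagged
#' informative (each member's squared VIPs average to one, so scores above
#' one mark predictors carrying more than an average share of the
#' explained response variance).
#'
#' @param model a \code{plsr_model} or \code{plsr_ensemble}.
#' @param threshold VIP cut-off for the informative mask (default 1).
#' @return data.frame with \code{wavelength} (if known), \code{vip},
#'   \code{informative}, \code{coef_mean}, \code{coef_sd}.
#' @export
vip_informative <- function(model, threshold = 1) {
  members <- if (inherits(model, "plsr_ensemble")) model$members
    else list(model)
  vips <- vapply(members, `[[`, numeric(length(members[[1L]]$vip)), "vip")
  coefs <- vapply(members, `[[`, numeric(length(members[[1L]]$coef)), "coef")
  vips <- matrix(vips, ncol = length(members))
  coefs <- matrix(coefs, ncol = length(members))
  vip <- rowMeans(vips)
  data.frame(
    wavelength = members[[1L]]$wavelengths %||%
      rep(NA_real_, length(vip)),
    vip = vip,
    informative = vip > threshold,
    coef_mean = rowMeans(coefs),
    coef_sd = apply(coefs, 1L, stats::sd))
}

#' Single-index linear baseline model
#'
#' Ordinary least squares of a microbial response on one vegetation index
#' (NDVI or NDWI), the standard baseline against which the full-spectrum
#' PLSR ensemble is compared.
#'
#' @param index numeric vector of index values (training plots).
#' @param y response (training plots).
#' @param index_new,y_new optional evaluation data; when omitted the
#'   training data are evaluated.
#' @return list with \code{slope}, \code{intercept} and \code{metrics}
#'   (see \code{\link{evaluate_predictions}}).
#' @export
baseline_index_model <- function(index, y, index_new = NULL, y_new = NULL) {
  stopifnot(length(index) == length(y), length(y) >= 3)
  if (stats::sd(index) == 0) stop("constant index; baseline undefined")
  fit <- lm(y ~ index)
  b <- unname(stats::coef(fit))
  ix <- index_new %||% index
  yy <- y_new %||% y
  pred <- b[1L] + b[2L] * ix
  list(slope = b[2L], intercept = b[1L],
       metrics = evaluate_predictions(yy, pred))
}
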