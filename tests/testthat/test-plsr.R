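test_that("PLSR nails rank-1 signal with one component", {
  set.seed(1)
  t1 <- rnorm(40)
  X1 <- outer(t1, rnorm(10))  # rank-1 predictors carrying the signal
  y1 <- 2 * t1
  fit <- fit_plsr(X1, y1, 1)
  expect_equal(cor(predict(fit, X1), y1)^2, 1, tolerance = 1e-10)
})

test_that("full-rank PLSR equals the least-squares oracle", {
  set.seed(2)
  for (i in 1:50) {
    n <- 10; p <- 4
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    fit <- fit_plsr(X, y, n_components = p)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(unname(fit$coef), ols[-1], tolerance = 1e-8)
    expect_equal(fit$intercept, ols[1], tolerance = 1e-8)
  }
})

test_that("VIP normalisation and the single-predictor degenerate case", {
  set.seed(3)
  X <- matrix(rnorm(60 * 30), 60)
  y <- X[, 3] + 0.5 * X[, 17] + rnorm(60, 0, 0.2)
  fit <- fit_plsr(X, y, 4)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-6)
  # single predictor: VIP forced to 1 exactly
  f1 <- fit_plsr(matrix(rnorm(30), 30, 1), rnorm(30), 1)
  expect_equal(f1$vip, 1, tolerance = 1e-12)
  # score vectors mutually orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
})

test_that("training fit is non-decreasing in the number of components", {
  set.seed(4)
  X <- matrix(rnorm(50 * 20), 50)
  y <- rowSums(X[, 1:5]) + rnorm(50)
  r2 <- vapply(1:8, function(a) {
    f <- fit_plsr(X, y, a)
    cor(predict(f, X), y)^2
  }, numeric(1))
  expect_true(all(diff(r2) > -1e-10))
  expect_error(fit_plsr(X, rep(1, 50), 2), "zero-variance")
  expect_error(fit_plsr(X, y, 60), "exceeds")
})

test_that("PRESS selection recovers a 3-factor structure and floors at 1 on noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    L <- matrix(rnorm(n * 3), n)
    X <- L %*% matrix(rnorm(3 * 25), 3) + matrix(rnorm(n * 25, 0, 0.05), n)
    y <- rowSums(L) + rnorm(n, 0, 0.1)
    press_select(X, y, max_components = 8, n_perm = 50,
                 seed = s)$n_components
  }, integer(1))
  expect_gte(sum(hits == 3), 18)  # >= 90% of 20 seeds
  # pure-noise response: parsimony floor of one component
  ones <- vapply(1:10, function(s) {
    set.seed(s)
    press_select(matrix(rnorm(100 * 20), 100), rnorm(100),
                 max_components = 8, n_perm = 50, seed = s)$n_components
  }, integer(1))
  expect_true(all(ones == 1))
  # infeasible max_components capped with a warning
  set.seed(1)
  expect_warning(press_select(matrix(rnorm(20 * 5), 20), rnorm(20),
                              max_components = 15, n_perm = 5, seed = 1),
                 "capped")
})

test_that("outlier screen removes floor(fraction*n) and finds planted outliers", {
  set.seed(5)
  X <- matrix(rnorm(200 * 20), 200)
  y <- rowSums(X[, 1:4]) + rnorm(200, 0, 0.5)
  scr <- outlier_screen(X, y, n_runs = 50, remove_fraction = 0.05, seed = 1)
  expect_length(scr$removed, 10)  # floor(0.05 * 200)
  expect_length(intersect(scr$kept, scr$removed), 0)
  expect_length(c(scr$kept, scr$removed), 200)
  # planted 10-residual-SD outlier is caught in >= 95% of 20 seeds
  caught <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    X <- matrix(rnorm(n * 20), n)
    y <- rowSums(X[, 1:4]) + rnorm(n, 0, 1)
    y[7] <- y[7] + 10
    7 %in% outlier_screen(X, y, n_runs = 100, remove_fraction = 0.05,
                          seed = s)$removed
  }, logical(1))
  expect_gte(sum(caught), 19)
})

test_that("calibration split: exact sizes, disjoint, deterministic", {
  sp <- split_calibration(100, 0.7, seed = 3)
  expect_length(sp$calibration, 70)
  expect_length(sp$validation, 30)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_identical(sp, split_calibration(100, 0.7, seed = 3))
  expect_false(identical(sp$calibration,
                         split_calibration(100, 0.7, seed = 4)$calibration))
  expect_warning(split_calibration(8, 0.7, seed = 1), "unstable")
})

test_that("ensembles: member count, subset variation, degenerate agreement", {
  set.seed(6)
  n <- 60
  t1 <- rnorm(n)
  X <- outer(t1, rnorm(12))          # zero-noise rank-1 data
  y <- 3 * t1
  ens <- ensemble_fit(X, y, n_components = 1, n_models = 20, seed = 2)
  expect_length(ens$members, 20)
  coefs <- vapply(ens$members, `[[`, numeric(12), "coef")
  expect_lt(max(abs(coefs - coefs[, 1])), 1e-8)  # identical fits
  expect_false(identical(ens$subsets[[1]], ens$subsets[[2]]))
  pr <- ensemble_predict(ens, X)
  expect_equal(pr$sd, rep(0, n), tolerance = 1e-8)
  expect_error(ensemble_predict(ens, X[, 1:5]), "bands")
  expect_error(ensemble_fit(X, y, n_components = 50, n_models = 3,
                            seed = 1), "too small")
})

test_that("ensemble mean/SD follow the sample definitions", {
  # three members predicting {1, 2, 3} for one plot -> mean 2, SD 1
  mk <- function(int) structure(list(coef = c(0, 0), intercept = int,
                                     vip = c(1, 1),
                                     n_components = 1, wavelengths = NULL),
                                class = "plsr_model")
  ens <- structure(list(members = list(mk(1), mk(2), mk(3)),
                        subsets = list(1, 1, 1), n_components = 1,
                        seed = 1), class = "plsr_ensemble")
  pr <- ensemble_predict(ens, matrix(0, 1, 2))
  expect_equal(pr$mean, 2)
  expect_equal(pr$sd, 1)
})

test_that("evaluation metrics match hand computation", {
  m0 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m0[c("r2", "rmse", "nrmse", "bias")]),
               c(r2 = 1, rmse = 0, nrmse = 0, bias = 0))
  m <- evaluate_predictions(c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(m$bias, 0.5)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$nrmse, 0.5 / 3, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_lt(m$r2_nse, 1)  # offset predictions punished by the 1:1 variant
})

test_that("index baselines: closed-form OLS and perfect-fit case", {
  b <- baseline_index_model(c(0, 1, 2), c(1, 3, 5))
  expect_equal(b$slope, 2)
  expect_equal(b$intercept, 1)
  expect_equal(b$metrics$r2, 1)
  set.seed(7)
  ndvi <- runif(30, 0.3, 0.9)
  y <- 4 * ndvi + 1
  expect_equal(baseline_index_model(ndvi, y)$metrics$r2, 1,
               tolerance = 1e-10)
  expect_error(baseline_index_model(rep(0.5, 10), rnorm(10)), "constant")
})

test_that("VIP interpretation table flags wavelengths above one", {
  set.seed(8)
  wl <- seq(500, 700, by = 10)
  X <- matrix(rnorm(80 * length(wl)), 80,
              dimnames = list(NULL, as.character(wl)))
  y <- X[, 6] + rnorm(80, 0, 0.3)
  ens <- ensemble_fit(X, y, n_components = 2, n_models = 15, seed = 3)
  tab <- vip_informative(ens)
  expect_identical(tab$wavelength, wl)
  expect_identical(tab$informative, tab$vip > 1)
  expect_identical(which.max(tab$vip), 6L)
  expect_true(all(tab$coef_sd >= 0))
})
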