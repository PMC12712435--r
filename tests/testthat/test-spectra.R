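test_that("spectra_matrix validates inputs and clips negative reflectance", {
  expect_error(spectra_matrix(matrix(0.1, 2, 3), c(500, 400, 600)),
               "strictly increasing")
  expect_error(spectra_matrix(matrix(0.1, 2, 3), c(400, 500)),
               "does not match")
  s <- spectra_matrix(matrix(c(0.2, -0.05, 0.3, 0.4), 2, 2), c(400, 500))
  expect_true(all(s$reflectance >= 0))
  expect_identical(attr(s, "n_clipped"), 1L)
})

test_that("resampling is the identity on the same grid and exact on affine spectra", {
  s <- make_spectra()
  expect_equal(resample_spectra(s, s$wavelengths)$reflectance,
               s$reflectance, tolerance = 1e-12)
  # affine spectrum r = a + b*wl on a shifted grid is a fixed point
  wl <- seq(400, 2400, by = 10)
  a <- 0.05; b <- 1e-4
  s2 <- spectra_matrix(rbind(a + b * wl), wl)
  target <- seq(405, 2395, by = 10)
  out <- resample_spectra(s2, target)
  expect_equal(as.numeric(out$reflectance), a + b * target,
               tolerance = 1e-12)
  expect_error(resample_spectra(s2, c(300, 500)), "outside source span")
})

test_that("buffer_mean matches brute-force pixel enumeration", {
  wl <- c(500, 600)
  nr <- nc <- 30
  set.seed(4)
  arr <- array(runif(nr * nc * 2, 0.1, 0.5), dim = c(nr, nc, 2))
  # centre on a pixel-corner grid point
  centre <- c(15, 15)
  patch <- list(reflectance = arr, wavelengths = wl, pixel_size_m = 1,
                centre = centre)
  res <- buffer_mean(patch, diameter_m = 20)
  # brute force: enumerate pixel centres, strict < radius
  acc <- c(0, 0); cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d <- sqrt((j - 0.5 - centre[1])^2 + (i - 0.5 - centre[2])^2)
    if (d < 10) { acc <- acc + arr[i, j, ]; cnt <- cnt + 1L }
  }
  expect_identical(res$n_pixels, cnt)
  expect_equal(res$spectrum, acc / cnt, tolerance = 1e-12)
  # uniform patch returns the constant pixel spectrum
  arr2 <- array(rep(c(0.2, 0.4), each = nr * nc), dim = c(nr, nc, 2))
  patch$reflectance <- arr2
  expect_equal(buffer_mean(patch, 20)$spectrum, c(0.2, 0.4))
  expect_error(buffer_mean(patch, 0.5), "exceed pixel spacing")
})

test_that("NDVI/NDWI arithmetic, nearest-band rule and scale invariance", {
  wl <- c(670, 675, 805, 860, 1240)
  refl <- rbind(c(0.1, 0.1, 0.5, 0.45, 0.30),
                c(0.2, 0.2, 0.2, 0.25, 0.25))
  s <- spectra_matrix(refl, wl)
  ndvi <- compute_index(s, "NDVI")  # resolves 804 -> 805, 673 -> 675
  expect_equal(unname(ndvi[1]), (0.5 - 0.1) / (0.5 + 0.1),
               tolerance = 1e-12)
  expect_equal(unname(ndvi[2]), 0)  # R804 == R673
  ndwi <- compute_index(s, "NDWI")
  expect_equal(unname(ndwi[1]), (0.45 - 0.3) / (0.45 + 0.3))
  # scale invariance under positive scalar multiplication
  s2 <- spectra_matrix(refl * 3.7, wl)
  expect_equal(compute_index(s2, "NDVI"), ndvi, tolerance = 1e-12)
  # no band within 3 nm -> error
  s3 <- spectra_matrix(refl[, 1:3, drop = FALSE], c(500, 600, 700))
  expect_error(compute_index(s3, "NDVI"), "no band within")
})

test_that("NDVI filter applies the strict < rule at the boundary", {
  wl <- c(673, 804)
  # reflectance pairs built from exact binary fractions so the edge plot's
  # NDVI is exactly 0.4: (0.875 - 0.375) / (0.875 + 0.375) = 0.5 / 1.25
  r673 <- c(0.40,  0.375, 0.35)
  r804 <- c(0.85,  0.875, 0.875)
  s <- spectra_matrix(cbind(r673, r804), wl,
                      plot_ids = c("low", "edge", "high"))
  ndvi <- compute_index(s, "NDVI")
  expect_lt(ndvi[["low"]], 0.4)
  expect_identical(ndvi[["edge"]], 0.4)
  res <- filter_by_ndvi(s, threshold = 0.4)
  expect_identical(res$spectra$plot_ids, c("edge", "high"))
  expect_identical(res$exclusions$plot_id, "low")
  expect_equal(res$exclusions$value, ndvi[["low"]], tolerance = 1e-12)
  # survivors + exclusions partition the input
  expect_setequal(c(res$spectra$plot_ids, res$exclusions$plot_id),
                  s$plot_ids)
  # all high NDVI -> no removals
  s2 <- spectra_matrix(cbind(c(0.1, 0.1), c(0.9, 0.9)), wl)
  expect_identical(nrow(filter_by_ndvi(s2)$exclusions), 0L)
})

test_that("band trimming keeps closed intervals and matches enumeration", {
  wl <- seq(380, 2500, by = 5)
  s <- spectra_matrix(matrix(0.3, 2, length(wl)), wl)
  out <- trim_bands(s)
  # 1400 nm sits in the 1334-1450 gap
  expect_false(1400 %in% out$wavelengths)
  # brute-force enumeration over the three closed intervals
  expected <- sum(wl >= 403 & wl <= 1334) + sum(wl >= 1450 & wl <= 1785) +
    sum(wl >= 1971 & wl <= 2396)
  expect_identical(length(out$wavelengths), as.integer(expected))
  # endpoints are included
  s2 <- spectra_matrix(matrix(0.3, 1, 3), c(403, 1334, 1400))
  expect_equal(trim_bands(s2)$wavelengths, c(403, 1334))
  expect_error(trim_bands(s2, list(c(100, 200))), "every band")
  expect_error(trim_bands(s2, list(c(400, 900), c(800, 1000))),
               "non-overlapping")
})

test_that("vector normalization yields unit rows and preserves shape", {
  s <- spectra_matrix(rbind(c(0.3, 0.4)), c(500, 600))
  out <- vector_normalize(s)
  expect_equal(as.numeric(out$reflectance), c(0.6, 0.8), tolerance = 1e-12)
  s2 <- make_spectra(n_plots = 5)
  n2 <- vector_normalize(s2)
  expect_equal(unname(sqrt(rowSums(n2$reflectance^2))), rep(1, 5),
               tolerance = 1e-12)
  s3 <- spectra_matrix(rbind(c(0, 0), c(1, 1)), c(500, 600),
                       plot_ids = c("z", "p"))
  expect_error(vector_normalize(s3), "z")
})

test_that("trim-then-normalize equals normalize-of-trimmed and CSV round-trips", {
  s <- make_spectra(n_plots = 4)
  a <- vector_normalize(trim_bands(s))
  b <- vector_normalize(trim_bands(s))
  expect_equal(a$reflectance, b$reflectance)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(a, tmp)
  back <- read_spectra_csv(tmp)
  expect_equal(back$wavelengths, a$wavelengths)
  expect_equal(unname(back$reflectance), unname(a$reflectance),
               tolerance = 1e-9)
  expect_identical(back$plot_ids, a$plot_ids)
})
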