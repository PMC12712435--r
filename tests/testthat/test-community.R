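test_that("taxonomic filter removes archaeal and undefined ASVs only", {
  m <- make_counts(4, 10)
  tax <- data.frame(asv = colnames(m),
                    kingdom = c(rep("Bacteria", 7), rep("Archaea", 3)),
                    phylum = c("Proteobacteria", "", "Acidobacteria",
                               "unclassified", "Firmicutes", NA,
                               "Chloroflexi", "Crenarchaeota",
                               "Euryarchaeota", "Thaumarchaeota"))
  out <- filter_taxa(m, tax)
  expect_setequal(out$removed, colnames(m)[c(2, 4, 6, 8, 9, 10)])
  expect_identical(out$counts, m[, c(1, 3, 5, 7)])
  # all-Bacteria, fully labelled table is unchanged
  tax2 <- data.frame(asv = colnames(m), kingdom = "Bacteria",
                     phylum = "Proteobacteria")
  expect_identical(filter_taxa(m, tax2)$counts, m)
})

test_that("rarefaction drops shallow samples and conserves depth exactly", {
  m <- rbind(a = c(3000L, 1999L, 0L), b = c(2500L, 2499L, 1L),
             c = c(5000L, 0L, 0L))
  colnames(m) <- paste0("t", 1:3)
  out <- suppressWarnings(rarefy_counts(m, depth = 5000, seed = 3))
  expect_identical(out$dropped, "a")          # 4999 reads -> dropped
  expect_identical(out$counts["b", ], m["b", ])  # exactly at depth: unchanged
  expect_identical(out$counts["c", ], m["c", ])
  expect_true(all(rowSums(out$counts) == 5000))
  # conservation + richness monotonicity over 100 random tables
  set.seed(11)
  for (i in 1:100) {
    tab <- make_counts(4, 25, depth_range = c(30, 200), seed = i)
    r <- rarefy_counts(tab, depth = 50, seed = i)
    expect_true(all(rowSums(r$counts) == 50))
    kept <- rownames(r$counts)
    expect_true(all(asv_richness(r$counts) <=
                      asv_richness(tab[kept, , drop = FALSE])))
    expect_true(all(r$counts <= tab[kept, , drop = FALSE]))
  }
  # deterministic given seed
  expect_identical(suppressWarnings(rarefy_counts(m, 5000, seed = 9))$counts,
                   suppressWarnings(rarefy_counts(m, 5000, seed = 9))$counts)
})

test_that("richness counts positive entries per sample", {
  m <- rbind(s1 = c(5L, 0L, 1L, 2L), s2 = c(0L, 0L, 0L, 0L))
  expect_identical(asv_richness(m), c(s1 = 3L, s2 = 0L))
})

test_that("dominant phyla: ubiquity + top-10% rule, rows sum to one", {
  # single-phylum dataset: that phylum dominant, Other = 0
  m <- make_counts(3, 5)
  tax <- data.frame(asv = colnames(m), kingdom = "Bacteria",
                    phylum = "Acidobacteria")
  out <- dominant_phyla(m, tax)
  expect_identical(out$dominant, "Acidobacteria")
  expect_equal(unname(out$rel_abund[, "Other"]), rep(0, 3))
  # 10 phyla; A ubiquitous at ~50%, others rare/patchy -> dominant = {A}
  set.seed(2)
  n_s <- 6; n_p <- 10
  counts <- matrix(0L, n_s, n_p,
                   dimnames = list(paste0("s", 1:n_s), paste0("p", 1:n_p)))
  counts[, 1] <- 500L
  for (j in 2:n_p) {
    present <- sample(n_s, 3)  # patchy
    counts[present, j] <- as.integer(sample(20:80, 3))
  }
  # one ASV per phylum
  tax2 <- data.frame(asv = paste0("p", 1:n_p), kingdom = "Bacteria",
                     phylum = paste0("Phy", 1:n_p))
  colnames(counts) <- tax2$asv
  out2 <- dominant_phyla(counts, tax2)
  expect_identical(out2$dominant, "Phy1")
  expect_equal(unname(out2$rel_abund[, "Other"]),
               unname(1 - out2$rel_abund[, "Phy1"]), tolerance = 1e-12)
  expect_equal(unname(rowSums(out2$rel_abund)), rep(1, n_s),
               tolerance = 1e-9)
})

test_that("Bray-Curtis matches the definition oracle and its bounds", {
  x <- c(2, 0, 1); y <- c(1, 1, 1)
  d <- bray_curtis(rbind(a = x, b = y))
  expect_equal(d["a", "b"], 2 / 6, tolerance = 1e-12)
  # identical rows -> 0; disjoint supports -> 1
  d2 <- bray_curtis(rbind(p = c(3, 1, 0), q = c(3, 1, 0), r = c(0, 0, 5)))
  expect_equal(d2["p", "q"], 0)
  expect_equal(d2["p", "r"], 1)
  # oracle equivalence on 20 random samples
  m <- make_counts(20, 15, seed = 5)
  d3 <- bray_curtis(m)
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(d3[i, j], oracle_bray(m[i, ], m[j, ]), tolerance = 1e-12)
  expect_true(all(d3 >= 0 & d3 <= 1))
  expect_equal(unname(diag(d3)), rep(0, 20))
  # invariant to appending all-zero taxa columns
  expect_equal(bray_curtis(cbind(m, z1 = 0L, z2 = 0L)), d3)
  expect_error(bray_curtis(rbind(ok = c(1, 2), bad = c(0, 0))), "bad")
})

test_that("NMDS embeds exact configurations with ~zero stress and recovers truth", {
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  nm <- suppressWarnings(nmds_ordination(d3, k = 2, seed = 1))
  expect_lt(nm$stress, 1e-6)
  # distances from a true 2-D configuration are recovered
  set.seed(5)
  pts <- matrix(rnorm(30 * 2), 30)
  d <- as.matrix(dist(pts))
  nm2 <- suppressWarnings(nmds_ordination(d, k = 2, seed = 3))
  expect_lt(nm2$stress, 1e-3)
  pr <- vegan::procrustes(pts, nm2$scores, symmetric = TRUE)
  expect_lt(pr$ss, 0.01)
  expect_identical(colnames(nm2$scores), c("NMDS1", "NMDS2"))
  # orientation convention: first nonzero loading of each axis positive
  expect_true(all(apply(nm2$scores, 2, function(v) v[abs(v) > 1e-12][1]) > 0))
  # deterministic given seed
  nm3 <- suppressWarnings(nmds_ordination(d, k = 2, seed = 3))
  expect_equal(nm2$scores, nm3$scores)
})

test_that("Hellinger transform: hand values and unit row norms", {
  expect_equal(as.numeric(hellinger_transform(rbind(c(4, 0)))), c(1, 0))
  out <- hellinger_transform(rbind(c(1, 1, 2)))
  expect_equal(as.numeric(out), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  m <- make_counts(10, 8, seed = 3)
  h <- hellinger_transform(m)
  expect_equal(unname(sqrt(rowSums(h^2))), rep(1, 10), tolerance = 1e-12)
  for (i in 1:10)
    expect_equal(h[i, ], oracle_hellinger(m[i, ]), tolerance = 1e-12)
  expect_error(hellinger_transform(rbind(c(0, 0))), "non-positive")
})

test_that("CLR transform: hand values, zero-sum rows, zero replacement", {
  expect_equal(as.numeric(clr_transform(rbind(c(2, 2, 2)))), rep(0, 3))
  out <- clr_transform(rbind(c(1, 4)))
  expect_equal(as.numeric(out), c(-log(4) / 2, log(4) / 2),
               tolerance = 1e-12)
  m <- make_counts(8, 10, seed = 7)  # contains zeros
  cl <- clr_transform(m)
  expect_equal(unname(rowSums(cl)), rep(0, 8), tolerance = 1e-9)
  # zero-free rows match the definition oracle exactly
  m2 <- m + 1L
  cl2 <- clr_transform(m2)
  for (i in 1:8)
    expect_equal(cl2[i, ], oracle_clr(m2[i, ] / sum(m2[i, ])),
                 tolerance = 1e-12)
})
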