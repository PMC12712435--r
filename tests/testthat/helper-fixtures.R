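# Fixture builders and independent definition oracles used across tests.

# random spectra with a smooth shape plus noise
make_spectra <- function(n_plots = 8, wl = seq(400, 2400, by = 20),
                         seed = 1) {
  set.seed(seed)
  base <- 0.2 + 0.2 * sin(wl / 300)
  refl <- t(replicate(n_plots, pmax(base + rnorm(length(wl), 0, 0.01),
                                    0.001)))
  spectra_matrix(refl, wl)
}

# unit-concentration lipid table: every biomarker at `conc` nmol/g
make_lipids <- function(samples = "s1", conc = 1) {
  lips <- unlist(spectromicrobe:::plfa_biomarkers, use.names = FALSE)
  expand.grid(sample_id = samples, lipid = lips,
              stringsAsFactors = FALSE) |>
    transform(concentration = conc)
}

# random ASV count table with uneven depths
make_counts <- function(n_samples = 6, n_asv = 30, depth_range = c(50, 500),
                        seed = 1) {
  set.seed(seed)
  m <- t(vapply(seq_len(n_samples), function(i) {
    d <- sample(depth_range[1]:depth_range[2], 1)
    as.integer(rmultinom(1, d, prob = rexp(n_asv)))
  }, integer(n_asv)))
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("asv", seq_len(n_asv)))
  m
}

# --- definition oracles (independent of package implementations) --------

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# first-order partial correlation on ranks
oracle_partial_spearman1 <- function(x, y, z) {
  rxy <- cor(rank(x), rank(y)); rxz <- cor(rank(x), rank(z))
  ryz <- cor(rank(y), rank(z))
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

oracle_clr <- function(row) log(row) - mean(log(row))

oracle_hellinger <- function(row) sqrt(row / sum(row))
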