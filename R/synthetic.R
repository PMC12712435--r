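# Seeded synthetic NEON-like data with known ground truth.
#
# The generator emulates the observational structure of a continental plot
# network: ecoclimatic domains carrying latent climate and soil gradients,
# plots nested in domains, soil cores nested in plots, canopy spectra whose
# absorption features are linear in foliar traits, and microbial responses
# driven partly by traits (direct channel) and partly by the shared
# environmental gradients (confounded channel). Every downstream stage can
# therefore be tested by parameter recovery against the planted truth.

# Foliar traits: loadings on the two latent gradients plus an independent
# component, unit total variance. Eight traits keep the gradients well
# recoverable from trait (and hence spectral) data.
synth_trait_defs <- data.frame(
  trait  = c("nitrogen", "carbon", "lignin", "sla", "water",
             "chlorophyll", "cellulose", "phosphorus"),
  a_clim = c( 0.55, -0.35, -0.30,  0.55,  0.50,  0.60, -0.40,  0.45),
  b_soil = c( 0.35,  0.55,  0.45, -0.25,  0.50,  0.15,  0.50,  0.40),
  stringsAsFactors = FALSE)
synth_trait_defs$c_direct <-
  sqrt(1 - synth_trait_defs$a_clim^2 - synth_trait_defs$b_soil^2)

# Gaussian absorption features: centre (nm), width (nm, Gaussian SD), mean
# depth, and depth sensitivity per SD of the driving trait. Centres sit in
# the retained wavelength windows, away from the NDVI bands.
synth_feature_defs <- data.frame(
  centre = c( 705,  983, 1205, 1520, 1660, 2100, 2300),
  width  = c(  18,   22,   26,   22,   22,   26,   24),
  depth  = c(0.06, 0.05, 0.06, 0.05, 0.045, 0.05, 0.045),
  sens   = c(0.025, 0.020, 0.030, 0.030, 0.028, 0.030, 0.028),
  trait  = c("chlorophyll", "water", "water", "nitrogen", "lignin",
             "carbon", "sla"),
  stringsAsFactors = FALSE)

# Microbial responses: weights on traits (direct channel) and on the latent
# gradients (shared-environment channel). `top_trait` marks the dominant
# trait, whose deepest absorption feature is the planted informative
# wavelength for VIP-recovery checks. Responses differ deliberately in how
# trait- vs environment-driven they are.
synth_response_defs <- list(
  total_plfa  = list(traits = c(nitrogen = 1.0, water = 0.35),
                     env = c(clim = 0.7, soil = 0.7),
                     top_trait = "nitrogen"),
  fb_ratio    = list(traits = c(carbon = 1.0, lignin = 0.3),
                     env = c(clim = 0.3, soil = 0.45),
                     top_trait = "carbon"),
  gp_gn_ratio = list(traits = c(lignin = 1.0, carbon = 0.3),
                     env = c(clim = 0.35, soil = 0.5),
                     top_trait = "lignin"),
  richness    = list(traits = c(sla = 1.0, nitrogen = 0.3),
                     env = c(clim = 0.6, soil = 0.4),
                     top_trait = "sla"),
  nmds1       = list(traits = c(water = 1.0, chlorophyll = 0.3),
                     env = c(clim = 0.6, soil = 0.6),
                     top_trait = "water"))

#' Configuration for the synthetic NEON-like generator
#'
#' Validates and assembles the dials of \code{\link{synth_dataset}}.
#'
#' @param n_domains number of ecoclimatic domains (default 14).
#' @param n_plots_per_domain plots per domain (default 20).
#' @param n_cores_per_plot soil cores per plot (default 3).
#' @param wavelength_grid band centres in nm, strictly increasing; default
#'   426 bands spanning 380-2500 nm (~5 nm spacing).
#' @param signal_fraction fraction of each microbial response's variance
#'   carried by the planted linear predictor, in [0, 1] (default 0.8).
#' @param confound_weight weight of the shared-environment channel relative
#'   to the direct trait channel, in [0, 1] (default 0.5).
#' @param asv_richness_pool number of distinct ASVs (default 400).
#' @param read_depth_range integer min/max reads per sample (default
#'   3000-50000, so some samples fall below a 5000-read filter by design).
#' @param core_noise_sd core-level noise SD as a fraction of the
#'   between-plot SD (default 0.3).
#' @param spectral_noise_sd heteroscedastic reflectance noise SD
#'   (default 0.005, i.e. 0.5\% reflectance).
#' @param structure_amplitude NIR plateau scaling per SD of the canopy
#'   structure covariate (default 0.04).
#' @param overdispersion Dirichlet overdispersion of ASV compositions;
#'   0 disables (default 0.15).
#' @param seed integer seed (default 1).
#' @return a validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_domains = 14, n_plots_per_domain = 20,
                         n_cores_per_plot = 3,
                         wavelength_grid = seq(380, 2500, length.out = 426),
                         signal_fraction = 0.8, confound_weight = 0.5,
                         asv_richness_pool = 400,
                         read_depth_range = c(3000, 50000),
                         core_noise_sd = 0.3, spectral_noise_sd = 0.005,
                         structure_amplitude = 0.04, overdispersion = 0.15,
                         seed = 1) {
  chk_count <- function(x, nm) if (!is.numeric(x) || length(x) != 1 ||
                                   x < 1 || x != round(x))
    stop_config(nm, "must be a positive integer")
  chk_count(n_domains, "n_domains")
  chk_count(n_plots_per_domain, "n_plots_per_domain")
  chk_count(n_cores_per_plot, "n_cores_per_plot")
  chk_count(asv_richness_pool, "asv_richness_pool")
  if (signal_fraction < 0 || signal_fraction > 1)
    stop_config("signal_fraction", "must lie in [0, 1]")
  if (confound_weight < 0 || confound_weight > 1)
    stop_config("confound_weight", "must lie in [0, 1]")
  if (length(read_depth_range) != 2 || read_depth_range[1] < 1 ||
      diff(read_depth_range) < 0)
    stop_config("read_depth_range", "must be c(min, max) with min >= 1")
  if (any(diff(wavelength_grid) <= 0))
    stop_config("wavelength_grid", "must be strictly increasing")
  structure(mget(names(formals())), class = "synth_config")
}

# Smooth vegetation-like baseline reflectance curve, plus masks for the NIR
# plateau used by the structural term.
synth_baseline <- function(wl) {
  vis <- 0.04 + 0.04 * exp(-((wl - 550) / 40)^2)              # green bump
  red_edge <- 1 / (1 + exp(-(wl - 715) / 18))                  # VIS -> NIR
  nir <- 0.45
  swir_decay <- ifelse(wl > 1300, exp(-(wl - 1300) / 1500), 1)
  water1 <- 0.35 * exp(-((wl - 1450) / 45)^2)                  # broad dips
  water2 <- 0.45 * exp(-((wl - 1940) / 55)^2)
  base <- vis * (1 - red_edge) + nir * red_edge * swir_decay *
    (1 - water1) * (1 - water2)
  pmax(base, 0.01)
}

synth_nir_mask <- function(wl) {
  exp(-((wl - 1000) / 220)^2)  # smooth plateau bump centred in the NIR
}

#' Generate a synthetic multi-plot dataset with known truth
#'
#' Draws a complete NEON-like dataset: domain/plot latent gradients, foliar
#' traits, canopy spectra (baseline curve + trait-driven Gaussian absorption
#' features + structural NIR term + heteroscedastic noise), microbial
#' responses with a planted linear predictor carrying
#' \code{signal_fraction} of their variance, core-level PLFA lipid
#' concentrations, per-core ASV counts with uneven depths, soil and climate
#' covariates, land-cover labels, and observation dates for temporal
#' alignment. Identical config (including seed) gives identical output.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{spectra} (\code{\link{spectra_matrix}}),
#'   \code{plots} (plot metadata incl. domain, land cover, dates),
#'   \code{responses} (plot-level microbial responses), \code{traits}
#'   (plot-level foliar traits), \code{soil}, \code{climate},
#'   \code{lipid_cores} (long-format core-level lipid table),
#'   \code{asv_counts} (core samples x ASVs), \code{asv_taxonomy}, and
#'   \code{truth} (latent gradients, loadings, planted wavelengths,
#'   per-response linear predictors).
#' @export
synth_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, synth_dataset_impl(config))
}

synth_dataset_impl <- function(cfg) {
  n_dom <- cfg$n_domains
  n_plot <- n_dom * cfg$n_plots_per_domain
  wl <- cfg$wavelength_grid
  dom_id <- rep(seq_len(n_dom), each = cfg$n_plots_per_domain)
  plot_id <- sprintf("D%02d_P%03d", dom_id, seq_len(n_plot))

  # latent gradients: domain effect + plot-level deviation, standardised
  z_clim <- rnorm(n_dom); z_soil <- rnorm(n_dom)
  env_clim <- as.numeric(scale(z_clim[dom_id] + 0.5 * rnorm(n_plot)))
  env_soil <- as.numeric(scale(z_soil[dom_id] + 0.5 * rnorm(n_plot)))
  structure_cov <- as.numeric(scale(0.6 * env_clim + 0.8 * rnorm(n_plot)))

  # foliar traits
  td <- synth_trait_defs
  traits <- vapply(seq_len(nrow(td)), function(k)
    as.numeric(scale(td$a_clim[k] * env_clim + td$b_soil[k] * env_soil +
                       td$c_direct[k] * rnorm(n_plot))), numeric(n_plot))
  colnames(traits) <- td$trait

  # spectra: baseline + structural NIR term - absorption features + noise
  base <- synth_baseline(wl)
  nirm <- synth_nir_mask(wl)
  refl <- matrix(rep(base, each = n_plot), n_plot, length(wl))
  refl <- refl + cfg$structure_amplitude *
    tcrossprod(structure_cov, nirm)
  fd <- synth_feature_defs
  for (k in seq_len(nrow(fd))) {
    shape <- exp(-((wl - fd$centre[k]) / fd$width[k])^2)
    depth <- fd$depth[k] + fd$sens[k] * traits[, fd$trait[k]]
    refl <- refl - tcrossprod(depth, shape)
  }
  refl <- refl + matrix(rnorm(n_plot * length(wl), 0, cfg$spectral_noise_sd),
                        n_plot)
  refl <- pmax(refl, 0.001)
  spectra <- spectra_matrix(refl, wl, plot_id)

  # microbial responses with planted linear predictor
  rd <- synth_response_defs
  sf <- cfg$signal_fraction; cw <- cfg$confound_weight
  lp <- vapply(rd, function(r) {
    direct <- as.numeric(traits[, names(r$traits), drop = FALSE] %*%
                           r$traits)
    envp <- r$env["clim"] * env_clim + r$env["soil"] * env_soil
    raw <- (1 - cw) * as.numeric(scale(direct)) +
      cw * as.numeric(scale(envp))
    as.numeric(scale(raw))
  }, numeric(n_plot))
  colnames(lp) <- names(rd)
  noise <- matrix(rnorm(n_plot * length(rd)), n_plot)
  resp <- sqrt(sf) * lp + sqrt(1 - sf) * noise  # sf = 0 gives pure noise
  responses <- data.frame(plot_id = plot_id, resp,
                          stringsAsFactors = FALSE)

  top_feature_nm <- vapply(rd, function(r) {
    cand <- fd[fd$trait == r$top_trait, ]
    cand$centre[which.max(cand$sens)]
  }, numeric(1))

  # land cover correlated with the climate gradient
  lc_levels <- c("forest", "grassland", "shrubland", "wetland")
  lc_logit <- cbind(1.2 * env_clim, -0.8 * env_clim, -0.4 * env_soil,
                    0.8 * env_soil)
  lc_prob <- exp(lc_logit) / rowSums(exp(lc_logit))
  land_cover <- lc_levels[apply(lc_prob, 1L, function(p)
    sample.int(4L, 1L, prob = p))]

  # observation dates: one image per plot near peak greenness; soil and
  # foliar sampling jittered so a few plots violate the alignment windows
  year <- 2019L
  img_date <- as.Date("2019-07-15") + round(rnorm(n_plot, 0, 10))
  soil_date <- img_date + round(rnorm(n_plot, 0, 25))
  foliar_date <- img_date + round(rnorm(n_plot, 0, 40))

  plots <- data.frame(
    plot_id = plot_id, domain = sprintf("D%02d", dom_id),
    land_cover = land_cover, year = year,
    image_date = img_date, soil_date = soil_date,
    foliar_date = foliar_date, stringsAsFactors = FALSE)

  # soil and climate covariates
  soil <- data.frame(
    plot_id = plot_id,
    ph = 6.2 - 0.9 * env_soil + 0.35 * rnorm(n_plot),
    soil_moisture = pmax(0.02, 0.28 + 0.10 * env_clim + 0.05 * env_soil +
                           0.04 * rnorm(n_plot)),
    organic_c = exp(2.2 + 0.5 * env_soil + 0.2 * rnorm(n_plot)),
    total_n = exp(0.3 + 0.4 * env_soil + 0.2 * rnorm(n_plot)),
    stringsAsFactors = FALSE)
  soil$cn_ratio <- soil$organic_c / soil$total_n
  lat <- 30 + 3.5 * scale(z_clim)[, 1] + 20 * stats::runif(n_dom)
  lon <- -120 + 45 * stats::runif(n_dom)
  climate <- data.frame(
    plot_id = plot_id,
    mat = 10 + 6 * z_clim[dom_id] + 0.5 * rnorm(n_plot),
    map = pmax(100, 800 + 380 * z_clim[dom_id] + 60 * rnorm(n_plot)),
    latitude = lat[dom_id], longitude = lon[dom_id],
    stringsAsFactors = FALSE)

  lipid_cores <- synth_lipid_cores(cfg, plot_id, resp)
  asv <- synth_asv_tables(cfg, plot_id, env_clim, env_soil, traits)

  truth <- list(
    latent = data.frame(plot_id = plot_id, domain = dom_id,
                        env_clim = env_clim, env_soil = env_soil,
                        structure = structure_cov),
    trait_loadings = td,
    spectral_features = fd,
    response_defs = rd,
    linear_predictor = lp,
    planted_informative_wavelengths = sort(unique(fd$centre)),
    top_feature_nm = top_feature_nm,
    signal_fraction = sf, confound_weight = cw)

  list(spectra = spectra, plots = plots, responses = responses,
       traits = data.frame(plot_id = plot_id, traits,
                           stringsAsFactors = FALSE),
       soil = soil, climate = climate, lipid_cores = lipid_cores,
       asv_counts = asv$counts, asv_taxonomy = asv$taxonomy,
       truth = truth, config = cfg)
}

# Core-level lipid concentrations. Plot-level group abundances are positive
# transforms of latent microbial responses; each group total is spread over
# its biomarker lipids with fixed proportions, and cores add noise around
# the plot value (truncated at zero).
synth_lipid_cores <- function(cfg, plot_id, resp) {
  n_plot <- length(plot_id)
  group_scale <- c(gram_positive = 28, gram_negative = 9,
                   actinomycetales = 12, saprophytic_fungi = 10,
                   am_fungi = 4)
  drivers <- cbind(
    gram_positive = resp[, "total_plfa"],
    gram_negative = 0.7 * resp[, "total_plfa"] - 0.5 * resp[, "gp_gn_ratio"],
    actinomycetales = 0.8 * resp[, "total_plfa"] +
      0.3 * resp[, "gp_gn_ratio"],
    saprophytic_fungi = 0.6 * resp[, "total_plfa"] +
      0.6 * resp[, "fb_ratio"],
    am_fungi = 0.5 * resp[, "total_plfa"] + 0.5 * resp[, "fb_ratio"])
  plot_groups <- vapply(names(group_scale), function(g)
    group_scale[g] * exp(0.35 * as.numeric(scale(drivers[, g]))),
    numeric(n_plot))
  rows <- list()
  for (g in names(plfa_biomarkers)) {
    lips <- plfa_biomarkers[[g]]
    prop <- seq(1.5, 0.5, length.out = length(lips))
    prop <- prop / sum(prop)
    for (j in seq_along(lips)) {
      plot_val <- plot_groups[, g] * prop[j]
      core_sd <- cfg$core_noise_sd * stats::sd(plot_val)
      for (core in seq_len(cfg$n_cores_per_plot)) {
        rows[[length(rows) + 1L]] <- data.frame(
          plot_id = plot_id,
          core_id = sprintf("%s_C%d", plot_id, core),
          lipid = lips[j],
          concentration = pmax(0, plot_val + rnorm(n_plot, 0, core_sd)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Per-core ASV counts (multinomial over softmax logits, with optional
# Dirichlet overdispersion) and a taxonomy table containing a few archaeal
# and undefined ASVs so the taxonomic filter has work to do.
synth_asv_tables <- function(cfg, plot_id, env_clim, env_soil, traits) {
  K <- cfg$asv_richness_pool
  n_plot <- length(plot_id)
  base_logit <- rnorm(K, 0, 1.3)
  structured <- runif(K) < 0.4
  load_clim <- ifelse(structured, rnorm(K, 0, 0.8), 0)
  load_soil <- ifelse(structured, rnorm(K, 0, 0.8), 0)
  load_trait <- ifelse(structured, rnorm(K, 0, 0.4), 0)
  phyla <- c("Proteobacteria", "Acidobacteria", "Actinobacteria",
             "Verrucomicrobia", "Bacteroidetes", "Planctomycetes",
             "Firmicutes", "Chloroflexi", "Gemmatimonadetes",
             "Nitrospirae")
  asv_ids <- sprintf("ASV%04d", seq_len(K))
  kingdom <- rep("Bacteria", K)
  kingdom[seq_len(max(1, round(0.03 * K)))] <- "Archaea"
  phylum <- sample(phyla, K, replace = TRUE,
                   prob = c(0.22, 0.18, 0.16, 0.09, 0.09, 0.07, 0.06,
                            0.05, 0.04, 0.04))
  undef <- sample(seq_len(K), max(1, round(0.02 * K)))
  phylum[undef] <- "undefined"
  taxonomy <- data.frame(asv = asv_ids, kingdom = kingdom, phylum = phylum,
                         stringsAsFactors = FALSE)
  n_core <- cfg$n_cores_per_plot
  sample_ids <- as.vector(t(outer(plot_id, seq_len(n_core),
                                  function(p, c) sprintf("%s_C%d", p, c))))
  counts <- matrix(0L, length(sample_ids), K,
                   dimnames = list(sample_ids, asv_ids))
  depths <- sample(seq(cfg$read_depth_range[1], cfg$read_depth_range[2]),
                   length(sample_ids), replace = TRUE)
  t1 <- as.numeric(scale(traits[, 1L]))
  row <- 0L
  for (i in seq_len(n_plot)) {
    logits <- base_logit + load_clim * env_clim[i] +
      load_soil * env_soil[i] + load_trait * t1[i]
    for (core in seq_len(n_core)) {
      row <- row + 1L
      counts[row, ] <- draw_asv_counts(logits, depths[row],
                                       cfg$overdispersion)
    }
  }
  list(counts = counts, taxonomy = taxonomy)
}

# Multinomial draw over softmax(logits), optionally Dirichlet-overdispersed.
draw_asv_counts <- function(logits, depth, overdispersion = 0) {
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  if (overdispersion > 0) {
    g <- rgamma(length(p), shape = p / overdispersion)
    if (sum(g) == 0) g <- p
    p <- g / sum(g)
  }
  as.integer(rmultinom(1L, depth, p))
}

#' Draw one ASV count vector from composition logits
#'
#' Multinomial sample of \code{depth} reads over \code{softmax(logits)},
#' with optional Dirichlet overdispersion of the composition. Counts are
#' non-negative integers summing exactly to \code{depth}.
#'
#' @param logits finite numeric vector of per-ASV composition logits.
#' @param depth total reads (>= 1).
#' @param seed integer seed.
#' @param overdispersion Dirichlet overdispersion parameter (0 = none).
#' @return integer vector of counts, same length as \code{logits}.
#' @export
generate_asv_counts <- function(logits, depth, seed = 1,
                                overdispersion = 0) {
  if (!all(is.finite(logits))) stop("non-finite composition logits")
  stopifnot(depth >= 1)
  with_seed(seed, draw_asv_counts(logits, depth, overdispersion))
}
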