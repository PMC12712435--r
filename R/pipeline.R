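# End-to-end orchestration: synthetic data -> spectral preprocessing ->
# temporal alignment -> microbial derivation -> association statistics ->
# ensemble PLSR, from a single config with one master seed.

#' Full PLSR modelling chain for one response
#'
#' Runs the complete predictive workflow on preprocessed spectra: MAE-based
#' outlier screening (before the split, matching the published order of
#' operations), a 70/30 calibration/validation split, PRESS-based component
#' selection on the calibration set, a 200-member ensemble, validation
#' predictions with uncertainty, accuracy metrics, VIP interpretation, and
#' (optionally) single-index linear baselines for comparison.
#'
#' @param X numeric matrix of preprocessed spectra (plots x wavelengths;
#'   trimmed and vector-normalised).
#' @param y response vector, one value per row of \code{X}.
#' @param indices optional named list of per-plot index vectors (e.g.
#'   \code{list(NDVI = ..., NDWI = ...)}) for baseline models.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @param n_models ensemble size (default 200).
#' @param outlier_fraction screened-out fraction (default 0.05).
#' @param calibration_fraction calibration share (default 0.7).
#' @param press_n_perm random splits for component selection (default 200).
#' @param max_components component-scan ceiling (default 15).
#' @param screen_runs outlier-screen repetitions (default 200).
#' @return list with \code{metrics}, \code{n_components},
#'   \code{predictions} (validation data.frame: observed, mean, sd),
#'   \code{vip} (see \code{\link{vip_informative}}), \code{baselines}
#'   (metrics per index), \code{removed} (screened indices), \code{split},
#'   and \code{seeds} (the derived per-stage seeds).
#' @export
plsr_pipeline <- function(X, y, indices = list(), seed = 1, n_models = 200,
                          outlier_fraction = 0.05,
                          calibration_fraction = 0.7, press_n_perm = 200,
                          max_components = 15, screen_runs = 200) {
  X <- as.matrix(X); y <- as.numeric(y)
  seeds <- c(screen = derive_seed(seed, "screen"),
             split = derive_seed(seed, "split"),
             press = derive_seed(seed, "press"),
             ensemble = derive_seed(seed, "ensemble"))
  scr <- outlier_screen(X, y, n_runs = screen_runs,
                        remove_fraction = outlier_fraction,
                        seed = seeds["screen"])
  Xk <- X[scr$kept, , drop = FALSE]
  yk <- y[scr$kept]
  sp <- split_calibration(nrow(Xk), calibration_fraction,
                          seed = seeds["split"])
  Xc <- Xk[sp$calibration, , drop = FALSE]; yc <- yk[sp$calibration]
  Xv <- Xk[sp$validation, , drop = FALSE]; yv <- yk[sp$validation]
  sel <- press_select(Xc, yc, max_components = max_components,
                      n_perm = press_n_perm, seed = seeds["press"])
  ens <- ensemble_fit(Xc, yc, n_components = sel$n_components,
                      n_models = n_models, seed = seeds["ensemble"])
  pv <- ensemble_predict(ens, Xv)
  metrics <- evaluate_predictions(yv, pv$mean)
  baselines <- lapply(indices, function(iv) {
    ivk <- iv[scr$kept]
    baseline_index_model(ivk[sp$calibration], yc,
                         ivk[sp$validation], yv)
  })
  list(metrics = metrics, n_components = sel$n_components,
       predictions = data.frame(observed = yv, predicted = pv$mean,
                                sd = pv$sd),
       press = sel, vip = vip_informative(ens), baselines = baselines,
       removed = scr$removed, split = sp, ensemble = ens, seeds = seeds)
}

#' Pipeline configuration
#'
#' Collects the stage parameters of \code{\link{run_pipeline}}. Defaults
#' follow the standard workflow values: NDVI threshold 0.4, rarefaction
#' depth 5000 reads, alignment windows 60/120 days, 5\% outlier removal,
#' 70/30 calibration split, 200-member ensembles, 999 permutations.
#'
#' @param synth a \code{\link{synth_config}} for the data-generation stage.
#' @param seed master seed for all stochastic stages.
#' @param ndvi_threshold low-vegetation NDVI cut-off.
#' @param keep_ranges retained wavelength windows (nm).
#' @param rarefy_depth reads per sample after rarefaction.
#' @param max_offset_days,cross_table_offset_days alignment windows.
#' @param n_models,outlier_fraction,calibration_fraction,press_n_perm,max_components,screen_runs
#'   PLSR-stage parameters (see \code{\link{plsr_pipeline}}).
#' @param n_perm permutations for partial-RDA tests.
#' @param responses names of response columns to model (default all).
#' @param do_microbial,do_assoc stage toggles (both default \code{TRUE});
#'   turning them off skips microbial derivation / association statistics.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synth = synth_config(), seed = 1,
                            ndvi_threshold = 0.4,
                            keep_ranges = list(c(403, 1334), c(1450, 1785),
                                               c(1971, 2396)),
                            rarefy_depth = 5000, max_offset_days = 60,
                            cross_table_offset_days = 120, n_models = 200,
                            outlier_fraction = 0.05,
                            calibration_fraction = 0.7, press_n_perm = 200,
                            max_components = 15, screen_runs = 200,
                            n_perm = 999, responses = NULL,
                            do_microbial = TRUE, do_assoc = TRUE) {
  structure(mget(names(formals())), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic data generation, spectral preprocessing
#' (NDVI/NDWI computation, low-vegetation filtering, band trimming, vector
#' normalisation), temporal alignment, microbial response derivation (PLFA
#' profiles with shrinkage aggregation; ASV filtering, rarefaction,
#' dominant phyla, richness, Bray-Curtis NMDS), association statistics
#' (variation partitioning with permuted partial RDA over foliar / land
#' cover / soil / climate+location groups), and the ensemble PLSR stage per
#' response. Identical config (including seed) reproduces the report
#' exactly.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return A run report: list with \code{counts} (plots surviving each
#'   stage), \code{exclusions}, \code{plsr} (per-response results of
#'   \code{\link{plsr_pipeline}}), \code{assoc} (variation partitioning and
#'   permutation tests), \code{microbial} (derived plot-level responses),
#'   \code{config} and \code{seed}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dat <- synth_dataset(cfg$synth)
  n0 <- nrow(dat$spectra$reflectance)

  # --- spectral preprocessing (indices on raw spectra, pre-trim) ---------
  ndvi <- compute_index(dat$spectra, "NDVI")
  ndwi <- compute_index(dat$spectra, "NDWI")
  filt <- filter_by_ndvi(dat$spectra, cfg$ndvi_threshold)
  prepped <- vector_normalize(trim_bands(filt$spectra, cfg$keep_ranges))

  # --- temporal alignment ------------------------------------------------
  al <- align_observations(
    image_dates = data.frame(plot_id = dat$plots$plot_id,
                             year = dat$plots$year,
                             date = dat$plots$image_date),
    soil_dates = data.frame(plot_id = dat$plots$plot_id,
                            year = dat$plots$year,
                            date = dat$plots$soil_date),
    other_dates = list(
      foliar = data.frame(plot_id = dat$plots$plot_id,
                          year = dat$plots$year,
                          date = dat$plots$foliar_date)),
    max_offset_days = cfg$max_offset_days,
    cross_table_offset_days = cfg$cross_table_offset_days)
  keep_ids <- intersect(prepped$plot_ids, al$kept$plot_id)
  if (!length(keep_ids))
    stop("no plots survive the NDVI and temporal-alignment filters")
  keep_rows <- match(keep_ids, prepped$plot_ids)
  X <- prepped$reflectance[keep_rows, , drop = FALSE]
  resp <- dat$responses[match(keep_ids, dat$responses$plot_id), ,
                        drop = FALSE]
  ndvi_k <- ndvi[keep_ids]; ndwi_k <- ndwi[keep_ids]

  # --- microbial derivation ---------------------------------------------
  microbial <- NULL
  if (isTRUE(cfg$do_microbial)) {
    prof <- plfa_groups(data.frame(
      sample_id = dat$lipid_cores$core_id,
      lipid = dat$lipid_cores$lipid,
      concentration = dat$lipid_cores$concentration))
    core_map <- unique(dat$lipid_cores[, c("plot_id", "core_id")])
    long <- do.call(rbind, lapply(
      setdiff(names(prof), "sample_id"), function(v)
        data.frame(plot_id = core_map$plot_id[
                     match(prof$sample_id, core_map$core_id)],
                   core_id = prof$sample_id, variable = v,
                   value = prof[[v]], stringsAsFactors = FALSE)))
    plfa_plot <- aggregate_cores(long, method = "shrinkage")

    ft <- filter_taxa(dat$asv_counts, dat$asv_taxonomy)
    rar <- rarefy_counts(ft$counts, cfg$rarefy_depth,
                         seed = derive_seed(cfg$seed, "rarefy"))
    plot_of <- sub("_C[0-9]+$", "", rownames(rar$counts))
    plot_asv <- rowsum(rar$counts, plot_of) /
      as.vector(table(plot_of)[sort(unique(plot_of))])
    rich_core <- asv_richness(rar$counts)
    richness_plot <- tapply(rich_core, plot_of, mean)
    dp <- dominant_phyla(plot_asv, ft$taxonomy)  # ubiquity across plots
    bc <- bray_curtis(plot_asv)
    nm <- nmds_ordination(bc, k = 2,
                          seed = derive_seed(cfg$seed, "nmds"))
    microbial <- list(plfa = plfa_plot, asv_plot = plot_asv,
                      richness = richness_plot, dominant = dp,
                      nmds = nm, rarefied_dropped = rar$dropped,
                      taxa_removed = ft$removed)
  }

  # --- association statistics -------------------------------------------
  assoc <- NULL
  if (isTRUE(cfg$do_assoc)) {
    ids <- dat$plots$plot_id
    lc <- stats::model.matrix(~ land_cover, data = dat$plots)[, -1,
                                                             drop = FALSE]
    grp <- list(
      foliar = pca_leading_axes(dat$traits[, -1])$scores,
      land_cover = lc,
      soil = pca_leading_axes(dat$soil[, -1])$scores,
      climate_location = pca_leading_axes(dat$climate[, -1])$scores)
    Y <- scale(as.matrix(dat$responses[, -1]))
    vp <- varpart_groups(Y, grp)
    tests <- lapply(names(grp), function(g)
      partial_rda_test(Y, grp[[g]],
                       do.call(cbind, grp[setdiff(names(grp), g)]),
                       n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, paste0("rda_", g))))
    names(tests) <- names(grp)
    assoc <- list(varpart = vp, tests = tests, groups = lapply(grp, ncol))
  }

  # --- ensemble PLSR per response ---------------------------------------
  resp_names <- cfg$responses %||% setdiff(names(resp), "plot_id")
  plsr <- lapply(resp_names, function(rn)
    plsr_pipeline(X, resp[[rn]],
                  indices = list(NDVI = ndvi_k, NDWI = ndwi_k),
                  seed = derive_seed(cfg$seed, paste0("plsr_", rn)),
                  n_models = cfg$n_models,
                  outlier_fraction = cfg$outlier_fraction,
                  calibration_fraction = cfg$calibration_fraction,
                  press_n_perm = cfg$press_n_perm,
                  max_components = cfg$max_components,
                  screen_runs = cfg$screen_runs))
  names(plsr) <- resp_names

  list(counts = c(generated = n0,
                  ndvi_survivors = length(filt$spectra$plot_ids),
                  aligned = nrow(al$kept),
                  modelled = length(keep_ids)),
       exclusions = list(ndvi = filt$exclusions,
                         alignment = al$exclusions),
       microbial = microbial, assoc = assoc, plsr = plsr,
       truth = dat$truth, config = cfg, seed = cfg$seed)
}
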