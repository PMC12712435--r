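# Core-to-plot aggregation and temporal alignment of multi-source plot data.

#' Aggregate core-level measurements to plot level
#'
#' Soil and lipid measurements are taken on several cores per plot; models
#' operate at plot level. Two aggregation methods:
#' \describe{
#'   \item{mean}{arithmetic mean of core values per plot and variable.}
#'   \item{shrinkage}{empirical-Bayes normal-normal partial pooling: each
#'     plot mean is shrunk toward the across-plot (site-level) mean with
#'     weight \code{(s2/n_p) / (s2/n_p + tau2)}, where \code{s2} is the
#'     pooled within-plot variance and \code{tau2} the between-plot variance
#'     estimated by method of moments (floored at zero). Plots with few
#'     cores are pulled hardest toward the site mean; with \code{tau2 =
#'     Inf} the estimate reduces to the plain plot mean. This is a
#'     closed-form stabilised plot estimate in the spirit of hierarchical
#'     plot-averaging models.}
#' }
#'
#' @param cores data.frame with columns \code{plot_id}, \code{core_id},
#'   \code{variable}, \code{value}.
#' @param method \code{"mean"} or \code{"shrinkage"}.
#' @param tau2 optional fixed between-plot variance (overrides the
#'   method-of-moments estimate; \code{Inf} disables pooling).
#' @return data.frame plot_id x variable (wide), one row per plot; plots
#'   with no finite value for a variable get \code{NA}.
#' @export
aggregate_cores <- function(cores, method = c("mean", "shrinkage"),
                            tau2 = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("plot_id", "variable", "value") %in% names(cores)))
  plots <- unique(cores$plot_id)
  vars <- unique(cores$variable)
  out <- matrix(NA_real_, length(plots), length(vars),
                dimnames = list(plots, vars))
  for (v in vars) {
    sub <- cores[cores$variable == v & is.finite(cores$value), ]
    if (!nrow(sub)) next
    m <- tapply(sub$value, factor(sub$plot_id, levels = plots), mean)
    if (method == "mean") {
      out[, v] <- as.numeric(m)
      next
    }
    n_p <- tapply(rep(1, nrow(sub)), factor(sub$plot_id, levels = plots), sum)
    n_p[is.na(n_p)] <- 0
    # pooled within-plot variance from plots with >= 2 cores
    ss <- tapply(sub$value, factor(sub$plot_id, levels = plots),
                 function(x) sum((x - mean(x))^2))
    df <- pmax(n_p - 1, 0)
    s2 <- if (sum(df, na.rm = TRUE) > 0)
      sum(ss, na.rm = TRUE) / sum(df, na.rm = TRUE) else 0
    site_mean <- mean(m, na.rm = TRUE)
    ok <- !is.na(m)
    t2 <- tau2 %||% max(
      stats::var(m[ok]) - s2 * mean(1 / n_p[ok]), 0)
    shrink <- if (is.infinite(t2)) rep(0, sum(ok)) else
      (s2 / n_p[ok]) / (s2 / n_p[ok] + t2)
    shrink[is.nan(shrink)] <- 0  # s2 = 0 and t2 = 0: degenerate, keep mean
    est <- shrink * site_mean + (1 - shrink) * m[ok]
    out[ok, v] <- as.numeric(est)
  }
  data.frame(plot_id = plots, out, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Temporally align multi-source plot observations
#'
#' Retains plots whose soil (microbial) sampling date falls within
#' \code{max_offset_days} of an airborne image date (inclusive), and whose
#' other tables (foliar traits, soil properties, ...) fall within
#' \code{cross_table_offset_days} of the imagery. When a plot qualifies in
#' several years, only the year with the smallest absolute soil-image gap is
#' kept (ties: earliest year). Calendar-day differences ignore time of day.
#'
#' @param image_dates data.frame \code{plot_id}, \code{year}, \code{date}
#'   (Date or parseable character) of airborne acquisitions.
#' @param soil_dates data.frame \code{plot_id}, \code{year}, \code{date} of
#'   soil microbial sampling.
#' @param other_dates optional named list of data.frames with the same
#'   columns for additional data sources.
#' @param max_offset_days soil vs image window (default 60, inclusive).
#' @param cross_table_offset_days other sources vs image window
#'   (default 120, inclusive).
#' @return list with \code{kept} (data.frame plot_id, year, soil_image_gap)
#'   and \code{exclusions} (plot_id, year, rule, offset_days).
#' @export
align_observations <- function(image_dates, soil_dates, other_dates = list(),
                               max_offset_days = 60,
                               cross_table_offset_days = 120) {
  stopifnot(max_offset_days > 0, cross_table_offset_days > 0)
  as_day <- function(x) as.integer(as.Date(x))
  img <- data.frame(plot_id = image_dates$plot_id, year = image_dates$year,
                    img_day = as_day(image_dates$date))
  soil <- data.frame(plot_id = soil_dates$plot_id, year = soil_dates$year,
                     soil_day = as_day(soil_dates$date))
  cand <- merge(img, soil, by = c("plot_id", "year"))
  cand$gap <- abs(cand$soil_day - cand$img_day)
  excl <- list()
  ok <- cand$gap <= max_offset_days
  if (any(!ok))
    excl[["soil_image"]] <- data.frame(
      plot_id = cand$plot_id[!ok], year = cand$year[!ok],
      rule = "soil_image_window", offset_days = cand$gap[!ok])
  cand <- cand[ok, , drop = FALSE]
  for (nm in names(other_dates)) {
    tab <- other_dates[[nm]]
    t2 <- data.frame(plot_id = tab$plot_id, year = tab$year,
                     oth_day = as_day(tab$date))
    m <- merge(cand, t2, by = c("plot_id", "year"))
    m$oth_gap <- abs(m$oth_day - m$img_day)
    bad <- m$oth_gap > cross_table_offset_days
    if (any(bad))
      excl[[nm]] <- data.frame(
        plot_id = m$plot_id[bad], year = m$year[bad],
        rule = paste0(nm, "_image_window"), offset_days = m$oth_gap[bad])
    drop_key <- paste(m$plot_id[bad], m$year[bad])
    cand <- cand[!(paste(cand$plot_id, cand$year) %in% drop_key), ,
                 drop = FALSE]
  }
  # keep the best year per plot: smallest soil-image gap, ties -> earliest
  cand <- cand[order(cand$plot_id, cand$gap, cand$year), ]
  best <- !duplicated(cand$plot_id)
  if (any(!best))
    excl[["multi_year"]] <- data.frame(
      plot_id = cand$plot_id[!best], year = cand$year[!best],
      rule = "larger_gap_year", offset_days = cand$gap[!best])
  kept <- cand[best, c("plot_id", "year", "gap")]
  names(kept)[3L] <- "soil_image_gap"
  rownames(kept) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
    else data.frame(plot_id = character(), year = integer(),
                    rule = character(), offset_days = numeric())
  list(kept = kept, exclusions = exclusions)
}
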