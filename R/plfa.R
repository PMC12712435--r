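# PLFA biomarker vocabulary. Group membership follows the standard
# biomarker assignments for soil lipid profiling; 16:1w7cis is kept with the
# saprophytic fungi as conventionally reported for this data product, but the
# mapping is user-overridable via the `groups` argument of plfa_groups().
plfa_biomarkers <- list(
  gram_positive     = c("i14:0", "i15:0", "i16:0", "i17:0", "a15:0", "a17:0"),
  gram_negative     = c("cyclo17:0", "cyclo19:0"),
  actinomycetales   = c("10Me16:0", "10Me17:0", "10Me18:0"),
  saprophytic_fungi = c("16:1w7cis", "18:2w6", "18:3w6"),
  am_fungi          = c("16:1w5")
)

#' PLFA functional-group abundances and ratios
#'
#' Sums per-sample lipid concentrations (nmol per g dry soil) into broad
#' microbial groups and derives the two standard community ratios:
#' \describe{
#'   \item{fb_ratio (F:B)}{(saprophytic fungi + AM fungi) /
#'     (Gram-positive + Gram-negative + Actinomycetales). Actinomycetales are
#'     Gram-positive bacteria, so they are counted in the bacterial sum.}
#'   \item{gp_gn_ratio (G+:G-)}{Gram-positive / Gram-negative.}
#' }
#' \code{total} is the sum of all supplied biomarker concentrations and
#' proxies total viable microbial biomass. Ratios with zero denominators are
#' returned as \code{NA} (flagged undefined).
#'
#' @param lipids data.frame with columns \code{sample_id}, \code{lipid},
#'   \code{concentration} (nmol/g, non-negative). Every biomarker in
#'   \code{groups} must be present for every sample.
#' @param groups named list mapping group name to lipid names; defaults to
#'   the standard soil biomarker set (see \code{spectromicrobe:::plfa_biomarkers}).
#' @return data.frame with one row per sample: the five group sums,
#'   \code{total}, \code{fb_ratio} and \code{gp_gn_ratio}.
#' @export
plfa_groups <- function(lipids, groups = plfa_biomarkers) {
  stopifnot(all(c("sample_id", "lipid", "concentration") %in% names(lipids)))
  if (any(lipids$concentration < 0)) stop("negative lipid concentration")
  need <- unlist(groups, use.names = FALSE)
  samples <- unique(lipids$sample_id)
  wide <- matrix(NA_real_, length(samples), length(need),
                 dimnames = list(samples, need))
  known <- lipids$lipid %in% need
  idx <- cbind(match(lipids$sample_id[known], samples),
               match(lipids$lipid[known], need))
  wide[idx] <- lipids$concentration[known]
  missing <- need[colSums(is.na(wide)) > 0]
  if (length(missing))
    stop("missing biomarker lipid(s): ", paste(missing, collapse = ", "))
  sums <- vapply(groups, function(g)
    rowSums(wide[, g, drop = FALSE]), numeric(length(samples)))
  sums <- matrix(sums, nrow = length(samples),
                 dimnames = list(samples, names(groups)))
  bact <- sums[, "gram_positive"] + sums[, "gram_negative"] +
    sums[, "actinomycetales"]
  fung <- sums[, "saprophytic_fungi"] + sums[, "am_fungi"]
  data.frame(
    sample_id = samples,
    as.data.frame(sums),
    total = rowSums(wide),
    fb_ratio = ifelse(bact > 0, fung / bact, NA_real_),
    gp_gn_ratio = ifelse(sums[, "gram_negative"] > 0,
                         sums[, "gram_positive"] / sums[, "gram_negative"],
                         NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}
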