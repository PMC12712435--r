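#' Construct a spectra matrix
#'
#' Container for plot-level surface reflectance: a numeric matrix with one
#' row per plot and one column per wavelength, plus an explicit wavelength
#' grid in nanometres. Negative reflectance values (atmospheric-correction
#' artifacts) are clipped to zero on ingest; the number clipped is recorded
#' in the \code{"n_clipped"} attribute.
#'
#' @param reflectance numeric matrix, plots x wavelengths; unitless surface
#'   reflectance.
#' @param wavelengths strictly increasing numeric vector of band-centre
#'   wavelengths in nm; length must equal \code{ncol(reflectance)}.
#' @param plot_ids character vector of plot identifiers; length must equal
#'   \code{nrow(reflectance)}.
#' @return An object of class \code{spectra_matrix}.
#' @export
spectra_matrix <- function(reflectance, wavelengths, plot_ids = NULL) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(reflectance))
    stop("wavelength grid length (", length(wavelengths),
         ") does not match spectra columns (", ncol(reflectance), ")")
  if (any(diff(wavelengths) <= 0) || any(wavelengths <= 0))
    stop("wavelength grid must be positive and strictly increasing")
  if (is.null(plot_ids)) plot_ids <- rownames(reflectance) %||%
      sprintf("plot_%03d", seq_len(nrow(reflectance)))
  plot_ids <- as.character(plot_ids)
  if (length(plot_ids) != nrow(reflectance))
    stop("plot_ids length does not match spectra rows")
  n_clipped <- sum(reflectance < 0, na.rm = TRUE)
  if (n_clipped > 0) reflectance[reflectance < 0] <- 0
  dimnames(reflectance) <- list(plot_ids, format_wl(wavelengths))
  structure(
    list(reflectance = reflectance, wavelengths = wavelengths,
         plot_ids = plot_ids),
    n_clipped = n_clipped, class = "spectra_matrix")
}

format_wl <- function(wl) sprintf("%g", wl)

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d plots x %d bands, %g-%g nm\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$reflectance)

#' Resample spectra onto a target wavelength grid
#'
#' Linear interpolation of each spectrum onto \code{target} wavelengths,
#' used to bring imagery from different acquisition years (whose band
#' centres drift with annual sensor calibration) onto one common grid.
#' Interpolation is exact for spectra that are affine in wavelength; no
#' extrapolation is permitted.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param target numeric vector of target wavelengths (nm), strictly
#'   increasing, contained in the span of the source grid.
#' @return A \code{spectra_matrix} on the target grid.
#' @export
resample_spectra <- function(spectra, target) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  target <- as.numeric(target)
  src <- spectra$wavelengths
  out_of_span <- target[target < min(src) | target > max(src)]
  if (length(out_of_span))
    stop("target wavelengths outside source span: ",
         paste(format_wl(out_of_span), collapse = ", "))
  out <- t(apply(spectra$reflectance, 1L, function(r)
    stats::approx(src, r, xout = target, method = "linear")$y))
  spectra_matrix(out, target, spectra$plot_ids)
}

#' Mean spectrum over a circular plot buffer
#'
#' Averages the pixel spectra of a gridded reflectance patch over a circular
#' buffer centred on the plot centre (default 20 m diameter). A pixel is
#' included when its centre lies strictly within \code{diameter_m / 2} of the
#' plot centre; ties at exactly the radius are excluded, so membership is
#' deterministic and grid-independent.
#'
#' @param patch list with \code{reflectance} (rows x cols x bands array),
#'   \code{wavelengths}, \code{pixel_size_m} (default 1), and \code{centre}
#'   (numeric length-2, metres, in the patch coordinate frame where pixel
#'   \code{[i, j]} has centre \code{((j - 0.5) * px, (i - 0.5) * px)}).
#' @param diameter_m buffer diameter in metres; must exceed the pixel size.
#' @return list with \code{spectrum} (mean reflectance per band) and
#'   \code{n_pixels} (number of pixels averaged).
#' @export
buffer_mean <- function(patch, diameter_m = 20) {
  a <- patch$reflectance
  stopifnot(length(dim(a)) == 3L)
  px <- patch$pixel_size_m %||% 1
  if (diameter_m <= px) stop("buffer diameter must exceed pixel spacing")
  nr <- dim(a)[1L]; nc <- dim(a)[2L]
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * px
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * px
  d2 <- (cx - patch$centre[1L])^2 + (cy - patch$centre[2L])^2
  keep <- d2 < (diameter_m / 2)^2
  if (!any(keep)) stop("no pixel centres fall inside the buffer")
  flat <- matrix(a, nrow = nr * nc)  # pixels x bands, column-major as cx/cy
  list(spectrum = colMeans(flat[keep, , drop = FALSE]),
       n_pixels = sum(keep))
}

# Nearest-band lookup; the ~5 nm grid makes nominal index wavelengths
# (804, 673, 860, 1240 nm) inexact, so resolve to the closest band and
# refuse matches further than `tol_nm` away.
nearest_band <- function(wavelengths, nominal, tol_nm = 3) {
  i <- which.min(abs(wavelengths - nominal))
  if (abs(wavelengths[i] - nominal) > tol_nm)
    stop(sprintf("no band within %g nm of %g nm", tol_nm, nominal))
  i
}

#' Normalized-difference spectral index
#'
#' Computes \code{(R_a - R_b) / (R_a + R_b)} per plot with bands resolved by
#' the nearest-band rule (within 3 nm). Built-in specs: NDVI uses
#' 804 / 673 nm; NDWI uses 860 / 1240 nm. Plots whose denominator is zero
#' get \code{NA} (flagged for downstream exclusion).
#'
#' @param spectra a \code{\link{spectra_matrix}} (raw, pre-normalisation
#'   reflectance; both indices are invariant to positive scaling so the
#'   choice only matters for zero denominators).
#' @param index \code{"NDVI"}, \code{"NDWI"}, or a list with fields
#'   \code{name}, \code{band_a}, \code{band_b} (nm).
#' @return named numeric vector of index values per plot, in [-1, 1].
#' @export
compute_index <- function(spectra, index = "NDVI") {
  spec <- index_spec(index)
  ia <- nearest_band(spectra$wavelengths, spec$band_a)
  ib <- nearest_band(spectra$wavelengths, spec$band_b)
  ra <- spectra$reflectance[, ia]
  rb <- spectra$reflectance[, ib]
  den <- ra + rb
  val <- ifelse(den == 0, NA_real_, (ra - rb) / den)
  setNames(val, spectra$plot_ids)
}

index_spec <- function(index) {
  if (is.list(index)) {
    stopifnot(index$band_a != index$band_b)
    return(index)
  }
  switch(toupper(index),
    NDVI = list(name = "NDVI", band_a = 804, band_b = 673),
    NDWI = list(name = "NDWI", band_a = 860, band_b = 1240),
    stop("unknown index: ", index))
}

#' Remove plots with low vegetation cover by NDVI threshold
#'
#' Drops plots whose NDVI is strictly below \code{threshold} (default 0.4),
#' plus any plot whose NDVI is undefined. Survivor order is preserved and
#' every exclusion is logged with its value.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param threshold NDVI cut-off; plots with \code{NDVI < threshold} are
#'   removed (strict inequality, so a plot exactly at the threshold stays).
#' @return list with \code{spectra} (survivors) and \code{exclusions}
#'   (data.frame plot_id / reason / value).
#' @export
filter_by_ndvi <- function(spectra, threshold = 0.4) {
  ndvi <- compute_index(spectra, "NDVI")
  drop <- is.na(ndvi) | ndvi < threshold
  excl <- data.frame(plot_id = spectra$plot_ids[drop],
                     reason = ifelse(is.na(ndvi[drop]), "ndvi_undefined",
                                     "ndvi_below_threshold"),
                     value = unname(ndvi[drop]),
                     stringsAsFactors = FALSE)
  if (all(drop)) warning("all plots removed by NDVI filter")
  out <- spectra_matrix(spectra$reflectance[!drop, , drop = FALSE],
                        spectra$wavelengths, spectra$plot_ids[!drop])
  list(spectra = out, exclusions = excl, ndvi = ndvi)
}

#' Trim spectra to retained wavelength ranges
#'
#' Keeps only bands whose wavelength lies inside one of the closed intervals
#' in \code{keep_ranges}; used to discard noisy detector edges and the
#' atmospheric water-vapour absorption windows. The default retains
#' 403-1334, 1450-1785 and 1971-2396 nm.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param keep_ranges list of \code{c(lo, hi)} nm intervals, increasing and
#'   non-overlapping; both endpoints are included.
#' @return A \code{spectra_matrix} restricted to the kept bands.
#' @export
trim_bands <- function(spectra,
                       keep_ranges = list(c(403, 1334), c(1450, 1785),
                                          c(1971, 2396))) {
  lo <- vapply(keep_ranges, `[`, numeric(1), 1L)
  hi <- vapply(keep_ranges, `[`, numeric(1), 2L)
  if (any(hi < lo) || is.unsorted(lo) || any(utils::head(hi, -1) >= lo[-1]))
    stop("keep_ranges must be increasing and non-overlapping")
  wl <- spectra$wavelengths
  keep <- Reduce(`|`, lapply(seq_along(lo),
                             function(k) wl >= lo[k] & wl <= hi[k]))
  if (!any(keep)) stop("band trimming removed every band")
  spectra_matrix(spectra$reflectance[, keep, drop = FALSE], wl[keep],
                 spectra$plot_ids)
}

#' Vector-normalise spectra to unit Euclidean norm
#'
#' Divides each plot's reflectance by its full-spectrum Euclidean (L2) norm
#' so that every row has length one; this suppresses brightness differences
#' caused by internal canopy shade while preserving spectral shape. Applied
#' after band trimming and before PLSR modelling.
#'
#' @param spectra a \code{\link{spectra_matrix}} with no all-zero rows.
#' @return A \code{spectra_matrix} whose rows have unit L2 norm.
#' @export
vector_normalize <- function(spectra) {
  norms <- sqrt(rowSums(spectra$reflectance^2))
  zero <- norms == 0
  if (any(zero))
    stop("cannot vector-normalise all-zero spectra for plot(s): ",
         paste(spectra$plot_ids[zero], collapse = ", "))
  spectra_matrix(spectra$reflectance / norms, spectra$wavelengths,
                 spectra$plot_ids)
}

#' Read / write a spectra matrix as CSV
#'
#' The CSV layout has one row per plot: a \code{plot_id} column followed by
#' one column per band named by its wavelength in nm.
#'
#' @param path file path.
#' @param spectra a \code{\link{spectra_matrix}} (for writing).
#' @return \code{read_spectra_csv} returns a \code{spectra_matrix};
#'   \code{write_spectra_csv} returns \code{path} invisibly.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-1L])
  spectra_matrix(as.matrix(df[, -1L, drop = FALSE]), wl,
                 as.character(df[[1L]]))
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(plot_id = spectra$plot_ids,
                   spectra$reflectance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
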