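# NoCA-phase detector: per-pixel Fourier features, component-wise z-scoring,
# component summation into a pollution-emphasis image, thresholding into the
# core-region map. Before the colour agent arrives only dark noise is
# expected, so any pixel with excess energy in some frequency component --
# a static offset (DC) or a flicker (non-DC) -- stands out after the
# per-component z-score puts all components on a common scale.

#' Per-pixel Fourier magnitudes of the NoCA phase
#'
#' Takes the discrete Fourier transform of every admissible pixel's length-L
#' NoCA timeline (plain forward transform, no 1/L normalization -- any fixed
#' scaling cancels in the later z-score) and keeps the magnitudes of the
#' first `ceiling(L/2)` components, including the zero-frequency (DC) term.
#' The second half of the spectrum is redundant for a real signal.
#'
#' @param noca_stack the NoCA-phase [fo_stack()], at least 4 frames long.
#' @return An object of class `fourier_features`: list with `magnitudes`
#'   (matrix, one row per admissible pixel, `m = ceiling(L/2)` columns),
#'   `pixel_idx` (linear indices of the admissible pixels, column-major),
#'   `dim` (spatial dimensions) and `L` (phase length).
#' @export
pixel_fourier_magnitudes <- function(noca_stack) {
  stopifnot_stack(noca_stack)
  d <- dim(noca_stack$counts)
  L <- d[3]
  if (L < 4L) stop("NoCA phase too short (need at least 4 frames)")
  adm <- which(!as.vector(noca_stack$excluded))
  if (length(adm) == 0L) stop("no admissible pixels")
  m <- ceiling(L / 2)
  flat <- matrix(noca_stack$counts, d[1] * d[2], L)
  tl <- t(flat[adm, , drop = FALSE])           # L x n, one column per pixel
  spec <- stats::mvfft(tl)
  mags <- t(Mod(spec[seq_len(m), , drop = FALSE]))
  structure(list(magnitudes = mags, pixel_idx = adm, dim = d[1:2], L = L),
            class = "fourier_features")
}

#' Z-score Fourier components across pixels
#'
#' Normalizes each retained Fourier component over all admissible pixels:
#' `(x - mu_j) / sigma_j`, with `mu_j` the component mean and `sigma_j` the
#' population standard deviation of component `j` across the n pixels. A
#' component that is constant across pixels (`sigma_j = 0`) carries no
#' discriminative information and is mapped to an all-zero column instead of
#' dividing by zero.
#'
#' @param ffs a `fourier_features` object.
#' @return list with `features` (the normalized `fourier_features`) and
#'   `stats` (list of per-component `mu` and `sigma`).
#' @export
zscore_components <- function(ffs) {
  if (!inherits(ffs, "fourier_features"))
    stop("expected a `fourier_features` object")
  x <- ffs$magnitudes
  n <- nrow(x)
  if (n < 2L) stop("insufficient pixels for normalization")
  mu <- colMeans(x)
  centred <- sweep(x, 2L, mu)
  sigma <- sqrt(colMeans(centred^2))           # population standard deviation
  z <- sweep(centred, 2L, ifelse(sigma > 0, sigma, 1), "/")
  z[, sigma == 0] <- 0
  out <- ffs
  out$magnitudes <- z
  list(features = out, stats = list(mu = mu, sigma = sigma))
}

#' Sum z-scored components into the pollution-emphasis image
#'
#' For each pixel the z-scored components are summed, yielding one score per
#' pixel; the scores are reshaped to the spatial grid. Excluded pixels carry
#' `NA` ("not scored"), never a fabricated score.
#'
#' @param normalized the z-scored `fourier_features` (first element of
#'   [zscore_components()]'s result).
#' @return An object of class `score_image`: list with `scores` (numeric
#'   `height x width` matrix, `NA` where not scored) and `phase_tag`.
#' @export
sum_components <- function(normalized) {
  if (!inherits(normalized, "fourier_features"))
    stop("expected a `fourier_features` object")
  pxl <- rowSums(normalized$magnitudes)
  img <- matrix(NA_real_, normalized$dim[1], normalized$dim[2])
  img[normalized$pixel_idx] <- pxl
  structure(list(scores = img, phase_tag = "noca"), class = "score_image")
}

#' Threshold the NoCA score image into the core-region map
#'
#' Pixels scoring above the threshold are foreground; 8-connected components
#' smaller than `min_area` pixels are removed. When `z_thresh` is `NULL`
#' (the default) the threshold is set robustly from the score image itself:
#' the median plus `z_mult` times the median-absolute-deviation estimate of
#' the scores' standard deviation. An empty mask is a valid
#' "no pollution in this phase" outcome.
#'
#' @param score a NoCA `score_image`.
#' @param z_thresh absolute score threshold, or `NULL` for the robust default.
#' @param z_mult multiplier of the robust standard deviation used when
#'   `z_thresh` is `NULL`.
#' @param min_area minimum component size in pixels.
#' @return logical `height x width` core-region mask.
#' @export
threshold_noca <- function(score, z_thresh = NULL, z_mult = 2.5, min_area = 5L) {
  if (!inherits(score, "score_image") || score$phase_tag != "noca")
    stop("expected a NoCA `score_image`")
  v <- score$scores[!is.na(score$scores)]
  if (length(v) == 0L) stop("no admissible pixels")
  if (is.null(z_thresh))
    z_thresh <- stats::median(v) + z_mult * stats::mad(v)
  fg <- !is.na(score$scores) & score$scores > z_thresh
  filter_small_components(fg, min_area)
}
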