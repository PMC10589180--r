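# Flush-out-phase detector. After the time point of full illumination the
# dye signal decays smoothly; ambient light shows up as rapid, localized
# signal changes. Each frame is high-pass filtered in the 2-D frequency
# domain (suppressing the smooth, low-resolution hand signal), the temporal
# standard deviation is computed interval-wise (so the globally decaying
# amplitude cannot drown late fluctuations), each interval map is min-max
# normalized, the maps are summed, rescaled to 0..255 and thresholded.

#' Gaussian high-pass filter a single frame
#'
#' Multiplies the frame's 2-D DFT spectrum by `1 - G`, where `G` is a
#' centred Gaussian of width `cutoff_sigma` (in frequency-space pixels) with
#' `G = 1` at zero frequency, and returns the real part of the inverse
#' transform. The zero-frequency gain is exactly 0, so the output mean over
#' all pixels is 0 up to numerical tolerance.
#'
#' @param frame numeric matrix, at least 4x4, all finite.
#' @param cutoff_sigma positive Gaussian width in frequency pixels.
#' @return numeric matrix of the same shape.
#' @export
gaussian_highpass <- function(frame, cutoff_sigma) {
  frame <- as.matrix(frame)
  if (nrow(frame) < 4L || ncol(frame) < 4L)
    stop("frame must be at least 4x4")
  if (anyNA(frame) || !all(is.finite(frame)))
    stop("frame must be finite")
  if (!is.numeric(cutoff_sigma) || cutoff_sigma <= 0)
    stop("`cutoff_sigma` must be positive")
  g <- highpass_gain(nrow(frame), ncol(frame), cutoff_sigma)
  spec <- stats::fft(frame) * g
  Re(stats::fft(spec, inverse = TRUE)) / length(frame)
}

# 1 - G gain grid in the unshifted DFT layout
highpass_gain <- function(h, w, cutoff_sigma) {
  fy <- pmin(0:(h - 1L), h - 0:(h - 1L))
  fx <- pmin(0:(w - 1L), w - 0:(w - 1L))
  d2 <- outer(fy^2, fx^2, "+")
  1 - exp(-d2 / (2 * cutoff_sigma^2))
}

#' High-pass filter every frame of a flush-out stack
#'
#' @param flushout_stack the flush-out-phase [fo_stack()].
#' @param cutoff_sigma Gaussian width in frequency pixels; `NULL` selects the
#'   default `min(height, width) / 16`.
#' @return numeric array `height x width x frames` of filtered frames.
#' @export
highpass_stack <- function(flushout_stack, cutoff_sigma = NULL) {
  stopifnot_stack(flushout_stack)
  d <- dim(flushout_stack$counts)
  if (is.null(cutoff_sigma)) cutoff_sigma <- min(d[1], d[2]) / 16
  g <- highpass_gain(d[1], d[2], cutoff_sigma)
  out <- array(0, d)
  for (f in seq_len(d[3])) {
    spec <- stats::fft(flushout_stack$counts[, , f]) * g
    out[, , f] <- Re(stats::fft(spec, inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

#' Interval-wise temporal standard deviation maps
#'
#' Splits the filtered flush-out frames into consecutive intervals of
#' `interval_len` frames (a trailing interval of fewer than 2 frames, whose
#' standard deviation would be undefined, is merged into the previous one),
#' computes each pixel's temporal standard deviation per interval and
#' min-max normalizes every map to `[0, 1]` over all admissible pixels. A
#' constant map (max = min) maps to all zeros.
#'
#' @param filtered numeric array `height x width x frames` (e.g. the result
#'   of [highpass_stack()]).
#' @param interval_len frames per interval, at least 2.
#' @param excluded optional logical matrix of pixels to skip (mapped to `NA`).
#' @return An object of class `interval_std_maps`: list with `maps` (list of
#'   normalized matrices) and `interval_len`.
#' @export
interval_std_maps <- function(filtered, interval_len = 30L, excluded = NULL) {
  if (!is.array(filtered) || length(dim(filtered)) != 3L)
    stop("`filtered` must be a 3-D array")
  d <- dim(filtered)
  if (d[3] < 2L) stop("flush-out too short (need at least 2 frames)")
  interval_len <- as.integer(interval_len)
  if (interval_len < 2L) stop("`interval_len` must be at least 2")
  if (is.null(excluded)) excluded <- matrix(FALSE, d[1], d[2])

  starts <- seq.int(1L, d[3], by = interval_len)
  ends <- pmin(starts + interval_len - 1L, d[3])
  k <- length(starts)
  if (k > 1L && (ends[k] - starts[k] + 1L) < 2L) {  # merge short tail
    ends[k - 1L] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }

  flat <- matrix(filtered, d[1] * d[2], d[3])
  adm <- !as.vector(excluded)
  maps <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    seg <- flat[, starts[i]:ends[i], drop = FALSE]
    mu <- rowMeans(seg)
    s <- sqrt(rowSums((seg - mu)^2) / (ncol(seg) - 1L))   # sample sd
    s[!adm] <- NA_real_
    maps[[i]] <- matrix(minmax_norm(s), d[1], d[2])
  }
  structure(list(maps = maps, interval_len = interval_len),
            class = "interval_std_maps")
}

minmax_norm <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] == r[1]) return(ifelse(is.na(x), NA_real_, 0))
  (x - r[1]) / (r[2] - r[1])
}

#' Sum interval maps and rescale to 0..255
#'
#' Pixel-wise sum of the normalized interval maps, affinely rescaled so the
#' admissible minimum maps to 0 and the maximum to 255, rounded half away
#' from zero. A constant sum image maps to all zeros. The rescale is
#' invariant to a common positive factor on the maps.
#'
#' @param maps an `interval_std_maps` object.
#' @return An object of class `summation_image`: list with `image`
#'   (integer matrix with values in 0..255, `NA` where not scored).
#' @export
sum_and_rescale <- function(maps) {
  if (!inherits(maps, "interval_std_maps"))
    stop("expected an `interval_std_maps` object")
  if (length(maps$maps) < 1L) stop("need at least one interval map")
  s <- Reduce(`+`, maps$maps)
  r <- range(s, na.rm = TRUE)
  img <- if (r[2] == r[1]) {
    ifelse(is.na(s), NA_real_, 0)
  } else {
    round_half_away((s - r[1]) / (r[2] - r[1]) * 255)
  }
  storage.mode(img) <- "integer"
  structure(list(image = img), class = "summation_image")
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Threshold the flush-out summation image into the core-region map
#'
#' Pixels whose 0..255 value is at least `thresh` are foreground; 8-connected
#' components smaller than `min_area` are removed. An empty mask is a valid
#' "no pollution in this phase" outcome.
#'
#' @param img a `summation_image`.
#' @param thresh integer threshold in 0..255 (compared with `>=`).
#' @param min_area minimum component size in pixels.
#' @return logical core-region mask.
#' @export
threshold_flushout <- function(img, thresh = 200L, min_area = 8L) {
  if (!inherits(img, "summation_image"))
    stop("expected a `summation_image`")
  thresh <- as.integer(thresh)
  if (thresh < 0L || thresh > 255L) stop("`thresh` must be in 0..255")
  fg <- !is.na(img$image) & img$image >= thresh
  filter_small_components(fg, min_area)
}
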