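#' Fluorescence optical imaging stack
#'
#' Container for one spatio-temporal NIR-FOI acquisition: a 3-D array of
#' non-negative pixel counts plus acquisition metadata and a carried
#' exclusion mask. Pixels flagged in the exclusion mask are skipped by every
#' downstream statistic (means, variances, normalizations, threshold pools)
#' rather than entering them as sentinel values.
#'
#' @param counts numeric array of dimension `height x width x frames` with
#'   finite, non-negative entries; indexed `[y, x, t]`, origin top-left.
#' @param frame_interval_s seconds between consecutive frames (metadata only).
#' @param excluded optional logical `height x width` matrix of pixels to be
#'   skipped by all statistics; defaults to none.
#' @return An object of class `fo_stack` with elements `counts`, `excluded`
#'   and `frame_interval_s`.
#' @examples
#' s <- fo_stack(array(1, c(4, 5, 6)))
#' dim(s$counts)
#' @export
fo_stack <- function(counts, frame_interval_s = 1.0, excluded = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-D array (height x width x frames)")
  storage.mode(counts) <- "double"
  if (anyNA(counts) || !all(is.finite(counts)))
    stop("`counts` must be finite")
  if (any(counts < 0))
    stop("`counts` must be non-negative")
  d <- dim(counts)
  if (d[3] < 3L)
    stop("a stack needs at least 3 frames (one per phase)")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("`frame_interval_s` must be a positive scalar")
  if (is.null(excluded)) {
    excluded <- matrix(FALSE, d[1], d[2])
  } else {
    excluded <- as.matrix(excluded)
    if (!identical(dim(excluded), d[1:2]))
      stop("`excluded` must match the spatial dimensions of `counts`")
    storage.mode(excluded) <- "logical"
    if (anyNA(excluded)) stop("`excluded` must not contain NA")
  }
  structure(
    list(counts = counts, excluded = excluded,
         frame_interval_s = frame_interval_s),
    class = "fo_stack"
  )
}

#' @export
print.fo_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<fo_stack> %d x %d pixels, %d frames (%.3g s/frame), %d excluded pixel(s)\n",
    d[1], d[2], d[3], x$frame_interval_s, sum(x$excluded)))
  invisible(x)
}

#' @export
dim.fo_stack <- function(x) dim(x$counts)

n_frames <- function(stack) dim(stack$counts)[3]

stopifnot_stack <- function(stack) {
  if (!inherits(stack, "fo_stack")) stop("expected an `fo_stack` object")
  invisible(stack)
}

#' Phase boundaries of an acquisition
#'
#' The two indices splitting the timeline into the no-colour-agent (NoCA),
#' illumination and flush-out phases. `ssp` (signal starting point) and
#' `tpfi` (time point of full illumination) are 0-based boundary indices with
#' half-open phase intervals: NoCA covers frames `[0, ssp)`, illumination
#' `[ssp, tpfi)` and flush-out `[tpfi, frame_count)`. Equivalently, `ssp` is
#' the number of NoCA frames and `tpfi - ssp` the number of illumination
#' frames.
#'
#' @param ssp 0-based index of the first illumination frame.
#' @param tpfi 0-based index of the first flush-out frame.
#' @param frame_count total frame count of the owning stack.
#' @return An object of class `phase_boundaries`.
#' @export
phase_boundaries <- function(ssp, tpfi, frame_count) {
  ssp <- as.integer(ssp); tpfi <- as.integer(tpfi)
  frame_count <- as.integer(frame_count)
  if (!(0L < ssp && ssp < tpfi && tpfi < frame_count))
    stop("phase boundaries must satisfy 0 < ssp < tpfi < frame_count")
  structure(list(ssp = ssp, tpfi = tpfi, frame_count = frame_count),
            class = "phase_boundaries")
}

#' @export
print.phase_boundaries <- function(x, ...) {
  cat(sprintf("<phase_boundaries> NoCA [0,%d) | illumination [%d,%d) | flush-out [%d,%d)\n",
              x$ssp, x$ssp, x$tpfi, x$tpfi, x$frame_count))
  invisible(x)
}

#' Detect the signal starting point and the time point of full illumination
#'
#' Splits a stack's timeline into the NoCA / illumination / flush-out phases
#' from its per-frame mean count curve. The curve (mean over admissible
#' pixels) is smoothed with a centred moving average; the signal starting
#' point (SSP) is the first frame whose smoothed mean exceeds the baseline
#' mean plus five baseline standard deviations -- both computed over the
#' first `baseline_frames` frames -- sustained for at least three consecutive
#' frames; the time point of full illumination (TPFI) is the global maximum
#' of the smoothed curve at or after the SSP. Both indices can be overridden
#' manually, bypassing detection entirely.
#'
#' The criterion is baseline-relative, so detection is invariant under a
#' global positive rescaling of the counts.
#'
#' @param stack an [fo_stack()].
#' @param baseline_frames number of leading frames treated as signal-free
#'   baseline; must be less than half the frame count.
#' @param smooth_window odd width of the centred moving average (frames).
#' @param ssp,tpfi optional manual overrides (0-based boundary indices);
#'   if both are given no detection is run.
#' @return A [phase_boundaries()] object.
#' @export
detect_phases <- function(stack, baseline_frames = 15L, smooth_window = 5L,
                          ssp = NULL, tpfi = NULL) {
  stopifnot_stack(stack)
  nt <- n_frames(stack)
  if (!is.null(ssp) && !is.null(tpfi))
    return(phase_boundaries(ssp, tpfi, nt))
  baseline_frames <- as.integer(baseline_frames)
  smooth_window <- as.integer(smooth_window)
  if (baseline_frames < 1L || baseline_frames >= nt / 2)
    stop("`baseline_frames` must be positive and below frame_count/2")
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("`smooth_window` must be a positive odd integer")

  curve <- frame_mean_curve(stack)
  sm <- centred_moving_average(curve, smooth_window)

  bl <- curve[seq_len(baseline_frames)]
  thresh <- mean(bl) + 5 * stats::sd(bl)

  above <- sm > thresh
  # sustained for >= 3 consecutive frames
  onset <- NA_integer_
  run <- 0L
  for (f in seq_len(nt)) {
    run <- if (above[f]) run + 1L else 0L
    if (run == 3L) { onset <- f - 2L; break }
  }
  if (is.na(onset))
    stop("no signal onset found")
  ssp0 <- onset - 1L                       # 0-based
  tpfi0 <- (onset - 1L) + which.max(sm[onset:nt]) - 1L
  if (!is.null(ssp)) ssp0 <- as.integer(ssp)
  if (!is.null(tpfi)) tpfi0 <- as.integer(tpfi)
  if (tpfi0 <= ssp0)
    stop("degenerate phase split (tpfi <= ssp)")
  if (ssp0 < 15L || ssp0 > 150L)
    warning(sprintf("NoCA phase length %d outside the typical 15-150 frame range",
                    ssp0))
  phase_boundaries(ssp0, tpfi0, nt)
}

# mean count per frame over admissible pixels
frame_mean_curve <- function(stack) {
  adm <- !stack$excluded
  if (!any(adm)) stop("no admissible pixels")
  d <- dim(stack$counts)
  m <- matrix(stack$counts, d[1] * d[2], d[3])
  colMeans(m[as.vector(adm), , drop = FALSE])
}

centred_moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(f)
    mean(x[max(1L, f - h):min(n, f + h)]), numeric(1))
}

#' Extract one phase of a stack
#'
#' Returns the sub-stack of the frames belonging to the requested phase;
#' spatial dimensions and the exclusion mask are unchanged. The three phase
#' sub-stacks partition the original stack exactly.
#'
#' @param stack an [fo_stack()].
#' @param phases a [phase_boundaries()] object.
#' @param which one of `"noca"`, `"illumination"`, `"flushout"`.
#' @return An `fo_stack` with the reduced frame span.
#' @export
extract_phase <- function(stack, phases,
                          which = c("noca", "illumination", "flushout")) {
  stopifnot_stack(stack)
  which <- match.arg(which)
  if (!inherits(phases, "phase_boundaries"))
    stop("`phases` must be a `phase_boundaries` object")
  nt <- n_frames(stack)
  if (phases$frame_count != nt)
    stop("phase boundaries refer to a different frame count")
  idx <- switch(which,
    noca = seq_len(phases$ssp),
    illumination = (phases$ssp + 1L):phases$tpfi,
    flushout = (phases$tpfi + 1L):nt)
  if (length(idx) == 0L) stop("empty phase span")
  sub <- stack$counts[, , idx, drop = FALSE]
  out <- fo_stack_unchecked(sub, stack$frame_interval_s, stack$excluded)
  out
}

# internal fast-path constructor for already-validated data
fo_stack_unchecked <- function(counts, frame_interval_s, excluded) {
  structure(list(counts = counts, excluded = excluded,
                 frame_interval_s = frame_interval_s),
            class = "fo_stack")
}

#' Exclude pixels from a stack
#'
#' Replaces every flagged pixel's timeline by zeros and records the flag in
#' the stack's carried exclusion mask, so that all downstream detectors skip
#' the pixel in their statistics. Applying the same mask twice equals
#' applying it once.
#'
#' @param stack an [fo_stack()].
#' @param mask logical `height x width` matrix; `TRUE` marks pixels to drop.
#' @return The stack with zeroed timelines and an updated exclusion mask.
#' @export
exclude_pixels <- function(stack, mask) {
  stopifnot_stack(stack)
  mask <- as.matrix(mask)
  d <- dim(stack$counts)
  if (!identical(dim(mask), d[1:2]))
    stop("exclusion mask shape does not match the stack")
  storage.mode(mask) <- "logical"
  counts <- stack$counts
  if (any(mask)) {
    flat <- matrix(counts, d[1] * d[2], d[3])
    flat[as.vector(mask), ] <- 0
    counts <- array(flat, d)
  }
  fo_stack_unchecked(counts, stack$frame_interval_s, stack$excluded | mask)
}

#' Timelines of selected pixels
#'
#' Extracts the full temporal sequence of each requested pixel as a row of a
#' matrix, in the order the coordinates are given.
#'
#' @param stack an [fo_stack()].
#' @param coords integer matrix with two columns `(y, x)`, 1-based.
#' @return numeric matrix, one row per coordinate, one column per frame.
#' @export
pixel_timelines <- function(stack, coords) {
  stopifnot_stack(stack)
  coords <- coord_matrix(coords)
  d <- dim(stack$counts)
  if (any(coords[, 1] < 1L | coords[, 1] > d[1] |
          coords[, 2] < 1L | coords[, 2] > d[2]))
    stop("coordinates out of bounds")
  flat <- matrix(stack$counts, d[1] * d[2], d[3])
  flat[coords[, 1] + (coords[, 2] - 1L) * d[1], , drop = FALSE]
}

coord_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coordinates must have two columns (y, x)")
  storage.mode(coords) <- "integer"
  coords
}
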