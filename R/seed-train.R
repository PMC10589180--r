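# Seed definition and training-data construction. Each connected foreground
# area of a core-region map becomes one Region with one seed (floor of the
# coordinate-wise centroid, snapped into the region if it falls outside) and
# one balanced two-class training set: Class1 = the whole-phase timelines of
# the region's pixels, Class0 = timelines sampled at random from outside a
# forbidden zone around ALL detected foreground areas, with a minimum
# spacing between picks for diversity.

#' Connected foreground areas of a core-region map
#'
#' @param mask logical core-region mask.
#' @param phase_tag `"noca"` or `"flushout"`, recorded on each region.
#' @return list of `pollution_region` objects in deterministic order by each
#'   component's (min row, min column); seeds not yet computed. Empty mask
#'   gives an empty list.
#' @export
label_regions <- function(mask, phase_tag = c("noca", "flushout")) {
  phase_tag <- match.arg(phase_tag)
  labels <- label_components(mask)
  k <- max(labels)
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    idx <- which(labels == i)
    h <- nrow(labels)
    pix <- cbind(y = ((idx - 1L) %% h) + 1L, x = ((idx - 1L) %/% h) + 1L)
    structure(list(pixels = pix, seed = NULL, phase_tag = phase_tag,
                   region_id = i, dim = dim(labels)),
              class = "pollution_region")
  })
}

#' @export
print.pollution_region <- function(x, ...) {
  cat(sprintf("<pollution_region> id %d (%s), %d pixel(s)%s\n",
              x$region_id, x$phase_tag, nrow(x$pixels),
              if (is.null(x$seed)) "" else
                sprintf(", seed (%d, %d)", x$seed[1], x$seed[2])))
  invisible(x)
}

#' Seed of a region
#'
#' The seed is the floor of the mean pixel index in each dimension. For a
#' non-convex region this point can land outside the region; it is then
#' snapped to the region pixel with minimal Euclidean distance, ties broken
#' by (row, column) order, so the grower always starts inside the region.
#'
#' @param region a `pollution_region`.
#' @return the region with its `seed` field set to an integer `(y, x)` pair.
#' @export
compute_seed <- function(region) {
  if (!inherits(region, "pollution_region"))
    stop("expected a `pollution_region`")
  pix <- region$pixels
  if (nrow(pix) == 0L) stop("region has no pixels")
  cand <- c(floor(mean(pix[, 1])), floor(mean(pix[, 2])))
  member <- pix[, 1] == cand[1] & pix[, 2] == cand[2]
  if (!any(member)) {
    d2 <- (pix[, 1] - cand[1])^2 + (pix[, 2] - cand[2])^2
    best <- order(d2, pix[, 1], pix[, 2])[1L]
    cand <- c(pix[best, 1], pix[best, 2])
  }
  region$seed <- as.integer(cand)
  region
}

#' Balanced two-class training set for one region
#'
#' Class1 holds the whole-phase timelines of all region pixels. Class0 holds
#' an equal number of timelines picked uniformly at random from outside the
#' forbidden zone -- the union of all detected foreground areas of the phase
#' map, each dilated by a square of radius `margin` -- rejecting any
#' candidate within Chebyshev distance `spacing` of an already accepted
#' Class0 pixel. Sampling is driven by `rng_seed` only and restores the
#' caller's RNG state, so the same call always yields the same coordinates.
#'
#' @param region a `pollution_region` (seed not required).
#' @param phase_stack the [fo_stack()] of the region's phase; timelines are
#'   taken from it unmodified.
#' @param phase_mask logical mask of all detected foreground areas of the
#'   same phase map (forbidden-zone base); defaults to the region's own
#'   pixels when `NULL`.
#' @param margin square dilation radius of the forbidden zone, pixels.
#' @param spacing minimum Chebyshev separation between Class0 picks, pixels.
#' @param rng_seed integer seed for the background sampling.
#' @return An object of class `training_set`: matrices `class1` / `class0`
#'   (one timeline per row), coordinate matrices `class1_coords` /
#'   `class0_coords`, the `forbidden_zone` mask, `rng_seed`, `phase_tag` and
#'   `region_id`.
#' @export
build_training_set <- function(region, phase_stack, phase_mask = NULL,
                               margin = 10L, spacing = 3L, rng_seed = 0L) {
  if (!inherits(region, "pollution_region"))
    stop("expected a `pollution_region`")
  stopifnot_stack(phase_stack)
  d <- dim(phase_stack$counts)
  if (is.null(phase_mask)) {
    phase_mask <- matrix(FALSE, d[1], d[2])
    phase_mask[region$pixels] <- TRUE
  }
  phase_mask <- as.matrix(phase_mask)
  if (!identical(dim(phase_mask), d[1:2]))
    stop("`phase_mask` shape does not match the stack")
  margin <- as.integer(margin); spacing <- as.integer(spacing)
  if (margin < 1L || spacing < 1L)
    stop("`margin` and `spacing` must be positive")

  forbidden <- dilate_square(phase_mask, margin)
  class1_coords <- region$pixels
  n1 <- nrow(class1_coords)
  candidates <- which(!as.vector(forbidden) & !as.vector(phase_stack$excluded))
  if (length(candidates) < n1)
    stop(sprintf("insufficient background pixels (achieved 0 of %d)", n1))

  picked <- matrix(0L, n1, 2)
  got <- 0L
  with_local_seed(rng_seed, {
    attempts <- 0L
    cap <- 100L * n1
    while (got < n1 && attempts < cap) {
      attempts <- attempts + 1L
      p <- candidates[sample.int(length(candidates), 1L)]
      py <- ((p - 1L) %% d[1]) + 1L
      px <- ((p - 1L) %/% d[1]) + 1L
      if (got > 0L) {
        cheb <- pmax(abs(picked[seq_len(got), 1L] - py),
                     abs(picked[seq_len(got), 2L] - px))
        if (any(cheb <= spacing)) next
      }
      got <- got + 1L
      picked[got, ] <- c(py, px)
    }
  })
  if (got < n1)
    stop(sprintf("insufficient background pixels (achieved %d of %d)", got, n1))

  structure(list(
    class1 = pixel_timelines(phase_stack, class1_coords),
    class0 = pixel_timelines(phase_stack, picked),
    class1_coords = class1_coords,
    class0_coords = picked,
    forbidden_zone = forbidden,
    rng_seed = as.integer(rng_seed),
    phase_tag = region$phase_tag,
    region_id = region$region_id
  ), class = "training_set")
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Export a training set as a tabular text file
#'
#' One row per sample: region id, class label, source row, source column,
#' then the timeline values. Tab-separated with a header.
#'
#' @param ts a `training_set`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_training_set <- function(ts, path) {
  if (!inherits(ts, "training_set")) stop("expected a `training_set`")
  tl <- rbind(ts$class1, ts$class0)
  df <- data.frame(
    region_id = ts$region_id,
    class = rep(c(1L, 0L), c(nrow(ts$class1), nrow(ts$class0))),
    y = c(ts$class1_coords[, 1], ts$class0_coords[, 1]),
    x = c(ts$class1_coords[, 2], ts$class0_coords[, 2])
  )
  colnames(tl) <- sprintf("t%03d", seq_len(ncol(tl)) - 1L)
  utils::write.table(cbind(df, tl), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
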