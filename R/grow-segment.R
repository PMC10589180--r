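# Seeded region growing with a learned inclusion criterion. Instead of a
# fixed intensity rule, each region's k-nearest-neighbour classifier --
# trained on that region's own timelines -- decides whether a frontier
# pixel's whole phase timeline belongs to the polluted area. Class1
# training pixels are accepted without classification; Class0 training
# pixels get no such shortcut and can be overrun when the classifier votes
# them in.

#' Train the per-region timeline classifier
#'
#' A k-nearest-neighbour classifier on raw timelines with Euclidean
#' distance. Majority vote among the `k` closest training samples decides
#' Class1 vs Class0; distance ties are broken by insertion order (all Class1
#' samples precede all Class0 samples), making the classifier fully
#' deterministic. If the training set is smaller than `k`, `k` is reduced to
#' the largest odd number not exceeding the Class1 count (minimum 1) with a
#' warning.
#'
#' @param ts a `training_set`.
#' @param k positive odd neighbour count (the pipeline default is 3).
#' @return An object of class `timeline_knn`.
#' @export
train_classifier <- function(ts, k = 3L) {
  if (!inherits(ts, "training_set")) stop("expected a `training_set`")
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("`k` must be a positive odd integer")
  n1 <- nrow(ts$class1)
  if (n1 + nrow(ts$class0) == 0L) stop("empty training set")
  if (n1 < k) {
    k_new <- max(1L, if (n1 %% 2L == 1L) n1 else n1 - 1L)
    warning(sprintf("k reduced from %d to %d (only %d Class1 samples)",
                    k, k_new, n1))
    k <- k_new
  }
  train <- rbind(ts$class1, ts$class0)
  structure(list(
    train = train,
    labels = rep(c(1L, 0L), c(n1, nrow(ts$class0))),
    k = k,
    sq_norms = rowSums(train^2),
    class1_coords = ts$class1_coords
  ), class = "timeline_knn")
}

#' Classify one timeline
#'
#' @param clf a `timeline_knn` classifier.
#' @param timeline numeric vector of the same length as the training
#'   timelines.
#' @return `1L` (Class1, polluted) or `0L` (Class0, background).
#' @export
classify_timeline <- function(clf, timeline) {
  if (!inherits(clf, "timeline_knn")) stop("expected a `timeline_knn`")
  if (length(timeline) != ncol(clf$train))
    stop("timeline length does not match the training data")
  d2 <- clf$sq_norms - 2 * drop(clf$train %*% timeline) + sum(timeline^2)
  ord <- order(d2, seq_along(d2))     # explicit insertion-order tie-break
  votes <- clf$labels[ord[seq_len(clf$k)]]
  as.integer(2L * sum(votes) > clf$k)
}

#' Grow one region from its seed
#'
#' Breadth-first frontier growth. The seed is accepted without
#' classification; each popped frontier pixel's eight neighbours are
#' enumerated in the fixed order N, NE, E, SE, S, SW, W, NW, and every
#' in-bounds, unvisited neighbour is either auto-accepted (if it is a Class1
#' training source), skipped (if it is an excluded pixel), or classified on
#' its whole phase timeline: Class1 pixels join the region and the frontier,
#' Class0 pixels are rejected and never revisited. Class0 training sources
#' receive no shortcut and are classified like any other pixel. Each pixel
#' is visited at most once, so growth always terminates, and for a
#' deterministic classifier the accepted set does not depend on the frontier
#' discipline.
#'
#' @param seed_region a `pollution_region` with its seed set (see
#'   [compute_seed()]).
#' @param classifier the region's `timeline_knn`.
#' @param ts the `training_set` the classifier was trained on (supplies the
#'   Class1 auto-accept coordinates).
#' @param phase_stack the [fo_stack()] of the region's phase.
#' @param frontier `"fifo"` (breadth-first, default) or `"lifo"`; exposed to
#'   let tests assert order-independence.
#' @return An object of class `region_growth`: logical matrices `accepted`,
#'   `tested` and `auto_accepted`, plus `region_id` and `phase_tag`.
#' @export
grow_region <- function(seed_region, classifier, ts, phase_stack,
                        frontier = c("fifo", "lifo")) {
  frontier <- match.arg(frontier)
  if (!inherits(seed_region, "pollution_region") || is.null(seed_region$seed))
    stop("expected a `pollution_region` with a computed seed")
  stopifnot_stack(phase_stack)
  d <- dim(phase_stack$counts)
  h <- d[1]; w <- d[2]
  seed <- seed_region$seed
  if (seed[1] < 1L || seed[1] > h || seed[2] < 1L || seed[2] > w)
    stop("seed out of bounds")
  if (phase_stack$excluded[seed[1], seed[2]])
    stop("seed excluded")

  flat <- matrix(phase_stack$counts, h * w, d[3])
  is_class1_src <- matrix(FALSE, h, w)
  is_class1_src[ts$class1_coords] <- TRUE

  accepted <- matrix(FALSE, h, w)
  tested <- matrix(FALSE, h, w)
  auto <- matrix(FALSE, h, w)
  visited <- matrix(FALSE, h, w)

  queue <- integer(h * w)
  sidx <- seed[1] + (seed[2] - 1L) * h
  queue[1L] <- sidx; head <- 1L; tail <- 1L
  visited[sidx] <- TRUE
  accepted[sidx] <- TRUE
  auto[sidx] <- TRUE                 # the seed is a Class1 pixel by construction

  while (head <= tail) {
    if (frontier == "fifo") {
      p <- queue[head]; head <- head + 1L
    } else {
      p <- queue[tail]; tail <- tail - 1L
    }
    y <- ((p - 1L) %% h) + 1L
    x <- ((p - 1L) %/% h) + 1L
    for (nb in 1:8) {
      ny <- y + NEIGHBOUR_OFFSETS[nb, 1L]
      nx <- x + NEIGHBOUR_OFFSETS[nb, 2L]
      if (ny < 1L || ny > h || nx < 1L || nx > w) next
      q <- ny + (nx - 1L) * h
      if (visited[q]) next
      visited[q] <- TRUE
      if (is_class1_src[q]) {
        accepted[q] <- TRUE
        auto[q] <- TRUE
      } else if (phase_stack$excluded[q]) {
        next                          # excluded pixels behave as out-of-bounds
      } else {
        tested[q] <- TRUE
        if (classify_timeline(classifier, flat[q, ]) == 0L) next
        accepted[q] <- TRUE
      }
      if (frontier == "lifo" && tail + 1L > length(queue)) {
        # LIFO pops from the tail, so compact the consumed head space first
        queue <- queue[head:tail]; tail <- tail - head + 1L; head <- 1L
        length(queue) <- h * w
      }
      tail <- tail + 1L
      queue[tail] <- q
    }
  }
  structure(list(accepted = accepted, tested = tested, auto_accepted = auto,
                 region_id = seed_region$region_id,
                 phase_tag = seed_region$phase_tag),
            class = "region_growth")
}

#' Merge grown regions into the final pollution map
#'
#' The final two-dimensional pollution map is the union of every growth's
#' accepted pixels with the NoCA core map (whose pixels were already
#' excluded upstream and therefore cannot be re-grown).
#'
#' @param growths list of `region_growth` objects (possibly empty).
#' @param noca_core logical NoCA core-region mask, or `NULL`.
#' @param dim integer `(height, width)`, required when both inputs are empty.
#' @return An object of class `pollution_map`: logical `grid` plus a
#'   `contributing_regions` data frame (`region_id`, `phase_tag`, `pixels`).
#' @export
assemble_pollution_map <- function(growths, noca_core = NULL, dim = NULL) {
  shape <- if (!is.null(noca_core)) dim(noca_core)
           else if (length(growths) > 0L) dim(growths[[1]]$accepted)
           else dim
  if (is.null(shape)) stop("cannot infer the map shape")
  grid <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(noca_core)) {
    if (!identical(dim(noca_core), shape)) stop("core mask shape mismatch")
    grid <- grid | noca_core
  }
  regs <- data.frame(region_id = integer(), phase_tag = character(),
                     pixels = integer())
  for (g in growths) {
    if (!identical(dim(g$accepted), shape)) stop("growth shape mismatch")
    grid <- grid | g$accepted
    regs <- rbind(regs, data.frame(region_id = g$region_id,
                                   phase_tag = g$phase_tag,
                                   pixels = sum(g$accepted)))
  }
  structure(list(grid = grid, contributing_regions = regs),
            class = "pollution_map")
}

#' @export
print.pollution_map <- function(x, ...) {
  cat(sprintf("<pollution_map> %d x %d, %d polluted pixel(s), %d region(s)\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid),
              nrow(x$contributing_regions)))
  invisible(x)
}
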