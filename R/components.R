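# Binary-mask utilities: 8-connected component labeling and square dilation.
# The whole pipeline uses 8-connectivity (a diagonal touch joins components).

NEIGHBOUR_OFFSETS <- cbind(
  dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)  # N, NE, E, SE, S, SW, W, NW -- fixed enumeration order used everywhere

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered 1..K in deterministic order by their (min row, min column).
#' @export
label_components <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (!any(mask)) return(labels)
  queue <- integer(sum(mask))
  lab <- 0L
  fg <- which(mask)  # column-major order
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      y <- ((p - 1L) %% h) + 1L
      x <- ((p - 1L) %/% h) + 1L
      for (k in 1:8) {
        ny <- y + NEIGHBOUR_OFFSETS[k, 1L]
        nx <- x + NEIGHBOUR_OFFSETS[k, 2L]
        if (ny < 1L || ny > h || nx < 1L || nx > w) next
        q <- ny + (nx - 1L) * h
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- lab
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  relabel_by_position(labels, lab)
}

# renumber labels by (min y, min x) of each component
relabel_by_position <- function(labels, k) {
  if (k <= 1L) return(labels)
  h <- nrow(labels)
  idx <- which(labels > 0L)
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  lab <- labels[idx]
  miny <- tapply(ys, lab, min)
  minx <- tapply(xs, lab, min)
  ord <- order(miny, minx)
  remap <- integer(k)
  remap[as.integer(names(miny))[ord]] <- seq_len(k)
  labels[idx] <- remap[lab]
  labels
}

#' Remove small connected components
#'
#' @param mask logical matrix.
#' @param min_area components with fewer pixels are dropped.
#' @return logical matrix.
#' @export
filter_small_components <- function(mask, min_area) {
  if (min_area <= 1L) return(mask & !is.na(mask))
  labels <- label_components(mask)
  if (max(labels) == 0L) return(labels > 0L)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_area)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Dilate a binary mask with a square structuring element
#'
#' Separable max-filter: each `TRUE` pixel spreads to the
#' `(2*radius+1) x (2*radius+1)` square centred on it.
#'
#' @param mask logical matrix.
#' @param radius non-negative integer radius of the square.
#' @return logical matrix.
#' @export
dilate_square <- function(mask, radius) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  radius <- as.integer(radius)
  if (radius < 0L) stop("`radius` must be non-negative")
  if (radius == 0L || !any(mask)) return(mask)
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (s in seq_len(radius)) {             # vertical pass
    out[seq_len(h - s), ] <- out[seq_len(h - s), ] | mask[(s + 1L):h, ]
    out[(s + 1L):h, ] <- out[(s + 1L):h, ] | mask[seq_len(h - s), ]
  }
  tmp <- out
  for (s in seq_len(radius)) {             # horizontal pass
    out[, seq_len(w - s)] <- out[, seq_len(w - s)] | tmp[, (s + 1L):w]
    out[, (s + 1L):w] <- out[, (s + 1L):w] | tmp[, seq_len(w - s)]
  }
  out
}
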