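# Synthetic NIR-FOI stack generator. Emulates the three temporal phases of
# a dye acquisition -- noise-only baseline, linear illumination rise to the
# peak, exponential flush-out decay -- on top of a bright, smooth-edged,
# hand-like elliptical object, plus configurable ambient-light pollution
# phenotypes ranging from a static brightness offset to a fluctuating
# signal. Every stack comes with pixel-exact ground truth, so all pipeline
# stages are testable without any clinical data.

#' Pollution phenotype specification
#'
#' @param kind `"static"` (constant offset for the whole acquisition),
#'   `"fluctuating"` (sinusoidal `amplitude * (1 + sin(2*pi*t/period + phi))/2`
#'   with a random phase `phi` drawn once per phenotype), or
#'   `"onset_fluctuating"` (static offset before `onset_frame`, fluctuating
#'   after -- a light switched or starting to flicker mid-acquisition).
#' @param shape `"rect"` or `"ellipse"`.
#' @param y,x top-left corner (rect) or centre (ellipse), 1-based pixels.
#' @param height,width rectangle extent in pixels.
#' @param ry,rx ellipse radii in pixels.
#' @param amplitude positive peak offset in counts.
#' @param period fluctuation period in frames.
#' @param onset_frame 0-based frame at which an `onset_fluctuating`
#'   phenotype starts to fluctuate.
#' @return An object of class `pollution_spec`.
#' @export
pollution_spec <- function(kind = c("static", "fluctuating", "onset_fluctuating"),
                           shape = c("rect", "ellipse"), y, x,
                           height = NULL, width = NULL, ry = NULL, rx = NULL,
                           amplitude = 60, period = 12, onset_frame = 60L) {
  kind <- match.arg(kind); shape <- match.arg(shape)
  if (amplitude <= 0) stop("`amplitude` must be positive")
  if (shape == "rect" && (is.null(height) || is.null(width)))
    stop("rectangles need `height` and `width`")
  if (shape == "ellipse" && (is.null(ry) || is.null(rx)))
    stop("ellipses need `ry` and `rx`")
  structure(list(kind = kind, shape = shape, y = y, x = x,
                 height = height, width = width, ry = ry, rx = rx,
                 amplitude = amplitude, period = period,
                 onset_frame = as.integer(onset_frame)),
            class = "pollution_spec")
}

spec_mask <- function(spec, h, w) {
  m <- matrix(FALSE, h, w)
  if (spec$shape == "rect") {
    ys <- spec$y:(spec$y + spec$height - 1L)
    xs <- spec$x:(spec$x + spec$width - 1L)
    if (min(ys) < 1L || max(ys) > h || min(xs) < 1L || max(xs) > w)
      stop("phenotype shape out of image bounds")
    m[ys, xs] <- TRUE
  } else {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- ((yy - spec$y) / spec$ry)^2 + ((xx - spec$x) / spec$rx)^2 <= 1
    if (any(m[1, ]) || any(m[h, ]) || any(m[, 1]) || any(m[, w])) {
      if (spec$y - spec$ry < 1 || spec$y + spec$ry > h ||
          spec$x - spec$rx < 1 || spec$x + spec$rx > w)
        stop("phenotype shape out of image bounds")
    }
    if (!any(m)) stop("phenotype ellipse covers no pixel")
  }
  m
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the synthetic acceptance suite
#' runs under: 64 x 64 pixels, 120 frames, NoCA phase of 20 frames, peak at
#' frame 50, dark-noise sigma 5 counts on a 100-count baseline, hand peak
#' 500 counts with an exponential flush-out of 0.02 per frame.
#'
#' @param height,width,frame_count stack geometry.
#' @param ssp,tpfi true phase boundaries (0-based, half-open convention of
#'   [phase_boundaries()]).
#' @param noise_sigma additive Gaussian noise scale, counts.
#' @param baseline_level constant detector offset, counts.
#' @param hand_peak hand amplitude at full illumination, counts.
#' @param decay_rate flush-out exponential constant, per frame.
#' @param rng_seed integer seed; fixes the stack bit-exactly.
#' @param phenotypes list of [pollution_spec()] objects (pairwise disjoint).
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(height = 64L, width = 64L, frame_count = 120L,
                       ssp = 20L, tpfi = 50L, noise_sigma = 5,
                       baseline_level = 100, hand_peak = 500,
                       decay_rate = 0.02, rng_seed = 0L,
                       phenotypes = list(),
                       noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  if (!(0L < ssp && ssp < tpfi && tpfi < frame_count))
    stop("need 0 < ssp < tpfi < frame_count")
  if (noise_sigma <= 0) stop("`noise_sigma` must be positive")
  structure(list(height = as.integer(height), width = as.integer(width),
                 frame_count = as.integer(frame_count),
                 ssp = as.integer(ssp), tpfi = as.integer(tpfi),
                 noise_sigma = noise_sigma, baseline_level = baseline_level,
                 hand_peak = hand_peak, decay_rate = decay_rate,
                 rng_seed = as.integer(rng_seed), phenotypes = phenotypes,
                 noise = noise),
            class = "sim_config")
}

# smooth-edged elliptical hand profile in [0, 1]; deliberately low spatial
# frequency so the flush-out high-pass can suppress it
hand_profile <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- 0.32 * h; b <- 0.22 * w
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  rho2 <- ((yy - cy) / a)^2 + ((xx - cx) / b)^2
  exp(-rho2^2)
}

# hand temporal amplitude per frame (0-based frame index tf)
hand_amplitude <- function(cfg) {
  tf <- seq_len(cfg$frame_count) - 1L
  amp <- numeric(cfg$frame_count)
  rise <- tf >= cfg$ssp & tf <= cfg$tpfi
  amp[rise] <- cfg$hand_peak * (tf[rise] - cfg$ssp + 1) / (cfg$tpfi - cfg$ssp + 1)
  post <- tf > cfg$tpfi
  amp[post] <- cfg$hand_peak * exp(-cfg$decay_rate * (tf[post] - cfg$tpfi))
  amp
}

#' Simulate one NIR-FOI stack with ground truth
#'
#' Counts are `baseline + hand + pollution + noise`, clipped at zero. The
#' hand is a smooth elliptical object at the image centre, zero before the
#' signal starting point, rising linearly to its peak at the time point of
#' full illumination and decaying exponentially afterwards. Pollution is
#' added per phenotype (see [pollution_spec()]); phenotype shapes must be
#' pairwise disjoint so region-level truth is unambiguous. The output is
#' bit-identical for a fixed `rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `stack` (an [fo_stack()]) and `truth` (list: logical
#'   `mask`, list of `pollution_region`s `regions`, logical `polluted`,
#'   `phases` the true [phase_boundaries()]).
#' @export
simulate_stack <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("expected a `sim_config`")
  h <- cfg$height; w <- cfg$width; nt <- cfg$frame_count

  masks <- lapply(cfg$phenotypes, spec_mask, h = h, w = w)
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1L])
      for (j in seq_len(i - 1L))
        if (any(masks[[i]] & masks[[j]]))
          stop("phenotypes must be disjoint")
  }

  tf <- seq_len(nt) - 1L
  hand <- outer(as.vector(hand_profile(h, w)), hand_amplitude(cfg))  # (h*w) x t

  signal <- matrix(cfg$baseline_level, h * w, nt) + hand
  with_local_seed(cfg$rng_seed, {
    for (i in seq_along(cfg$phenotypes)) {
      spec <- cfg$phenotypes[[i]]
      phi <- stats::runif(1, 0, 2 * pi)    # drawn even for static phenotypes,
                                           # keeping the noise stream aligned
      tl <- switch(spec$kind,
        static = rep(spec$amplitude, nt),
        fluctuating = spec$amplitude * (1 + sin(2 * pi * tf / spec$period + phi)) / 2,
        onset_fluctuating = {
          v <- rep(spec$amplitude, nt)
          late <- tf >= spec$onset_frame
          v[late] <- spec$amplitude *
            (1 + sin(2 * pi * tf[late] / spec$period + phi)) / 2
          v
        })
      idx <- which(as.vector(masks[[i]]))
      signal[idx, ] <- signal[idx, ] + rep(tl, each = length(idx))
    }
    counts <- if (cfg$noise == "gaussian") {
      signal + stats::rnorm(length(signal), 0, cfg$noise_sigma)
    } else {
      matrix(stats::rpois(length(signal), lambda = pmax(signal, 0)), nrow(signal))
    }
  })
  counts <- pmax(counts, 0)

  truth_mask <- Reduce(`|`, masks, matrix(FALSE, h, w))
  regions <- lapply(seq_along(masks), function(i) {
    idx <- which(masks[[i]])
    structure(list(
      pixels = cbind(y = ((idx - 1L) %% h) + 1L, x = ((idx - 1L) %/% h) + 1L),
      seed = NULL, phase_tag = "noca", region_id = i, dim = c(h, w)),
      class = "pollution_region")
  })
  list(
    stack = fo_stack(array(counts, c(h, w, nt))),
    truth = list(mask = truth_mask, regions = regions,
                 polluted = length(masks) > 0L,
                 phases = phase_boundaries(cfg$ssp, cfg$tpfi, nt))
  )
}

# deterministic anchor points near the image border, away from the central
# hand (windows and doors sit at the room edges)
suite_anchors <- function() {
  list(c(6L, 5L), c(50L, 55L), c(5L, 53L), c(54L, 6L), c(30L, 3L), c(3L, 30L))
}

#' The fixed synthetic acceptance suite
#'
#' A battery of 40 configurations at 64 x 64 x 120 (ssp 20, tpfi 50):
#' 10 pollution-free stacks, 10 with one static phenotype, 10 with one
#' fluctuating phenotype, 5 with one onset-fluctuating phenotype and 5 with
#' 2-3 disjoint phenotypes. Seeds and placements are fixed, so the suite is
#' fully reproducible.
#'
#' @return list of [sim_config()] objects with a `suite_group` attribute on
#'   each element (`"clean"`, `"static"`, `"fluctuating"`, `"onset"`,
#'   `"multi"`).
#' @export
default_suite <- function() {
  anchors <- suite_anchors()
  static_at <- function(a, amp = 60)
    pollution_spec("static", "rect", y = a[1], x = a[2],
                   height = 5L, width = 5L, amplitude = amp)
  fluct_at <- function(a, amp = 80)
    pollution_spec("fluctuating", "ellipse", y = a[1] + 2L, x = a[2] + 2L,
                   ry = 3.2, rx = 3.2, amplitude = amp, period = 12)
  onset_at <- function(a)
    pollution_spec("onset_fluctuating", "rect", y = a[1], x = a[2],
                   height = 5L, width = 6L, amplitude = 70, period = 10,
                   onset_frame = 60L)

  cfgs <- list()
  add <- function(group, seed, phen) {
    cfg <- sim_config(rng_seed = seed, phenotypes = phen)
    attr(cfg, "suite_group") <- group
    cfgs[[length(cfgs) + 1L]] <<- cfg
  }
  for (s in 0:9) add("clean", s, list())
  for (s in 10:19) add("static", s, list(static_at(anchors[[s %% 6L + 1L]])))
  for (s in 20:29) add("fluctuating", s, list(fluct_at(anchors[[s %% 6L + 1L]])))
  for (s in 30:34) add("onset", s, list(onset_at(anchors[[s %% 6L + 1L]])))
  for (s in 35:39) {
    picks <- ((s - 35L) + c(0L, 2L, 4L)) %% 6L + 1L
    phen <- list(static_at(anchors[[picks[1]]]),
                 fluct_at(anchors[[picks[2]]]))
    if (s %% 2L == 1L) phen <- c(phen, list(onset_at(anchors[[picks[3]]])))
    add("multi", s, phen)
  }
  cfgs
}
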