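# Independent brute-force oracles and small fixture builders. The oracles
# transcribe each definition literally and share no code with the package
# implementation.

# naive O(L^2) DFT magnitudes of one timeline, first ceiling(L/2) components
oracle_dft_magnitudes <- function(x) {
  L <- length(x)
  m <- ceiling(L / 2)
  vapply(0:(m - 1L), function(j) {
    re <- sum(x * cos(-2 * pi * j * (0:(L - 1L)) / L))
    im <- sum(x * sin(-2 * pi * j * (0:(L - 1L)) / L))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# literal per-component z-score + component sum on a pixel x component table
oracle_score_table <- function(tab) {
  n <- nrow(tab)
  z <- tab
  for (j in seq_len(ncol(tab))) {
    mu <- sum(tab[, j]) / n
    sigma <- sqrt(sum((tab[, j] - mu)^2) / n)   # population sd
    z[, j] <- if (sigma == 0) 0 else (tab[, j] - mu) / sigma
  }
  apply(z, 1, sum)
}

# full NoCA scoring from a raw stack array, straight from the definitions
oracle_noca_scores <- function(counts) {
  d <- dim(counts)
  n <- d[1] * d[2]
  tab <- t(apply(matrix(counts, n, d[3]), 1, oracle_dft_magnitudes))
  matrix(oracle_score_table(tab), d[1], d[2])
}

# interval-wise temporal sd maps with min-max normalization, literal loops
oracle_interval_maps <- function(arr, interval_len) {
  d <- dim(arr)
  starts <- seq(1, d[3], by = interval_len)
  ends <- pmin(starts + interval_len - 1, d[3])
  k <- length(starts)
  if (k > 1 && ends[k] - starts[k] + 1 < 2) {
    ends[k - 1] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  lapply(seq_along(starts), function(i) {
    s <- matrix(0, d[1], d[2])
    for (y in seq_len(d[1])) for (x in seq_len(d[2]))
      s[y, x] <- stats::sd(arr[y, x, starts[i]:ends[i]])
    rng <- range(s)
    if (rng[2] == rng[1]) s * 0 else (s - rng[1]) / (rng[2] - rng[1])
  })
}

# brute-force kNN vote with insertion-order tie-break (class1 rows first)
oracle_knn <- function(train, labels, k, query) {
  d2 <- rowSums(sweep(train, 2, query)^2)
  ord <- order(d2, seq_along(d2))
  as.integer(2 * sum(labels[ord[seq_len(k)]]) > k)
}

# small noise stack with an optional static offset region
make_noise_stack <- function(h = 16, w = 16, L = 20, sigma = 2, seed = 1,
                             offset = 0, region = NULL) {
  set.seed(seed)
  counts <- array(abs(rnorm(h * w * L, 50, sigma)), c(h, w, L))
  if (!is.null(region) && offset != 0)
    counts[region$y, region$x, ] <- counts[region$y, region$x, ] + offset
  fo_stack(counts)
}

# deterministic three-phase mean-curve stack (no noise)
make_ramp_stack <- function(h = 4, w = 4, nt = 200, ssp = 50, tpfi = 120,
                            peak = 100) {
  amp <- numeric(nt)
  tf <- 0:(nt - 1)
  rise <- tf >= ssp & tf <= tpfi
  amp[rise] <- peak * (tf[rise] - ssp + 1) / (tpfi - ssp + 1)
  amp[tf > tpfi] <- peak * exp(-0.03 * (tf[tf > tpfi] - tpfi))
  counts <- array(rep(amp, each = h * w), c(h, w, nt))
  fo_stack(counts)
}

# mask from (y, x) coordinate rows
mask_from_coords <- function(coords, h, w) {
  m <- matrix(FALSE, h, w)
  m[as.matrix(coords)] <- TRUE
  m
}

# training set built directly from explicit timelines (bypasses sampling)
manual_training_set <- function(class1, class0, class1_coords, class0_coords,
                                phase_tag = "noca", region_id = 1L) {
  structure(list(class1 = class1, class0 = class0,
                 class1_coords = as.matrix(class1_coords),
                 class0_coords = as.matrix(class0_coords),
                 forbidden_zone = NULL, rng_seed = 0L,
                 phase_tag = phase_tag, region_id = region_id),
            class = "training_set")
}

# region object from explicit pixels
manual_region <- function(coords, dim, phase_tag = "noca", region_id = 1L) {
  structure(list(pixels = as.matrix(coords), seed = NULL,
                 phase_tag = phase_tag, region_id = region_id, dim = dim),
            class = "pollution_region")
}
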