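# Degenerate accept-all / reject-all classifiers are emulated through
# constructed training sets whose geometry forces the vote.

test_that("the classifier follows zero-distance dominance and tie-break order", {
  class1 <- rbind(c(0, 0, 0), c(10, 10, 10))
  class0 <- rbind(c(100, 100, 100), c(200, 200, 200))
  ts <- manual_training_set(class1, class0, rbind(c(1, 1), c(1, 2)),
                            rbind(c(5, 5), c(6, 6)))
  clf <- train_classifier(ts, k = 1)
  expect_equal(classify_timeline(clf, c(0, 0, 0)), 1L)
  expect_equal(classify_timeline(clf, c(150, 150, 150)), 0L)
  # equidistant between one class1 and one class0 sample: class1 wins (order)
  tie <- manual_training_set(rbind(c(0, 0)), rbind(c(10, 10)),
                             rbind(c(1, 1)), rbind(c(5, 5)))
  expect_equal(classify_timeline(train_classifier(tie, 1), c(5, 5)), 1L)
})

test_that("k is reduced to the largest odd value within the class1 count", {
  ts <- manual_training_set(rbind(c(0, 0), c(1, 1)), rbind(c(9, 9), c(8, 8)),
                            rbind(c(1, 1), c(1, 2)), rbind(c(5, 5), c(6, 6)))
  expect_warning(clf <- train_classifier(ts, k = 3), "reduced")
  expect_equal(clf$k, 1L)
  expect_error(train_classifier(
    manual_training_set(matrix(0, 0, 2), matrix(0, 0, 2),
                        matrix(0L, 0, 2), matrix(0L, 0, 2)), 1),
    "empty training set")
})

test_that("classifier labels match a brute-force all-pairs kNN oracle", {
  set.seed(71)
  train1 <- matrix(rnorm(10 * 8), 10, 8)
  train0 <- matrix(rnorm(10 * 8, 2), 10, 8)
  ts <- manual_training_set(train1, train0,
                            cbind(1:10, 1), cbind(1:10, 5))
  clf <- train_classifier(ts, k = 3)
  train <- rbind(train1, train0)
  labels <- rep(c(1L, 0L), each = 10)
  for (q in 1:50) {
    query <- rnorm(8, 1)
    expect_equal(classify_timeline(clf, query),
                 oracle_knn(train, labels, 3, query))
  }
})

test_that("classifier agrees with class::knn away from distance ties", {
  skip_if_not_installed("class")
  set.seed(73)
  train1 <- matrix(rnorm(8 * 6), 8, 6)
  train0 <- matrix(rnorm(8 * 6, 3), 8, 6)
  ts <- manual_training_set(train1, train0, cbind(1:8, 1), cbind(1:8, 3))
  clf <- train_classifier(ts, k = 3)
  queries <- matrix(rnorm(40 * 6, 1.5), 40, 6)
  got <- apply(queries, 1, classify_timeline, clf = clf)
  want <- as.integer(as.character(class::knn(
    rbind(train1, train0), queries, factor(rep(c(1, 0), each = 8)), k = 3)))
  expect_equal(got, want)
})

test_that("a reject-all classifier yields the singleton seed", {
  st <- make_noise_stack(h = 8, w = 8, L = 6, seed = 79)
  # class1 timeline far away from every image pixel -> nothing else accepted
  far <- matrix(1e6, 1, 6)
  ts <- manual_training_set(far, pixel_timelines(st, rbind(c(1, 1))) ,
                            rbind(c(4, 4)), rbind(c(1, 1)))
  reg <- compute_seed(manual_region(rbind(c(4, 4)), c(8L, 8L)))
  g <- grow_region(reg, train_classifier(ts, 1), ts, st)
  expect_equal(sum(g$accepted), 1)
  expect_true(g$accepted[4, 4])
  expect_true(g$auto_accepted[4, 4])
})

test_that("an accept-all classifier floods the image, visiting each pixel once", {
  st <- fo_stack(array(5, c(7, 9, 4)))
  # every pixel's timeline equals the class1 sample -> always accepted
  ts <- manual_training_set(matrix(5, 1, 4), matrix(1e6, 1, 4),
                            rbind(c(3, 3)), rbind(c(1, 1)))
  reg <- compute_seed(manual_region(rbind(c(3, 3)), c(7L, 9L)))
  g <- grow_region(reg, train_classifier(ts, 1), ts, st)
  expect_equal(sum(g$accepted), 7 * 9)
  # every non-source pixel was classified exactly once
  expect_equal(sum(g$tested) + sum(g$auto_accepted), 7 * 9)
})

test_that("growth is independent of the frontier discipline", {
  for (seed in c(83, 89, 97)) {
    cfg <- sim_config(height = 32, width = 32, frame_count = 40, ssp = 10,
                      tpfi = 20, rng_seed = seed, phenotypes = list(
        pollution_spec("static", "rect", y = 4, x = 22, height = 6, width = 6,
                       amplitude = 60)))
    sim <- simulate_stack(cfg)
    noca <- extract_phase(sim$stack, sim$truth$phases, "noca")
    reg <- compute_seed(manual_region(as.matrix(expand.grid(y = 5:8, x = 23:26)),
                                      c(32L, 32L)))
    m <- mask_from_coords(reg$pixels, 32, 32)
    ts <- build_training_set(reg, noca, phase_mask = m, margin = 4,
                             spacing = 2, rng_seed = seed)
    clf <- train_classifier(ts, 3)
    fifo <- grow_region(reg, clf, ts, noca, frontier = "fifo")
    lifo <- grow_region(reg, clf, ts, noca, frontier = "lifo")
    expect_identical(fifo$accepted, lifo$accepted)
  }
})

test_that("growth recovers a planted block from a partial core (Dice >= 0.9)", {
  for (seed in 0:9) {
    cfg <- sim_config(rng_seed = seed, phenotypes = list(
      pollution_spec("static", "rect", y = 6, x = 50, height = 8, width = 8,
                     amplitude = 60)))
    sim <- simulate_stack(cfg)
    noca <- extract_phase(sim$stack, sim$truth$phases, "noca")
    core <- as.matrix(expand.grid(y = 8:11, x = 52:55))      # interior 4x4
    reg <- compute_seed(manual_region(core, c(64L, 64L)))
    m <- mask_from_coords(core, 64, 64)
    ts <- build_training_set(reg, noca, phase_mask = m, margin = 10,
                             spacing = 3, rng_seed = seed)
    g <- grow_region(reg, train_classifier(ts, 3), ts, noca)
    expect_gte(dice_masks(g$accepted, sim$truth$mask), 0.9)
  }
})

test_that("growth can escape the forbidden zone and overrun Class0 sources", {
  # pollution block bigger than the forbidden margin suggests; one Class0
  # sample was (wrongly) drawn from a pixel whose timeline matches class1
  st <- fo_stack(array(10, c(12, 12, 5)))
  blk <- as.matrix(expand.grid(y = 3:9, x = 3:9))
  st$counts[3:9, 3:9, ] <- 200
  core <- as.matrix(expand.grid(y = 5:6, x = 5:6))
  class0_coords <- rbind(c(8, 8), c(1, 1), c(12, 12), c(1, 12))
  ts <- manual_training_set(pixel_timelines(st, core),
                            pixel_timelines(st, class0_coords),
                            core, class0_coords)
  reg <- compute_seed(manual_region(core, c(12L, 12L)))
  g <- grow_region(reg, train_classifier(ts, 3), ts, st)
  expect_true(g$accepted[8, 8])     # Class0 source pixel overrun
  expect_true(g$tested[8, 8])       # ... after a real classification
  expect_equal(sum(g$accepted), nrow(blk))
})

test_that("excluded pixels block growth and excluded seeds error", {
  st <- fo_stack(array(5, c(6, 6, 4)))
  mask <- matrix(FALSE, 6, 6); mask[, 4] <- TRUE     # excluded wall
  ex <- exclude_pixels(st, mask)
  ts <- manual_training_set(matrix(5, 1, 4), matrix(1e6, 1, 4),
                            rbind(c(3, 2)), rbind(c(1, 1)))
  reg <- compute_seed(manual_region(rbind(c(3, 2)), c(6L, 6L)))
  g <- grow_region(reg, train_classifier(ts, 1), ts, ex)
  expect_false(any(g$accepted[, 4:6]))   # wall blocks the flood
  expect_true(all(g$accepted[, 1:3]))
  seed_reg <- compute_seed(manual_region(rbind(c(3, 4)), c(6L, 6L)))
  expect_error(grow_region(seed_reg, train_classifier(ts, 1), ts, ex),
               "seed excluded")
})

test_that("pollution maps are unions with provenance and shape checks", {
  g1 <- structure(list(accepted = mask_from_coords(rbind(c(1, 1), c(1, 2)), 4, 4),
                       tested = matrix(FALSE, 4, 4),
                       auto_accepted = matrix(FALSE, 4, 4),
                       region_id = 1L, phase_tag = "noca"),
                  class = "region_growth")
  g2 <- g1; g2$accepted <- mask_from_coords(rbind(c(1, 2), c(3, 3)), 4, 4)
  g2$region_id <- 2L; g2$phase_tag <- "flushout"
  core <- mask_from_coords(rbind(c(4, 4)), 4, 4)
  pm <- assemble_pollution_map(list(g1, g2), core)
  expect_equal(sum(pm$grid), 4)            # overlap not double-counted
  expect_equal(pm$contributing_regions$phase_tag, c("noca", "flushout"))
  empty <- assemble_pollution_map(list(), NULL, dim = c(4L, 4L))
  expect_equal(sum(empty$grid), 0)
  bad <- g2; bad$accepted <- matrix(FALSE, 5, 5)
  expect_error(assemble_pollution_map(list(g1, bad), core), "shape")
})
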