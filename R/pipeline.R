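# End-to-end pipeline: phase detection -> NoCA detector -> exclusion of the
# NoCA core -> flush-out detector -> per-region seeds, training sets and
# kNN-gated growing -> merged 2-D pollution map plus a reproducible run
# report. Training data and growing for NoCA regions use the pre-exclusion
# stack (the exclusion would otherwise zero the very timelines that form
# their Class1 training data); the flush-out detector and flush-out growing
# see the stack with the NoCA core removed.

#' Pipeline configuration
#'
#' All tunables of the pipeline with their defaults. Unknown names are
#' rejected.
#'
#' @param baseline_frames,smooth_window phase detection, see
#'   [detect_phases()].
#' @param z_thresh,z_mult,noca_min_area NoCA thresholding, see
#'   [threshold_noca()].
#' @param cutoff_sigma flush-out high-pass width (`NULL` = `min(h, w)/16`).
#' @param interval_len flush-out interval length in frames.
#' @param flushout_thresh,flushout_min_area flush-out thresholding, see
#'   [threshold_flushout()].
#' @param margin,spacing training-data construction, see
#'   [build_training_set()].
#' @param k neighbour count of the inclusion classifier.
#' @param rng_seed global seed; per-region sampling seeds are derived from
#'   it deterministically.
#' @param ssp,tpfi optional manual phase-boundary overrides.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(baseline_frames = 15L, smooth_window = 5L,
                            z_thresh = NULL, z_mult = 2.5, noca_min_area = 5L,
                            cutoff_sigma = NULL, interval_len = 30L,
                            flushout_thresh = 200L, flushout_min_area = 8L,
                            margin = 10L, spacing = 3L, k = 3L,
                            rng_seed = 0L, ssp = NULL, tpfi = NULL) {
  cfg <- list(baseline_frames = as.integer(baseline_frames),
              smooth_window = as.integer(smooth_window),
              z_thresh = z_thresh, z_mult = z_mult,
              noca_min_area = as.integer(noca_min_area),
              cutoff_sigma = cutoff_sigma,
              interval_len = as.integer(interval_len),
              flushout_thresh = as.integer(flushout_thresh),
              flushout_min_area = as.integer(flushout_min_area),
              margin = as.integer(margin), spacing = as.integer(spacing),
              k = as.integer(k), rng_seed = as.integer(rng_seed),
              ssp = if (is.null(ssp)) NULL else as.integer(ssp),
              tpfi = if (is.null(tpfi)) NULL else as.integer(tpfi))
  if (cfg$k < 1L || cfg$k %% 2L == 0L) stop("`k` must be a positive odd integer")
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a named list
#'
#' Used by the file-based configuration interface; unknown keys are an
#' error.
#'
#' @param values named list (e.g. parsed YAML or JSON).
#' @return a [pipeline_config()].
#' @export
as_pipeline_config <- function(values) {
  if (inherits(values, "pipeline_config")) return(values)
  values <- as.list(values)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(values), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, values)
}

# deterministic per-region sampling seed derived from the global seed
region_seed <- function(rng_seed, phase_tag, region_id) {
  (rng_seed + 100003L * (phase_tag == "flushout") + 541L * region_id) %% .Machine$integer.max
}

#' Run the full light-pollution segmentation pipeline on one stack
#'
#' Executes phase detection, the NoCA-phase frequency-domain detector, the
#' flush-out-phase temporal-variance detector (on the stack with the NoCA
#' core excluded), per-region seed/training-set construction and kNN-gated
#' region growing, and merges everything into one 2-D pollution map. If no
#' signal onset is found the analysis downgrades to treating the whole
#' stack as NoCA-like, with a warning.
#'
#' @param stack an [fo_stack()] or a path readable by [read_stack()].
#' @param config a [pipeline_config()].
#' @return list with `map` (a `pollution_map`) and `report` (a named list:
#'   phase boundaries, per-phase core pixel/region counts, per-region growth
#'   sizes and seeds, the polluted verdict, the configuration snapshot and
#'   the seed).
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot_stack(stack)
  config <- as_pipeline_config(config)
  d <- dim(stack$counts)

  phases <- tryCatch(
    detect_phases(stack, config$baseline_frames, config$smooth_window,
                  ssp = config$ssp, tpfi = config$tpfi),
    error = function(e) {
      if (grepl("no signal onset", conditionMessage(e))) {
        warning("no signal onset found; running NoCA-only analysis")
        NULL
      } else stop(e)
    })

  noca_stack <- if (is.null(phases)) stack else
    extract_phase(stack, phases, "noca")

  # --- phase 1: NoCA core detection
  score <- sum_components(zscore_components(
    pixel_fourier_magnitudes(noca_stack))$features)
  noca_core <- threshold_noca(score, z_thresh = config$z_thresh,
                              z_mult = config$z_mult,
                              min_area = config$noca_min_area)
  noca_regions <- label_regions(noca_core, "noca")

  growths <- list()
  region_records <- list()
  grow_phase <- function(regions, core_mask, phase_stack) {
    for (reg0 in regions) tryCatch({
      reg <- compute_seed(reg0)
      rs <- region_seed(config$rng_seed, reg$phase_tag, reg$region_id)
      ts <- build_training_set(reg, phase_stack, phase_mask = core_mask,
                               margin = config$margin,
                               spacing = config$spacing, rng_seed = rs)
      clf <- train_classifier(ts, k = config$k)
      g <- grow_region(reg, clf, ts, phase_stack)
      growths[[length(growths) + 1L]] <<- g
      region_records[[length(region_records) + 1L]] <<- list(
        region_id = reg$region_id, phase = reg$phase_tag,
        seed = as.integer(reg$seed), core_pixels = nrow(reg$pixels),
        grown_pixels = sum(g$accepted), rng_seed = rs)
    }, error = function(e)
      stop(sprintf("seed/train/grow stage (%s region %d): %s",
                   reg0$phase_tag, reg0$region_id, conditionMessage(e)),
           call. = FALSE))
  }
  grow_phase(noca_regions, noca_core, noca_stack)

  # --- exclusion of the NoCA core, then phase 3: flush-out detection
  excluded_stack <- exclude_pixels(stack, noca_core)
  flush_regions <- list()
  if (!is.null(phases) && phases$tpfi < d[3] - 1L) {
    flush_stack <- extract_phase(excluded_stack, phases, "flushout")
    if (dim(flush_stack$counts)[3] >= 2L) {
      filtered <- highpass_stack(flush_stack, config$cutoff_sigma)
      ism <- interval_std_maps(filtered, config$interval_len,
                               excluded = flush_stack$excluded)
      summ <- sum_and_rescale(ism)
      flush_core <- threshold_flushout(summ, config$flushout_thresh,
                                       config$flushout_min_area)
      flush_regions <- label_regions(flush_core, "flushout")
      grow_phase(flush_regions, flush_core, flush_stack)
    }
  }

  map <- assemble_pollution_map(growths, noca_core, dim = d[1:2])
  verdict <- length(noca_regions) > 0L || length(flush_regions) > 0L

  report <- list(
    phases = if (is.null(phases)) NULL else
      list(ssp = phases$ssp, tpfi = phases$tpfi),
    noca_core_pixels = sum(noca_core),
    noca_regions = length(noca_regions),
    flushout_regions = length(flush_regions),
    regions = region_records,
    polluted = verdict,
    polluted_pixels = sum(map$grid),
    config = config_snapshot(config),
    rng_seed = config$rng_seed
  )
  list(map = map, report = report)
}

# JSON-serializable configuration snapshot (NULLs become NA for round-trip)
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap[vapply(snap, is.null, logical(1))] <- NA
  snap
}

#' Restore a pipeline configuration from a report snapshot
#'
#' @param snapshot the `config` element of a run report.
#' @return a [pipeline_config()] reproducing the run.
#' @export
config_from_snapshot <- function(snapshot) {
  snapshot <- lapply(snapshot, function(v)
    if (length(v) == 1L && is.na(v)) NULL else v)
  as_pipeline_config(snapshot)
}

#' Evaluate a pipeline result against ground truth
#'
#' @param map a `pollution_map`.
#' @param truth the `truth` element of [simulate_stack()] (or any list with
#'   `mask`, `regions`, `polluted`).
#' @return list with `dice` (NA when truth and prediction are both empty),
#'   area `counts`, `area_f1` (NA when no regions exist on either side) and
#'   the logical `predicted_polluted` / `labelled_polluted` pair.
#' @export
evaluate_against_truth <- function(map, truth) {
  pred_regions <- label_regions(map$grid, "noca")
  counts <- area_detection_counts(pred_regions, truth$regions,
                                  dim = dim(map$grid))
  dice <- if (any(map$grid) || any(truth$mask))
    dice_masks(map$grid, truth$mask) else NA_real_
  area_f1 <- if (counts$tp + counts$fp + counts$fn > 0)
    f1_from_counts(counts$tp, counts$fp, counts$fn) else NA_real_
  list(dice = dice, counts = counts, area_f1 = area_f1,
       predicted_polluted = any(map$grid),
       labelled_polluted = isTRUE(truth$polluted))
}

#' Run the pipeline over a list of synthetic configurations
#'
#' Simulates each configuration, segments it, and evaluates the result
#' against the known ground truth -- the synthetic analogue of a clinical
#' evaluation table.
#'
#' @param configs list of [sim_config()] objects (e.g. [default_suite()]).
#' @param config a [pipeline_config()] applied to every stack.
#' @param progress print one line per dataset.
#' @return data frame with one row per dataset: `dataset`, `group`,
#'   `labelled`, `predicted`, `dice`, `tp`, `fn`, `fp`, `area_f1`,
#'   `included` (polluted datasets only, for Dice/area averaging).
#' @export
evaluate_suite <- function(configs, config = pipeline_config(),
                           progress = FALSE) {
  rows <- lapply(seq_along(configs), function(i) {
    sim <- simulate_stack(configs[[i]])
    res <- run_pipeline(sim$stack, config)
    ev <- evaluate_against_truth(res$map, sim$truth)
    if (progress)
      message(sprintf("dataset %d: predicted=%s labelled=%s dice=%.3f",
                      i, ev$predicted_polluted, ev$labelled_polluted,
                      if (is.na(ev$dice)) NaN else ev$dice))
    data.frame(dataset = i,
               group = attr(configs[[i]], "suite_group") %||% NA_character_,
               labelled = ev$labelled_polluted,
               predicted = ev$predicted_polluted,
               dice = ev$dice,
               tp = ev$counts$tp, fn = ev$counts$fn, fp = ev$counts$fp,
               area_f1 = ev$area_f1,
               included = ev$labelled_polluted)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
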