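# Segmentation evaluation: pixel-level Dice per dataset, region-level
# area-detection F1, and a dataset-level pollution-classification F1. All
# three reduce to F1 = 2*TP / (2*TP + FP + FN) on different count
# definitions. The dataset-level score follows the convention of the
# clinical evaluation this package mirrors: correct identifications of BOTH
# classes count as true positives (an accuracy-flavoured F1); the standard
# positive-class F1 is available separately.

#' F1 score from confusion counts
#'
#' `F1 = 2*TP / (2*TP + FP + FN)`. For binary masks this equals Dice's
#' coefficient.
#'
#' @param tp,fp,fn non-negative counts; not all zero.
#' @return the F1 score in `[0, 1]`.
#' @examples
#' f1_from_counts(74, 1, 0)   # 0.9933
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fp + fn == 0) stop("undefined F1 (all counts zero)")
  2 * tp / (2 * tp + fp + fn)
}

#' Dice's coefficient between two binary masks
#'
#' Pixel-wise true positives, false positives and false negatives between a
#' predicted and a ground-truth mask, combined with [f1_from_counts()].
#' Symmetric in its arguments; equals 1 iff the masks are identical.
#'
#' @param pred,truth logical matrices of the same shape, not both empty.
#' @return Dice's coefficient in `[0, 1]`.
#' @export
dice_masks <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  storage.mode(pred) <- "logical"; storage.mode(truth) <- "logical"
  pred[is.na(pred)] <- FALSE; truth[is.na(truth)] <- FALSE
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) stop("undefined Dice (both masks empty)")
  f1_from_counts(tp, fp, fn)
}

#' Region-level detection counts
#'
#' A ground-truth region counts as detected (TP) if at least one of its
#' pixels is covered by any predicted pixel, otherwise it is a miss (FN);
#' a predicted region overlapping no truth pixel is a false alarm (FP).
#' A predicted region spanning several truth regions marks each of them
#' detected and is itself not an FP.
#'
#' @param pred_regions,truth_regions lists of `pollution_region` objects
#'   (e.g. from [label_regions()]) sharing one image shape.
#' @param dim integer `(height, width)` of the shared image; inferred from
#'   the regions when `NULL`.
#' @return list with integer counts `tp`, `fp`, `fn`.
#' @export
area_detection_counts <- function(pred_regions, truth_regions, dim = NULL) {
  shape <- dim
  for (r in c(pred_regions, truth_regions))
    if (!is.null(r$dim)) { shape <- r$dim; break }
  if (is.null(shape)) {
    if (length(pred_regions) + length(truth_regions) == 0L)
      return(list(tp = 0L, fp = 0L, fn = 0L))
    stop("cannot infer the image shape; pass `dim`")
  }
  pred_mask <- matrix(FALSE, shape[1], shape[2])
  for (r in pred_regions) pred_mask[r$pixels] <- TRUE
  truth_mask <- matrix(FALSE, shape[1], shape[2])
  for (r in truth_regions) truth_mask[r$pixels] <- TRUE

  tp <- 0L; fn <- 0L
  for (r in truth_regions) {
    if (any(pred_mask[r$pixels])) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- 0L
  for (r in pred_regions) {
    if (!any(truth_mask[r$pixels])) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Dataset-level pollution-classification F1
#'
#' Scores the per-dataset polluted / pollution-free verdicts. Following the
#' convention this package mirrors, a correct verdict on EITHER class counts
#' as a true positive, a pollution-free dataset flagged polluted as a false
#' positive, and a missed polluted dataset as a false negative; the result
#' is [f1_from_counts()] on those counts. Use
#' [classification_f1_positive()] for the standard positive-class F1.
#'
#' @param predicted,labelled logical vectors of equal, positive length:
#'   `TRUE` = polluted.
#' @return the dataset-level F1.
#' @export
dataset_classification_f1 <- function(predicted, labelled) {
  check_verdicts(predicted, labelled)
  tp <- sum(predicted == labelled)
  fp <- sum(!labelled & predicted)
  fn <- sum(labelled & !predicted)
  f1_from_counts(tp, fp, fn)
}

#' Standard positive-class F1 for dataset verdicts
#'
#' The conventional F1 where only correctly detected polluted datasets count
#' as true positives.
#'
#' @inheritParams dataset_classification_f1
#' @return the positive-class F1.
#' @export
classification_f1_positive <- function(predicted, labelled) {
  check_verdicts(predicted, labelled)
  tp <- sum(predicted & labelled)
  fp <- sum(predicted & !labelled)
  fn <- sum(!predicted & labelled)
  f1_from_counts(tp, fp, fn)
}

check_verdicts <- function(predicted, labelled) {
  if (length(predicted) == 0L || length(predicted) != length(labelled))
    stop("verdict vectors must be non-empty and of equal length")
  if (!is.logical(predicted) || !is.logical(labelled))
    stop("verdicts must be logical")
  invisible(TRUE)
}

#' Summarize per-dataset evaluations
#'
#' Averages the Dice coefficients and pools the area-detection counts over
#' the included datasets (datasets whose ground truth is considered
#' unreliable can be excluded from both averages while still contributing to
#' the dataset-level verdict F1 elsewhere).
#'
#' @param evals data frame with columns `dice`, `tp`, `fn`, `fp` and
#'   logical `included`.
#' @return list with `mean_dice`, `min_dice`, pooled `counts` (tp/fp/fn) and
#'   `total_area_f1`.
#' @export
summarize_evaluations <- function(evals) {
  evals <- as.data.frame(evals)
  need <- c("dice", "tp", "fn", "fp", "included")
  if (!all(need %in% names(evals))) stop("missing evaluation columns")
  inc <- evals[evals$included, , drop = FALSE]
  if (nrow(inc) == 0L) stop("no datasets included in the averages")
  counts <- list(tp = sum(inc$tp), fp = sum(inc$fp), fn = sum(inc$fn))
  list(
    mean_dice = mean(inc$dice),
    min_dice = min(inc$dice),
    counts = counts,
    total_area_f1 = f1_from_counts(counts$tp, counts$fp, counts$fn)
  )
}

#' Reference per-dataset evaluation results
#'
#' The published per-dataset segmentation results of the clinical NIR-FOI
#' light-pollution study this package re-implements: for each of the 18
#' light-polluted datasets, the pixel-level Dice coefficient, the
#' region-level detection counts (TP / FN / FP) and the resulting area F1.
#' One dataset (number 12) could not be labelled reliably and is flagged
#' `included = FALSE`; it is excluded from the Dice and area-F1 averages but
#' still counts in the dataset-level verdict score.
#'
#' @return data frame with columns `dataset`, `dice`, `tp`, `fn`, `fp`,
#'   `area_f1`, `included`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_evaluation.csv",
                      package = "nirpol", mustWork = TRUE)
  df <- utils::read.csv(path)
  df$included <- as.logical(df$included)
  df
}
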