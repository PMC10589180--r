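# File I/O: multi-page TIFF stacks in, PNG masks / float TIFF score images /
# JSON reports / YAML-JSON configuration files out.

#' Read a stack from disk
#'
#' Supports multi-page TIFF (one page per frame, 16-bit unsigned counts) and
#' `.rds` files holding either an [fo_stack()] or a plain 3-D array (or a
#' list with a `counts` element).
#'
#' @param path input file.
#' @param frame_interval_s seconds per frame metadata to attach.
#' @return an [fo_stack()].
#' @export
read_stack <- function(path, frame_interval_s = 1.0) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("cannot read stack: ", path, " (", conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    counts <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (f in seq_along(pages)) {
      pg <- pages[[f]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # first channel
      counts[, , f] <- pg
    }
    fo_stack(counts, frame_interval_s)
  } else if (ext == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "fo_stack")) obj
    else if (is.list(obj) && !is.null(obj$counts))
      fo_stack(obj$counts, frame_interval_s)
    else fo_stack(obj, frame_interval_s)
  } else {
    stop("unsupported stack format: ", path)
  }
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' Counts must lie in 0..65535; they are stored as 16-bit unsigned samples
#' and round-trip exactly through [read_stack()].
#'
#' @param stack an [fo_stack()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot_stack(stack)
  if (max(stack$counts) > 65535)
    stop("counts exceed the 16-bit range")
  nt <- n_frames(stack)
  pages <- lapply(seq_len(nt), function(f)
    round(stack$counts[, , f]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' @param path input file; any strictly positive pixel is foreground.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write a score image as a 32-bit float TIFF
#'
#' For visual inspection of the pollution-emphasis image. Values are
#' min-max scaled to `[0, 1]` (the absolute score scale is meaningful only
#' relative to the per-dataset threshold); unscored pixels are written as 0.
#'
#' @param score a `score_image`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_score_tiff <- function(score, path) {
  if (!inherits(score, "score_image")) stop("expected a `score_image`")
  v <- score$scores
  v[is.na(v)] <- min(v, na.rm = TRUE)
  v <- minmax_norm(v)
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml` / `.yaml`) or JSON (`.json`); keys must be valid
#' [pipeline_config()] arguments.
#'
#' @param path configuration file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  values <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported configuration format: ", path))
  as_pipeline_config(values)
}

#' Write a run report as JSON
#'
#' @param report the `report` element of [run_pipeline()]'s result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a suite evaluation table as CSV
#'
#' @param evals data frame from [evaluate_suite()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_evaluation_csv <- function(evals, path) {
  utils::write.csv(evals, path, row.names = FALSE)
  invisible(path)
}
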