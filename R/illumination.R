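#' Classify an image as high or low illumination
#'
#' The default rule thresholds the Rec.601 mean luma of the image: mean luma
#' (0..255 scale) at or above \code{threshold} is \code{"high"}, below is
#' \code{"low"}. A custom \code{predictor} (e.g. a wrapper around a trained
#' classifier) may be supplied; its label is used verbatim. The default
#' threshold of 90 separates well-lit daytime scenes from backlit, evening
#' and artificial-night images in typical orchard footage; it is a heuristic
#' stand-in, not a reimplementation of any particular trained model.
#'
#' @param img RGB raster array (see \code{\link{read_raster}}).
#' @param threshold Luma threshold in [0, 255]; default 90.
#' @param predictor Optional function(img) returning "high" or "low".
#' @return \code{"high"} or \code{"low"}.
#' @export
#' @examples
#' classify_illumination(solid <- array(1, c(4, 4, 3)))          # "high"
#' classify_illumination(array(0, c(4, 4, 3)))                   # "low"
classify_illumination <- function(img, threshold = 90, predictor = NULL) {
  if (!is.null(predictor)) {
    lab <- predictor(img)
    return(assert_illumination(lab))
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("classify_illumination expects an RGB raster", call. = FALSE)
  if (mean_luma(img) >= threshold) "high" else "low"
}

#' Partition a dataset into (region, illumination) sub-datasets
#'
#' Each image is assigned to exactly one sub-dataset keyed
#' \code{"<REGION>_H"} or \code{"<REGION>_L"}. If the dataset's images table
#' already carries an \code{illumination} column (e.g. from a manifest) it is
#' used directly; otherwise each image file is read and classified with
#' \code{labeler}.
#'
#' @param dataset An \code{ob_dataset} whose images all have a region.
#' @param labeler Function(img raster) returning "high"/"low"; defaults to
#'   \code{\link{classify_illumination}} with its default threshold.
#' @param use_manifest Use the images table's illumination column when
#'   present (default TRUE).
#' @return Named list of \code{ob_dataset}s keyed by sub-dataset key; the
#'   sub-dataset sizes sum to the input size.
#' @export
partition_by_illumination <- function(dataset, labeler = classify_illumination,
                                      use_manifest = TRUE) {
  imgs <- dataset$images
  if (nrow(imgs) == 0) return(structure(list(), names = character()))
  if (use_manifest && "illumination" %in% names(imgs) &&
      !anyNA(imgs$illumination)) {
    lab <- vapply(imgs$illumination, assert_illumination, character(1))
  } else {
    lab <- vapply(imgs$path, function(p) labeler(read_raster(p)), character(1))
  }
  keys <- mapply(subdataset_key, imgs$region, lab)
  out <- lapply(split(imgs$image_id, keys), function(ids) {
    d <- dataset_subset(dataset, ids)
    d$images$illumination <- lab[match(d$images$image_id, imgs$image_id)]
    d
  })
  for (k in names(out)) out[[k]]$name <- k
  out
}
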