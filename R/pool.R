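#' Occlusion element kinds
#' @return Character vector of the four element kinds.
#' @export
element_kinds <- function() c("fruit", "branch", "leaf", "composite")

#' Construct an occlusion element
#'
#' An element is an RGBA raster whose alpha channel is the segmentation mask
#' of a fruit, branch, leaf, or composite occluder, tagged with the
#' illumination condition it was cut from.
#'
#' @param raster RGBA array (h x w x 4). Alpha is binarized at 0.5 when
#'   pasting. If an RGB raster is given, \code{bg_key} (an RGB triplet)
#'   identifies background pixels to derive the mask from; otherwise fully
#'   opaque.
#' @param kind One of \code{\link{element_kinds}}.
#' @param illumination "high" or "low".
#' @param source_id Identifier of the source file / generator call.
#' @param bg_key Optional background RGB triplet for mask inference.
#' @return An \code{ob_element}.
#' @export
ob_element <- function(raster, kind, illumination, source_id = "element",
                       bg_key = NULL) {
  kind <- match.arg(kind, element_kinds())
  assert_illumination(illumination)
  if (raster_channels(raster) < 4L) {
    rgbr <- rgb_of(raster)
    a <- if (is.null(bg_key)) matrix(1, raster_height(raster), raster_width(raster))
    else {
      d <- abs(rgbr[, , 1] - bg_key[1]) + abs(rgbr[, , 2] - bg_key[2]) +
        abs(rgbr[, , 3] - bg_key[3])
      (d > 0.05) * 1
    }
    raster <- abind_channels(rgbr, array(a, c(dim(a), 1L)))
  }
  if (sum(raster[, , 4] >= 0.5) < 1)
    stop("element '", source_id, "' has an empty mask", call. = FALSE)
  structure(list(raster = raster, kind = kind, illumination = illumination,
                 source_id = source_id), class = "ob_element")
}

#' @export
print.ob_element <- function(x, ...) {
  cat("<ob_element>", x$kind, x$illumination,
      paste0(raster_width(x$raster), "x", raster_height(x$raster)),
      x$source_id, "\n")
  invisible(x)
}

#' Canonical base-image sizes
#'
#' Base images are standardized to 640x480 or 1280x720 (width x height) to
#' match the raw orchard image sizes.
#' @return A list of two c(width, height) pairs.
#' @export
base_image_sizes <- function() list(c(640L, 480L), c(1280L, 720L))

#' Component pool
#'
#' The pool holds the material synthesis draws from: occlusion elements
#' indexed by (kind, illumination) and fruit-free base images indexed by
#' illumination. High and low illumination pools are isolated — sampling
#' never crosses them.
#'
#' @param elements List of \code{ob_element}.
#' @param base_images List of base-image records (as made by
#'   \code{\link{prepare_base_images}}).
#' @return An \code{ob_pool}.
#' @export
ob_pool <- function(elements = list(), base_images = list()) {
  el_index <- list()
  for (k in element_kinds()) for (il in illumination_levels())
    el_index[[paste(k, il, sep = "/")]] <- list()
  for (e in elements) {
    key <- paste(e$kind, e$illumination, sep = "/")
    el_index[[key]] <- c(el_index[[key]], list(e))
  }
  bi_index <- list(high = list(), low = list())
  for (b in base_images) bi_index[[b$illumination]] <-
    c(bi_index[[b$illumination]], list(b))
  structure(list(elements = el_index, base_images = bi_index),
            class = "ob_pool")
}

#' @export
print.ob_pool <- function(x, ...) {
  cat("<ob_pool>\n")
  for (key in names(x$elements))
    cat(sprintf("  %-16s %d elements\n", key, length(x$elements[[key]])))
  for (il in names(x$base_images))
    cat(sprintf("  base/%-11s %d images\n", il, length(x$base_images[[il]])))
  invisible(x)
}

#' Load a component pool from a directory
#'
#' Expected layout: \code{<pool_dir>/<illumination>/<kind>/*.png} for
#' elements (PNG with alpha; RGB-only files get a mask inferred from
#' \code{bg_key} or are rejected) and \code{<pool_dir>/<illumination>/base/*}
#' for base images. Empty categories yield a warning, not an error, so toy
#' pools work.
#'
#' @param pool_dir Pool root directory.
#' @param bg_key Optional RGB triplet for mask inference on RGB elements.
#' @param reference_count Per-category element count that silences the "small
#'   category" warning (default 500, the recommended full-scale pool size).
#' @return An \code{ob_pool}. Base images are loaded as-is (not resized);
#'   pass them through \code{\link{prepare_base_images}} if they are not at a
#'   canonical size.
#' @export
load_pool <- function(pool_dir, bg_key = NULL, reference_count = 500L) {
  elements <- list(); bases <- list()
  for (il in illumination_levels()) {
    for (k in element_kinds()) {
      d <- file.path(pool_dir, il, k)
      files <- if (dir.exists(d))
        sort(list.files(d, pattern = "\\.(png|PNG)$", full.names = TRUE))
      else character()
      if (length(files) == 0)
        warning("empty pool category: ", il, "/", k, call. = FALSE)
      else if (length(files) < reference_count)
        warning("pool category ", il, "/", k, " has ", length(files),
                " elements (< ", reference_count, ")", call. = FALSE)
      for (f in files) {
        r <- read_raster(f)
        if (raster_channels(r) < 4L && is.null(bg_key))
          stop("element without alpha and no bg_key: ", f, call. = FALSE)
        elements <- c(elements, list(
          ob_element(r, k, il, source_id = basename(f), bg_key = bg_key)))
      }
    }
    bd <- file.path(pool_dir, il, "base")
    bfiles <- if (dir.exists(bd))
      sort(list.files(bd, pattern = "\\.(png|jpg|jpeg|PNG|JPG)$",
                      full.names = TRUE))
    else character()
    if (length(bfiles) == 0)
      warning("no base images for illumination ", il, call. = FALSE)
    for (f in bfiles) {
      r <- rgb_of(read_raster(f))
      bases <- c(bases, list(list(raster = r, illumination = il,
                                  blurred = FALSE, source_id = basename(f))))
    }
  }
  ob_pool(elements, bases)
}

#' Standardize base images
#'
#' Each input raster is scaled to one of the two canonical sizes (640x480 or
#' 1280x720), chosen uniformly at random under the seed. For low
#' illumination, a fraction of the outputs is additionally Gaussian-blurred
#' (sigma \code{blur_sigma}) and flagged — blurred copies supplement the
#' scarcer low-light base material.
#'
#' @param images List of RGB rasters.
#' @param illumination "high" or "low".
#' @param seed Integer seed.
#' @param blur_fraction Fraction of low-illumination outputs to blur
#'   (default 0.25; ignored for high illumination).
#' @param blur_sigma Gaussian sigma in pixels (default 2).
#' @return List of base-image records: \code{raster}, \code{illumination},
#'   \code{blurred}, \code{source_id}.
#' @export
prepare_base_images <- function(images, illumination, seed = 1L,
                                blur_fraction = 0.25, blur_sigma = 2.0) {
  assert_illumination(illumination)
  stopifnot(length(images) > 0)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  sizes <- base_image_sizes()
  lapply(seq_along(images), function(i) {
    sz <- sizes[[sample.int(2L, 1L)]]
    r <- resize_raster(rgb_of(images[[i]]), height = sz[2], width = sz[1])
    blurred <- illumination == "low" && stats::runif(1) < blur_fraction
    if (blurred) r <- blur_raster(r, sigma = blur_sigma)
    list(raster = r, illumination = illumination, blurred = blurred,
         source_id = paste0("base_", i))
  })
}

#' Sample one element from the pool
#'
#' Uniform draw from the (kind, illumination) category using the current RNG
#' state; the pool is never mutated.
#'
#' @param pool An \code{ob_pool}.
#' @param kind Element kind.
#' @param illumination "high" or "low".
#' @return An \code{ob_element}.
#' @export
sample_element <- function(pool, kind, illumination) {
  kind <- match.arg(kind, element_kinds())
  assert_illumination(illumination)
  lst <- pool$elements[[paste(kind, illumination, sep = "/")]]
  if (length(lst) == 0)
    stop("component pool exhausted for ", kind, "/", illumination,
         call. = FALSE)
  lst[[sample.int(length(lst), 1L)]]
}

sample_base_image <- function(pool, illumination) {
  lst <- pool$base_images[[illumination]]
  if (length(lst) == 0)
    stop("no base images for illumination ", illumination, call. = FALSE)
  lst[[sample.int(length(lst), 1L)]]
}

#' Summarize a pool as a validation report
#'
#' @param pool An \code{ob_pool}.
#' @param reference_count Target per-category element count (default 500).
#' @param reference_base Target base-image count per illumination (1000).
#' @return List with per-category counts and a \code{complete} flag.
#' @export
pool_summary <- function(pool, reference_count = 500L,
                         reference_base = 1000L) {
  el <- vapply(pool$elements, length, integer(1))
  bi <- vapply(pool$base_images, length, integer(1))
  list(elements = el, base_images = bi,
       complete = all(el >= reference_count) && all(bi >= reference_base))
}
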