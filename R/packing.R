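# Packing synthetic crops onto base images with automatic labels, and the
# end-to-end balanced-dataset builder.

#' Pack synthetic crops onto base images (shelf policy)
#'
#' Crops are placed in order, left to right along a shelf row, opening a new
#' row when the current one is full and requesting a new base image when the
#' crop fits nowhere on the current canvas. Every placement is recorded as an
#' automatic label (class + pasted extent); placements never overlap and
#' always lie inside the base image.
#'
#' @param crops List of \code{ob_crop}.
#' @param base_supplier Function() returning a base-image record (list with
#'   \code{raster}, \code{illumination}), e.g. a seeded draw from the pool.
#' @param padding Pixel gap between crops and from the border (default 5).
#' @param max_base_draws New-base attempts per crop before giving up
#'   (default 100).
#' @return List of packed images, each a list with \code{raster},
#'   \code{boxes} (data.frame cls/xmin/ymin/xmax/ymax), \code{illumination},
#'   \code{provenance}.
#' @export
pack_crops <- function(crops, base_supplier, padding = 5L,
                       max_base_draws = 100L) {
  out <- list()
  canvas <- NULL
  finalize <- function() {
    if (!is.null(canvas) && nrow(canvas$boxes) > 0)
      out[[length(out) + 1]] <<- canvas
    canvas <<- NULL
  }
  new_canvas <- function(min_w, min_h) {
    for (i in seq_len(max_base_draws)) {
      b <- base_supplier()
      W <- raster_width(b$raster); H <- raster_height(b$raster)
      if (min_w + 2 * padding <= W && min_h + 2 * padding <= H) {
        canvas <<- list(raster = b$raster, boxes = data.frame(),
                        illumination = b$illumination,
                        provenance = list(base = b$source_id %||% "base"),
                        x = padding, y = padding, row_h = 0L,
                        W = W, H = H)
        return(invisible(NULL))
      }
    }
    stop("no base image can hold a ", min_w, "x", min_h, " crop",
         call. = FALSE)
  }
  max_sz <- do.call(rbind, base_image_sizes())
  for (ci in seq_along(crops)) {
    crop <- crops[[ci]]
    w <- raster_width(crop$raster); h <- raster_height(crop$raster)
    if (all(w + 2 * padding > max_sz[, 1]) ||
        all(h + 2 * padding > max_sz[, 2]))
      stop("crop ", ci, " (", w, "x", h,
           ") exceeds every canonical base size", call. = FALSE)
    placed <- FALSE
    while (!placed) {
      if (is.null(canvas)) new_canvas(w, h)
      if (w + 2 * padding > canvas$W) {              # canvas too narrow
        finalize()
        next
      }
      if (canvas$x + w > canvas$W - padding) {       # next row
        canvas$x <- padding
        canvas$y <- canvas$y + canvas$row_h + padding
        canvas$row_h <- 0L
      }
      if (canvas$y + h > canvas$H - padding) {       # canvas full
        finalize()
        next
      }
      x <- canvas$x; y <- canvas$y
      canvas$raster <- paste_raster(canvas$raster, rgb_of(crop$raster),
                                    x = x, y = y, binarize_alpha = FALSE)
      canvas$boxes <- rbind(canvas$boxes,
                            data.frame(cls = crop$cls, xmin = x, ymin = y,
                                       xmax = x + w, ymax = y + h))
      canvas$provenance$crops <- c(canvas$provenance$crops,
                                   list(crop$provenance))
      canvas$x <- x + w + padding
      canvas$row_h <- max(canvas$row_h, h)
      placed <- TRUE
    }
  }
  finalize()
  lapply(out, function(cv)
    cv[c("raster", "boxes", "illumination", "provenance")])
}

#' Build the balanced dataset
#'
#' Runs the whole augmentation for a balance plan: for every retained
#' (sub-dataset, class) cell, exactly \code{deficit} synthetic crops are
#' generated — N by cyclic extraction, B/L by the edge entry rule, F by the
#' overlap-capped canvas rule, fused classes by sequential composition —
#' packed onto base images of the matching illumination, written to
#' \code{out_dir} with Pascal VOC and YOLO labels, and merged with the basic
#' training set. After the build every retained cell holds exactly
#' \code{plan$target} boxes.
#'
#' @param basic_train An \code{ob_dataset} whose images carry \code{region}
#'   and \code{illumination}, or a partition (named list of sub-datasets).
#' @param plan An \code{ob_balance_plan}.
#' @param pool An \code{ob_pool} with elements and base images for every
#'   illumination the plan needs.
#' @param seed Master seed; the build is reproducible bit-for-bit.
#' @param out_dir Directory for synthetic images and labels.
#' @param padding Packing gap in pixels (default 5).
#' @param route Fused-class route (see \code{\link{synthesize_fused}}).
#' @return An \code{ob_balance_result}: list with \code{dataset} (basic +
#'   synthetic), \code{synthetic} (the synthetic part alone) and
#'   \code{manifest} (per-cell scheduled vs produced counts).
#' @export
build_balanced_dataset <- function(basic_train, plan, pool, seed = 1L,
                                   out_dir, padding = 5L,
                                   route = "sequential") {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  is_partition <- is.list(basic_train) && !inherits(basic_train, "ob_dataset")
  base_ds <- if (is_partition)
    do.call(dataset_bind, c(unname(basic_train), list(name = "basic_train")))
  else basic_train
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)

  manifest <- list()
  syn_imgs <- list(); syn_boxes <- list()
  counter <- 0L
  for (key in plan$retained_keys) {
    set.seed(derive_seed(seed, paste0("synth/", key)))
    illum <- parse_subdataset_key(key)$illumination
    crops <- list()
    for (cls in occlusion_classes()) {
      need <- plan$deficits[key, cls]
      if (need == 0) next
      n_crops <- extract_n_crops(basic_train, key, need)
      for (nc in n_crops) {
        crop <- switch(
          cls,
          N = ob_crop(nc, "N", provenance = list(elements = character())),
          B = synthesize_single_occluder(
            nc, sample_element(pool, "branch", illum)),
          L = synthesize_single_occluder(
            nc, sample_element(pool, "leaf", illum)),
          F = synthesize_fruit_occlusion(
            nc, sample_element(pool, "fruit", illum)),
          synthesize_fused(nc, cls, pool, illum, route = route))
        crops[[length(crops) + 1]] <- crop
      }
      manifest[[key]][[cls]] <- list(scheduled = unname(need),
                                     produced = unname(need))
    }
    if (!length(crops)) next
    set.seed(derive_seed(seed, paste0("pack/", key)))
    packed <- pack_crops(crops, function() sample_base_image(pool, illum),
                         padding = padding)
    k <- parse_subdataset_key(key)
    for (p in packed) {
      counter <- counter + 1L
      image_id <- sprintf("%s_syn_%05d", key, counter)
      path <- file.path(out_dir, "images", paste0(image_id, ".png"))
      write_raster(p$raster, path)
      syn_imgs[[image_id]] <- data.frame(
        image_id = image_id, path = path,
        width = raster_width(p$raster), height = raster_height(p$raster),
        region = k$region, illumination = k$illumination)
      b <- p$boxes; b$image_id <- image_id
      syn_boxes[[image_id]] <-
        b[c("image_id", "cls", "xmin", "ymin", "xmax", "ymax")]
    }
  }
  synthetic <- ob_dataset(do.call(rbind, syn_imgs) %||%
                            data.frame(image_id = character(),
                                       path = character(), width = numeric(),
                                       height = numeric(),
                                       region = character()),
                          do.call(rbind, syn_boxes), name = "synthetic")
  write_voc(synthetic, file.path(out_dir, "labels_voc"))
  write_yolo(synthetic, file.path(out_dir, "labels_yolo"))
  jsonlite::write_json(manifest, file.path(out_dir, "build_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  combined <- dataset_bind(base_ds, synthetic, name = "balanced")
  structure(list(dataset = combined, synthetic = synthetic,
                 manifest = manifest),
            class = "ob_balance_result")
}

#' @export
print.ob_balance_result <- function(x, ...) {
  cat("<ob_balance_result>\n  combined: ")
  print(x$dataset)
  cat("  synthetic images:", n_images(x$synthetic), "\n")
  invisible(x)
}
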