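# Synthesis of occluded apple crops from no-occlusion (N) crops and pool
# elements. Geometry lives on a lattice over the N crop: branch/leaf
# occluders enter from the crop boundary (edge entry rule), fruit occluders
# are placed on an enlarged canvas with a hard overlap cap.

#' Grid over an N crop
#'
#' The N crop is divided into \code{cells_per_side} equal parts per axis
#' (default 6), giving a lattice of \code{(cells_per_side + 1)^2} points.
#' Cell sizes are kept fractional; pixel positions are rounded only when a
#' concrete paste rectangle is formed.
#'
#' @param width,height N crop size in pixels.
#' @param cells_per_side Grid resolution (default 6).
#' @return A \code{grid_spec} list: cells_per_side, cell_w, cell_h.
#' @export
grid_spec <- function(width, height, cells_per_side = 6L) {
  stopifnot(cells_per_side >= 2L, width > 0, height > 0)
  structure(list(cells_per_side = as.integer(cells_per_side),
                 cell_w = width / cells_per_side,
                 cell_h = height / cells_per_side,
                 width = width, height = height),
            class = "grid_spec")
}

#' Edge entry points of a grid
#'
#' The boundary lattice points of the grid, in row-major order — the
#' positions where an occluder may enter the crop. A grid with
#' \code{cells_per_side = n} has exactly \code{4n} such points (24 for the
#' default 6x6 grid).
#'
#' @param grid A \code{grid_spec}, or an integer cells_per_side.
#' @return data.frame with integer columns \code{row}, \code{col} in
#'   \code{[0, cells_per_side]}.
#' @export
#' @examples
#' nrow(edge_entry_points(6))  # 24
edge_entry_points <- function(grid) {
  n <- if (inherits(grid, "grid_spec")) grid$cells_per_side else as.integer(grid)
  pts <- expand.grid(col = 0:n, row = 0:n)[, c("row", "col")]
  pts <- pts[order(pts$row, pts$col), ]
  pts <- pts[pts$row %in% c(0L, n) | pts$col %in% c(0L, n), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Valid endpoints for an occluder starting point
#'
#' Given a starting lattice point on the grid boundary, the endpoint may be
#' any lattice point that is (a) not in the same row, (b) not in the same
#' column, and (c) farther than \code{min_distance} grid lengths away
#' (Chebyshev distance by default) — close endpoints would give a degenerate
#' or inconspicuous paste rectangle.
#'
#' @param start List or one-row data.frame with \code{row}, \code{col}.
#' @param grid \code{grid_spec} or integer cells_per_side.
#' @param min_distance Exclusion radius in grid lengths (default 3; the
#'   constraint is strict: distance must exceed it).
#' @param metric "chebyshev" (default) or "euclidean".
#' @return data.frame of valid \code{row}, \code{col} lattice points.
#' @export
valid_endpoints <- function(start, grid, min_distance = 3,
                            metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  n <- if (inherits(grid, "grid_spec")) grid$cells_per_side else as.integer(grid)
  pts <- expand.grid(col = 0:n, row = 0:n)[, c("row", "col")]
  dr <- abs(pts$row - start$row); dc <- abs(pts$col - start$col)
  d <- if (metric == "chebyshev") pmax(dr, dc) else sqrt(dr^2 + dc^2)
  out <- pts[pts$row != start$row & pts$col != start$col & d > min_distance, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# pixel rectangle spanned by two lattice points (0-based half-open)
lattice_rect <- function(p, q, grid) {
  bbox(round(min(p$col, q$col) * grid$cell_w),
       round(min(p$row, q$row) * grid$cell_h),
       round(max(p$col, q$col) * grid$cell_w),
       round(max(p$row, q$row) * grid$cell_h))
}

#' Synthetic occlusion crop
#'
#' @param raster RGB raster, same size as the source N crop.
#' @param cls Occlusion class of the synthesized crop.
#' @param provenance List describing sources and sampled geometry.
#' @return An \code{ob_crop}.
#' @export
ob_crop <- function(raster, cls, provenance = list()) {
  occlusion_class_index(cls)
  structure(list(raster = raster, cls = cls, provenance = provenance),
            class = "ob_crop")
}

#' @export
print.ob_crop <- function(x, ...) {
  cat("<ob_crop>", x$cls,
      paste0(raster_width(x$raster), "x", raster_height(x$raster)), "\n")
  invisible(x)
}

# seeded sub-rectangle of an element covering scale^2 of its area, anchored
# at the alpha-weighted centroid (clamped into bounds)
crop_element_subrect <- function(raster, scale) {
  h <- raster_height(raster); w <- raster_width(raster)
  a <- alpha_of(raster)
  tot <- sum(a)
  if (tot > 0) {
    cy <- sum(row(a) * a) / tot; cx <- sum(col(a) * a) / tot
  } else {  # degenerate all-transparent mask: anchor at the center
    cy <- h / 2; cx <- w / 2
  }
  sw <- max(1L, round(scale * w)); sh <- max(1L, round(scale * h))
  x0 <- min(max(0, round(cx - sw / 2)), w - sw)
  y0 <- min(max(0, round(cy - sh / 2)), h - sh)
  raster[(y0 + 1):(y0 + sh), (x0 + 1):(x0 + sw), , drop = FALSE]
}

#' Synthesize a branch- or leaf-occluded crop
#'
#' Applies the edge entry rule: a start point is drawn from the grid's 24
#' boundary lattice points, an endpoint from \code{\link{valid_endpoints}};
#' the element is cropped at a random scale in [0.5, 1], resized to the
#' rectangle spanned by the two points, and alpha-composited onto the N
#' crop. The result is class B for a branch element and L for a leaf
#' element; pixels outside the paste rectangle are untouched.
#'
#' @param n_crop RGB raster of a no-occlusion apple crop.
#' @param element An \code{ob_element} of kind branch, leaf, or composite.
#' @param cells_per_side Grid resolution (default 6).
#' @param min_distance Endpoint exclusion radius in grid lengths (default 3).
#' @param scale_range Element crop scale range (default c(0.5, 1)).
#' @param max_retries Start-point resampling budget (default 100).
#' @param cls Output class override (used for the composite-element route of
#'   fused synthesis; defaults to B/L by element kind).
#' @return An \code{ob_crop}.
#' @export
synthesize_single_occluder <- function(n_crop, element, cells_per_side = 6L,
                                       min_distance = 3,
                                       scale_range = c(0.5, 1),
                                       max_retries = 100L, cls = NULL) {
  if (is.null(cls))
    cls <- switch(element$kind, branch = "B", leaf = "L",
                  stop("element kind ", element$kind,
                       " needs an explicit output class", call. = FALSE))
  grid <- grid_spec(raster_width(n_crop), raster_height(n_crop),
                    cells_per_side)
  entries <- edge_entry_points(grid)
  ends <- NULL
  for (try in seq_len(max_retries)) {
    start <- entries[sample.int(nrow(entries), 1L), ]
    cand <- valid_endpoints(start, grid, min_distance)
    if (nrow(cand) > 0) { ends <- cand; break }
  }
  if (is.null(ends))
    stop("no valid endpoint found after ", max_retries, " retries",
         call. = FALSE)
  end <- ends[sample.int(nrow(ends), 1L), ]
  rect <- lattice_rect(start, end, grid)
  scale <- stats::runif(1, scale_range[1], scale_range[2])
  sub <- crop_element_subrect(element$raster, scale)
  pw <- rect$xmax - rect$xmin; ph <- rect$ymax - rect$ymin
  sub <- resize_raster(sub, height = ph, width = pw)
  out <- paste_raster(rgb_of(n_crop), sub, x = rect$xmin, y = rect$ymin)
  ob_crop(out, cls,
          provenance = list(elements = element$source_id,
                            start = c(start$row, start$col),
                            end = c(end$row, end$col), scale = scale,
                            paste_box = rect))
}

#' Sample a fruit-occluder placement
#'
#' The N crop sits centered on a 14x14-cell canvas (cells the size of the N
#' grid's cells); the fruit element — resized to the N size — gets its
#' upper-left corner drawn uniformly at pixel resolution inside quadrant 1
#' (the canvas's upper-left 7x7 cells). A draw is rejected until the overlap
#' of the fruit footprint with the N footprint is at most
#' \code{max_overlap} of the N area (an over-covered apple would effectively
#' be an unoccluded one) and the element centroid does not coincide with the
#' canvas origin.
#'
#' @param width,height N crop size in pixels.
#' @param max_overlap Overlap cap as a fraction of the N area (default 0.34).
#' @param max_retries Rejection budget (default 100).
#' @return List: \code{corner} c(x, y) on the canvas, \code{overlap_fraction},
#'   \code{canvas} c(W, H), \code{n_offset} c(x, y) of the N footprint.
#' @export
sample_fruit_placement <- function(width, height, max_overlap = 0.34,
                                   max_retries = 100L) {
  stopifnot(max_overlap > 0, max_overlap < 1)
  cw <- width / 6; ch <- height / 6
  W <- round(14 * cw); H <- round(14 * ch)
  nx <- round(4 * cw); ny <- round(4 * ch)
  qx <- max(1L, floor(7 * cw)); qy <- max(1L, floor(7 * ch))
  for (try in seq_len(max_retries)) {
    cx <- sample.int(qx, 1L) - 1L
    cy <- sample.int(qy, 1L) - 1L
    ox <- max(0, min(cx + width, nx + width) - max(cx, nx))
    oy <- max(0, min(cy + height, ny + height) - max(cy, ny))
    frac <- ox * oy / (width * height)
    centered <- (cx + width / 2 == W / 2) && (cy + height / 2 == H / 2)
    if (frac <= max_overlap && !centered)
      return(list(corner = c(cx, cy), overlap_fraction = frac,
                  canvas = c(W, H), n_offset = c(nx, ny)))
  }
  stop("fruit placement rejected ", max_retries, " times", call. = FALSE)
}

#' Synthesize a fruit-occluded crop
#'
#' The fruit element is resized to the N crop size and pasted on the 14x14
#' canvas at an accepted \code{\link{sample_fruit_placement}}; the canvas is
#' then cropped back to the N footprint, so the output has the N crop's size
#' and at most \code{max_overlap} of its pixels covered.
#'
#' @param n_crop RGB raster of a no-occlusion apple crop.
#' @param fruit An \code{ob_element} of kind fruit.
#' @param max_overlap Overlap cap (default 0.34).
#' @param max_retries Rejection budget (default 100).
#' @return An \code{ob_crop} of class F.
#' @export
synthesize_fruit_occlusion <- function(n_crop, fruit, max_overlap = 0.34,
                                       max_retries = 100L) {
  if (fruit$kind != "fruit")
    stop("element kind must be fruit", call. = FALSE)
  w <- raster_width(n_crop); h <- raster_height(n_crop)
  pl <- sample_fruit_placement(w, h, max_overlap, max_retries)
  canvas <- solid_raster(pl$canvas[2], pl$canvas[1], rgb = c(0, 0, 0))
  canvas <- paste_raster(canvas, rgb_of(n_crop),
                         x = pl$n_offset[1], y = pl$n_offset[2],
                         binarize_alpha = FALSE)
  fr <- resize_raster(fruit$raster, height = h, width = w)
  canvas <- paste_raster(canvas, fr, x = pl$corner[1], y = pl$corner[2])
  out <- crop_raster(canvas, bbox(pl$n_offset[1], pl$n_offset[2],
                                  pl$n_offset[1] + w, pl$n_offset[2] + h))
  ob_crop(out, "F",
          provenance = list(elements = fruit$source_id,
                            corner = pl$corner,
                            overlap_fraction = pl$overlap_fraction))
}

#' Synthesize a fused occlusion crop (BL, BF, LF, BLF)
#'
#' Two routes. \code{"sequential"} (default) composes the single-occluder
#' steps: BL = branch then leaf; BF = fruit then branch; LF = fruit then
#' leaf; BLF = fruit, then branch, then leaf. \code{"composite_element"}
#' pastes one pre-segmented composite element by the edge entry rule.
#'
#' @param n_crop RGB raster of a no-occlusion apple crop.
#' @param target_cls One of "BL", "BF", "LF", "BLF".
#' @param pool An \code{ob_pool} holding the needed element kinds.
#' @param illumination "high" or "low" (element pool to draw from).
#' @param route "sequential" or "composite_element".
#' @param ... Passed to the single-step synthesizers.
#' @return An \code{ob_crop} of class \code{target_cls}.
#' @export
synthesize_fused <- function(n_crop, target_cls, pool, illumination,
                             route = c("sequential", "composite_element"),
                             ...) {
  route <- match.arg(route)
  if (!target_cls %in% c("BL", "BF", "LF", "BLF"))
    stop("not a fused class: ", target_cls, call. = FALSE)
  if (route == "composite_element") {
    el <- sample_element(pool, "composite", illumination)
    crop <- synthesize_single_occluder(n_crop, el, cls = target_cls, ...)
    return(crop)
  }
  steps <- switch(target_cls,
                  BL = c("branch", "leaf"),
                  BF = c("fruit", "branch"),
                  LF = c("fruit", "leaf"),
                  BLF = c("fruit", "branch", "leaf"))
  cur <- rgb_of(n_crop)
  used <- character(0)
  extra <- list()
  for (k in steps) {
    el <- sample_element(pool, k, illumination)
    step_crop <- if (k == "fruit")
      synthesize_fruit_occlusion(cur, el, ...)
    else
      synthesize_single_occluder(cur, el, ...)
    cur <- step_crop$raster
    used <- c(used, el$source_id)
    if (!is.null(step_crop$provenance$overlap_fraction))
      extra$overlap_fraction <- step_crop$provenance$overlap_fraction
  }
  ob_crop(cur, target_cls,
          provenance = c(list(elements = used, route = route), extra))
}

#' Cyclically extract N crops from a sub-dataset
#'
#' Crops every no-occlusion (N) box of the given (region, illumination)
#' sub-dataset, in a seeded random order, cycling through the available
#' boxes round-robin until \code{count} crops are produced — when more
#' synthetic instances are needed than distinct N boxes exist, boxes are
#' reused as evenly as possible.
#'
#' @param dataset An \code{ob_dataset}, or a partition (named list) from
#'   \code{\link{partition_by_illumination}}.
#' @param key Sub-dataset key, e.g. "ZY_H".
#' @param count Number of crops to extract.
#' @return List of RGB rasters (each the size of its source box).
#' @export
extract_n_crops <- function(dataset, key, count) {
  sub <- if (is.list(dataset) && !inherits(dataset, "ob_dataset"))
    dataset[[key]]
  else {
    k <- parse_subdataset_key(key)
    imgs <- dataset$images
    keep <- imgs$region == k$region
    if ("illumination" %in% names(imgs) && !anyNA(imgs$illumination))
      keep <- keep & imgs$illumination == k$illumination
    dataset_subset(dataset, imgs$image_id[keep], name = key)
  }
  if (is.null(sub)) stop("no sub-dataset for key ", key, call. = FALSE)
  nb <- sub$boxes[sub$boxes$cls == "N", , drop = FALSE]
  if (count == 0) return(list())
  if (nrow(nb) == 0)
    stop("no N boxes available in ", key, call. = FALSE)
  perm <- sample.int(nrow(nb))
  idx <- rep(perm, length.out = count)
  cache <- new.env(parent = emptyenv())
  lapply(idx, function(i) {
    rec <- sub$images[sub$images$image_id == nb$image_id[i], ]
    img <- get0(rec$path, envir = cache)
    if (is.null(img)) {
      img <- rgb_of(read_raster(rec$path))
      assign(rec$path, img, envir = cache)
    }
    crop_raster(img, nb[i, ])
  })
}
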