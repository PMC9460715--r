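# Procedural toy data: orchard-like images, component pools and detector
# outputs with the structural properties the pipeline assumes, so every
# stage is testable without any download. Rendering is deliberately flat
# (disks, rectangles, ellipses) — the pipeline's logic is geometric and
# count-based and never inspects apple appearance.

# pixel-center masks; shapes are drawn where mask is TRUE
mask_disk <- function(h, w, cx, cy, r) {
  yy <- matrix(seq_len(h) - 0.5, h, w)
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
mask_ellipse <- function(h, w, cx, cy, rx, ry) {
  yy <- matrix(seq_len(h) - 0.5, h, w)
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}
mask_rect <- function(h, w, x0, y0, x1, y1) {
  m <- matrix(FALSE, h, w)
  ys <- max(1, y0 + 1):min(h, y1); xs <- max(1, x0 + 1):min(w, x1)
  m[ys, xs] <- TRUE
  m
}
fill_mask <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]; plane[mask] <- rgb[ch]; img[, , ch] <- plane
  }
  img
}

FIXTURE_COLORS <- list(apple = c(0.80, 0.15, 0.10),
                       fruit = c(0.85, 0.35, 0.10),
                       branch = c(0.45, 0.30, 0.12),
                       leaf = c(0.15, 0.55, 0.15))

#' Fixture specification
#'
#' Describes a toy detection dataset: which (sub-dataset, class) cells exist
#' and how many annotation boxes each receives, plus rendering parameters.
#'
#' @param per_cell_counts data.frame with a \code{key} column (sub-dataset
#'   keys like "ZY_H") and one integer column per occlusion class.
#' @param image_size Side of the square toy images in pixels (default 256).
#' @param box_size Side of each annotation slot in pixels (default 40).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param illumination_means Named vector, mean background gray (0..255) per
#'   illumination (default high 160, low 40 — on either side of the default
#'   illumination threshold).
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(per_cell_counts, image_size = 256L, box_size = 40L,
                         seed = 1L,
                         illumination_means = c(high = 160, low = 40)) {
  cls <- occlusion_classes()
  miss <- setdiff(cls, names(per_cell_counts))
  for (m in miss) per_cell_counts[[m]] <- 0L
  stopifnot(all(per_cell_counts[cls] >= 0), image_size >= 2 * box_size)
  structure(list(per_cell_counts = per_cell_counts[c("key", cls)],
                 image_size = as.integer(image_size),
                 box_size = as.integer(box_size), seed = as.integer(seed),
                 illumination_means = illumination_means),
            class = "fixture_spec")
}

# draw one annotated apple of class cls inside slot (x0, y0, side)
draw_fixture_box <- function(img, x0, y0, side, cls) {
  cx <- x0 + side / 2; cy <- y0 + side / 2
  r <- side * 0.38
  h <- raster_height(img); w <- raster_width(img)
  img <- fill_mask(img, mask_disk(h, w, cx, cy, r), FIXTURE_COLORS$apple)
  code <- strsplit(cls, "")[[1]]
  if ("F" %in% code)
    img <- fill_mask(img, mask_disk(h, w, cx - r * 0.8, cy - r * 0.6,
                                    r * 0.7), FIXTURE_COLORS$fruit)
  if ("B" %in% code)
    img <- fill_mask(img, mask_rect(h, w, round(x0), round(cy - side * 0.06),
                                    round(x0 + side), round(cy + side * 0.06)),
                     FIXTURE_COLORS$branch)
  if ("L" %in% code)
    img <- fill_mask(img, mask_ellipse(h, w, cx + r * 0.5, cy + r * 0.5,
                                       r * 0.75, r * 0.45),
                     FIXTURE_COLORS$leaf)
  img
}

#' Generate a toy annotated detection dataset
#'
#' Renders flat-shape orchard images so that each requested (sub-dataset,
#' class) cell receives exactly the requested number of annotation boxes:
#' disks for apples, rectangles for branches, ellipses for leaves, an offset
#' disk for an occluding fruit. Images, Pascal VOC XML and a manifest CSV
#' (with region and illumination) are written under \code{out_dir}.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param out_dir Output directory.
#' @return An \code{ob_dataset} whose recount reproduces the spec exactly.
#' @export
generate_fixture_dataset <- function(spec, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  cls_all <- occlusion_classes()
  sz <- spec$image_size; side <- spec$box_size
  margin <- 4L
  per_row <- (sz - margin) %/% (side + margin)
  slots <- per_row^2
  imgs <- list(); boxes <- list()
  img_counter <- 0L
  for (i in seq_len(nrow(spec$per_cell_counts))) {
    row <- spec$per_cell_counts[i, ]
    key <- row$key
    k <- parse_subdataset_key(key)
    gray <- spec$illumination_means[[k$illumination]] / 255
    # one flat list of class labels to draw for this sub-dataset
    todo <- rep(cls_all, times = as.integer(row[cls_all]))
    if (!length(todo)) next
    todo <- sample(todo)
    while (length(todo)) {
      img_counter <- img_counter + 1L
      image_id <- sprintf("%s_img_%04d", key, img_counter)
      take <- utils::head(todo, slots)
      todo <- utils::tail(todo, max(0, length(todo) - slots))
      img <- solid_raster(sz, sz, rgb = rep(gray, 3))
      img <- clamp01(img + array(stats::runif(sz * sz * 3, -0.03, 0.03),
                                 c(sz, sz, 3)))
      bx <- list()
      for (j in seq_along(take)) {
        sr <- (j - 1) %/% per_row; sc <- (j - 1) %% per_row
        x0 <- margin + sc * (side + margin)
        y0 <- margin + sr * (side + margin)
        img <- draw_fixture_box(img, x0, y0, side, take[j])
        bx[[j]] <- data.frame(image_id = image_id, cls = take[j],
                              xmin = x0, ymin = y0,
                              xmax = x0 + side, ymax = y0 + side)
      }
      path <- file.path(out_dir, "images", paste0(image_id, ".png"))
      write_raster(img, path)
      imgs[[image_id]] <- data.frame(image_id = image_id, path = path,
                                     width = sz, height = sz,
                                     region = k$region,
                                     illumination = k$illumination)
      boxes[[image_id]] <- do.call(rbind, bx)
    }
  }
  ds <- ob_dataset(do.call(rbind, imgs) %||%
                     data.frame(image_id = character(), path = character(),
                                width = numeric(), height = numeric(),
                                region = character()),
                   do.call(rbind, boxes), name = "fixture")
  write_voc(ds, file.path(out_dir, "labels_voc"))
  write_manifest(ds, file.path(out_dir, "manifest.csv"),
                 relative_to = out_dir)
  ds
}

# one procedurally drawn element on a transparent canvas
draw_fixture_element <- function(kind, size = 48L, jitter = 0) {
  h <- w <- size
  canvas <- solid_raster(h, w, rgb = c(0, 0, 0), alpha = 0)
  add <- function(canvas, mask, col) {
    canvas <- fill_mask(canvas, mask, col)
    a <- canvas[, , 4]; a[mask] <- 1; canvas[, , 4] <- a
    canvas
  }
  c0 <- size / 2 + jitter
  r <- size * 0.4
  shapes <- list(
    fruit = function(cv) add(cv, mask_disk(h, w, c0, c0, r),
                             FIXTURE_COLORS$fruit),
    branch = function(cv) add(cv, mask_rect(h, w, 0L, round(c0 - size * 0.1),
                                            w, round(c0 + size * 0.1)),
                              FIXTURE_COLORS$branch),
    leaf = function(cv) add(cv, mask_ellipse(h, w, c0, c0, r, r * 0.55),
                            FIXTURE_COLORS$leaf),
    composite = function(cv) {
      cv <- add(cv, mask_rect(h, w, 0L, round(c0 - size * 0.08), w,
                              round(c0 + size * 0.08)), FIXTURE_COLORS$branch)
      cv <- add(cv, mask_ellipse(h, w, c0 * 0.7, c0, r * 0.6, r * 0.35),
                FIXTURE_COLORS$leaf)
      add(cv, mask_disk(h, w, c0 * 1.3, c0 * 1.2, r * 0.45),
          FIXTURE_COLORS$fruit)
    })
  shapes[[kind]](canvas)
}

#' Generate a toy component pool
#'
#' Procedurally draws fruit (disk), branch (rectangle), leaf (ellipse) and
#' composite (union) elements with exact alpha masks, plus base images at
#' the two canonical sizes whose mean gray matches the spec's illumination
#' means (so they classify correctly under the default threshold).
#'
#' @param spec A \code{\link{fixture_spec}} (only seed, illumination_means
#'   are used).
#' @param out_dir Optional; when given, the pool is also written in the
#'   \code{<illumination>/<kind>/*.png} directory layout.
#' @param n_per_kind Elements per (kind, illumination) (default 3).
#' @param n_base Base images per illumination (default 2, one per canonical
#'   size).
#' @param element_size Element canvas side in pixels (default 48).
#' @return An \code{ob_pool}.
#' @export
generate_fixture_pool <- function(spec, out_dir = NULL, n_per_kind = 3L,
                                  n_base = 2L, element_size = 48L) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "fixture_pool"))
  elements <- list(); bases <- list()
  for (il in illumination_levels()) {
    for (kind in element_kinds()) {
      for (i in seq_len(n_per_kind)) {
        r <- draw_fixture_element(kind, size = element_size,
                                  jitter = (i - 1) %% 3 - 1)
        sid <- sprintf("%s_%s_%02d", il, kind, i)
        elements <- c(elements, list(ob_element(r, kind, il, source_id = sid)))
        if (!is.null(out_dir))
          write_raster(r, file.path(out_dir, il, kind, paste0(sid, ".png")))
      }
    }
    gray <- spec$illumination_means[[il]] / 255
    sizes <- base_image_sizes()
    for (i in seq_len(n_base)) {
      szb <- sizes[[(i - 1) %% 2 + 1]]
      r <- solid_raster(szb[2], szb[1], rgb = rep(gray, 3))
      r <- clamp01(r + array(stats::runif(prod(szb) * 3, -0.02, 0.02),
                             c(szb[2], szb[1], 3)))
      sid <- sprintf("%s_base_%02d", il, i)
      bases <- c(bases, list(list(raster = r, illumination = il,
                                  blurred = FALSE, source_id = sid)))
      if (!is.null(out_dir))
        write_raster(r, file.path(out_dir, il, "base", paste0(sid, ".png")))
    }
  }
  ob_pool(elements, bases)
}

#' Generate toy detector outputs of controllable quality
#'
#' Emits jittered, confidence-scored copies of the ground-truth boxes plus
#' spurious detections, so that expected AP rises monotonically with
#' \code{quality}: at \code{quality = 1} every box is an exact copy at
#' confidence 1 (a perfect detector); at \code{quality = 0} boxes are
#' essentially random.
#'
#' @param dataset An \code{ob_dataset}.
#' @param quality Detector quality in [0, 1].
#' @param seed Integer seed.
#' @return Detection data.frame (image_id, cls, confidence, box).
#' @export
generate_fixture_predictions <- function(dataset, quality, seed = 1L) {
  stopifnot(quality >= 0, quality <= 1)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  gt <- dataset$boxes
  imgs <- dataset$images
  preds <- list()
  for (i in seq_len(nrow(gt))) {
    if (stats::runif(1) > 0.3 + 0.7 * quality) next  # missed detection
    b <- gt[i, ]
    rec <- imgs[imgs$image_id == b$image_id, ]
    w <- b$xmax - b$xmin; h <- b$ymax - b$ymin
    jit <- (1 - quality) * 0.35
    dx <- stats::rnorm(1, 0, jit * w); dy <- stats::rnorm(1, 0, jit * h)
    conf <- if (quality == 1) 1 else
      min(1, max(0.01, quality + stats::rnorm(1, 0, 0.1) * (1 - quality)))
    nb <- data.frame(image_id = b$image_id, cls = b$cls, confidence = conf,
                     xmin = b$xmin + dx, ymin = b$ymin + dy,
                     xmax = b$xmax + dx, ymax = b$ymax + dy)
    nb <- clip_bbox(nb, rec$width, rec$height)
    if (nrow(nb)) preds[[length(preds) + 1]] <- nb
  }
  # spurious detections
  n_fp <- round((1 - quality) * nrow(gt))
  for (j in seq_len(n_fp)) {
    rec <- imgs[sample.int(nrow(imgs), 1L), ]
    s <- stats::runif(1, 10, max(12, min(rec$width, rec$height) / 3))
    x0 <- stats::runif(1, 0, rec$width - s)
    y0 <- stats::runif(1, 0, rec$height - s)
    preds[[length(preds) + 1]] <- data.frame(
      image_id = rec$image_id,
      cls = sample(occlusion_classes(), 1L),
      confidence = stats::runif(1, 0.01, max(0.31, 1 - quality)),
      xmin = x0, ymin = y0, xmax = x0 + s, ymax = y0 + s)
  }
  out <- do.call(rbind, preds) %||%
    data.frame(image_id = character(), cls = character(),
               confidence = numeric(), xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric())
  rownames(out) <- NULL
  out
}
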