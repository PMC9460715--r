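#' Read a Pascal VOC XML annotation directory
#'
#' One XML file per image is expected (object/name/bndbox layout). VOC boxes
#' are 1-based inclusive; they are converted to the package's 0-based
#' half-open convention on read, so a VOC box \code{(1, 1, 100, 100)} becomes
#' \code{(0, 0, 100, 100)}.
#'
#' @param annotation_dir Directory of \code{.xml} files.
#' @param image_dir Directory holding the images named in the files.
#' @param regions Region assignment: a single string applied to all images, a
#'   named character vector keyed by image_id, or a function of image_id.
#' @param on_invalid What to do with a box outside its image: \code{"reject"}
#'   (error, default) or \code{"clip"} to the image.
#' @param name Dataset name.
#' @return An \code{ob_dataset}.
#' @export
read_voc <- function(annotation_dir, image_dir = annotation_dir,
                     regions = "unknown", on_invalid = c("reject", "clip"),
                     name = basename(annotation_dir)) {
  on_invalid <- match.arg(on_invalid)
  files <- sort(list.files(annotation_dir, pattern = "\\.xml$", full.names = TRUE))
  imgs <- list(); boxes <- list()
  for (f in files) {
    doc <- xml2::read_xml(f)
    fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
    image_id <- tools::file_path_sans_ext(basename(f))
    w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
    h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
    if (is.na(w) || is.na(h)) {
      r <- read_raster(file.path(image_dir, fname))
      w <- raster_width(r); h <- raster_height(r)
    }
    region <- if (is.function(regions)) regions(image_id)
      else if (length(regions) > 1L || !is.null(names(regions)))
        unname(regions[[image_id]])
      else regions
    objs <- xml2::xml_find_all(doc, "./object")
    if (length(objs)) {
      cls <- xml2::xml_text(xml2::xml_find_all(objs, "./name"))
      bad <- setdiff(unique(cls), occlusion_classes())
      if (length(bad))
        stop("unknown class '", bad[1], "' in ", f, call. = FALSE)
      num <- function(tag) as.numeric(xml2::xml_text(
        xml2::xml_find_all(objs, paste0("./bndbox/", tag))))
      b <- data.frame(image_id = image_id, cls = cls,
                      xmin = num("xmin") - 1, ymin = num("ymin") - 1,
                      xmax = num("xmax"), ymax = num("ymax"))
      oob <- b$xmin < 0 | b$ymin < 0 | b$xmax > w | b$ymax > h |
        b$xmin >= b$xmax | b$ymin >= b$ymax
      if (any(oob)) {
        if (on_invalid == "reject")
          stop("box outside image bounds in ", f, call. = FALSE)
        b <- clip_bbox(b, w, h)
      }
      boxes[[image_id]] <- b
    }
    imgs[[image_id]] <- data.frame(
      image_id = image_id, path = file.path(image_dir, fname),
      width = w, height = h, region = region %||% "unknown")
  }
  ob_dataset(do.call(rbind, imgs) %||% data.frame(),
             do.call(rbind, boxes), name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset as Pascal VOC XML files
#'
#' Writes one XML per image record (images with no boxes still get a file),
#' converting internal 0-based half-open boxes back to VOC's 1-based
#' inclusive convention so \code{read_voc(write_voc(d))} reproduces \code{d}'s
#' annotations exactly.
#'
#' @param dataset An \code{ob_dataset}.
#' @param out_dir Output directory (created if missing).
#' @return Number of files written, invisibly.
#' @export
write_voc <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset$images))) {
    rec <- dataset$images[i, ]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", basename(rec$path))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", format(rec$width))
    xml2::xml_add_child(size, "height", format(rec$height))
    xml2::xml_add_child(size, "depth", "3")
    b <- dataset$boxes[dataset$boxes$image_id == rec$image_id, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", b$cls[j])
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(b$xmin[j] + 1))
      xml2::xml_add_child(bb, "ymin", format(b$ymin[j] + 1))
      xml2::xml_add_child(bb, "xmax", format(b$xmax[j]))
      xml2::xml_add_child(bb, "ymax", format(b$ymax[j]))
    }
    xml2::write_xml(doc, file.path(out_dir, paste0(rec$image_id, ".xml")))
  }
  invisible(nrow(dataset$images))
}

#' Write a dataset as YOLO txt label files
#'
#' One text file per image; each line is
#' \code{"<class_index_0based> <cx> <cy> <w> <h>"} with box center and size
#' normalized to [0,1] by the image dimensions. The class index follows
#' \code{\link{occlusion_classes}} order.
#'
#' @param dataset An \code{ob_dataset}.
#' @param out_dir Output directory.
#' @return Number of files written, invisibly.
#' @export
write_yolo <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(dataset$images) && any(dataset$images$width <= 0 |
                                  dataset$images$height <= 0))
    stop("zero-size image", call. = FALSE)
  for (i in seq_len(nrow(dataset$images))) {
    rec <- dataset$images[i, ]
    b <- dataset$boxes[dataset$boxes$image_id == rec$image_id, , drop = FALSE]
    lines <- character(0)
    if (nrow(b)) {
      cx <- (b$xmin + b$xmax) / 2 / rec$width
      cy <- (b$ymin + b$ymax) / 2 / rec$height
      w <- (b$xmax - b$xmin) / rec$width
      h <- (b$ymax - b$ymin) / rec$height
      lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                       occlusion_class_index(b$cls) - 1L, cx, cy, w, h)
    }
    writeLines(lines, file.path(out_dir, paste0(rec$image_id, ".txt")))
  }
  invisible(nrow(dataset$images))
}

#' Read YOLO txt label files
#'
#' The inverse of \code{\link{write_yolo}}. Image dimensions are not stored
#' in YOLO files, so an \code{images} table (as in an \code{ob_dataset}) must
#' be supplied; pixel boxes are recovered within 0.5 px of the originals.
#'
#' @param label_dir Directory of \code{.txt} files named by image_id.
#' @param images data.frame with image_id, path, width, height, region.
#' @param name Dataset name.
#' @return An \code{ob_dataset}.
#' @export
read_yolo <- function(label_dir, images, name = basename(label_dir)) {
  boxes <- list()
  for (i in seq_len(nrow(images))) {
    rec <- images[i, ]
    f <- file.path(label_dir, paste0(rec$image_id, ".txt"))
    if (!file.exists(f)) next
    lines <- readLines(f)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) next
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    boxes[[rec$image_id]] <- data.frame(
      image_id = rec$image_id,
      cls = occlusion_classes()[m[, 1] + 1],
      xmin = (m[, 2] - m[, 4] / 2) * rec$width,
      ymin = (m[, 3] - m[, 5] / 2) * rec$height,
      xmax = (m[, 2] + m[, 4] / 2) * rec$width,
      ymax = (m[, 3] + m[, 5] / 2) * rec$height)
  }
  b <- do.call(rbind, boxes)
  if (!is.null(b)) {
    i <- match(b$image_id, images$image_id)
    b <- clip_bbox(b, images$width[i], images$height[i])
  }
  ob_dataset(images, b, name = name)
}

#' Write a dataset manifest CSV
#'
#' Columns: image_id, path, region and, when known, illumination.
#'
#' @param dataset An \code{ob_dataset}.
#' @param path Output CSV path.
#' @param relative_to Optional directory; image paths are written relative
#'   to it, keeping the manifest portable across output roots.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(dataset, path, relative_to = NULL) {
  cols <- intersect(c("image_id", "path", "region", "illumination"),
                    names(dataset$images))
  m <- dataset$images[cols]
  if (!is.null(relative_to) && nrow(m) > 0)
    m$path <- sub(paste0("^", normalizePath(relative_to, mustWork = FALSE),
                         "/?"), "", normalizePath(m$path, mustWork = FALSE))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
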