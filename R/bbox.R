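#' Bounding boxes
#'
#' Boxes are stored 0-based and half-open: a box covers pixel columns
#' \code{xmin .. xmax-1} and rows \code{ymin .. ymax-1}, so its width is
#' \code{xmax - xmin} exactly. Pascal VOC's 1-based inclusive convention is
#' converted at the file boundary by the VOC reader/writer.
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of pixel coordinates.
#' @return A data.frame with columns xmin, ymin, xmax, ymax.
#' @export
#' @examples
#' bbox(0, 0, 100, 50)
bbox <- function(xmin, ymin, xmax, ymax) {
  b <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_bbox(b)
  b
}

validate_bbox <- function(b, width = NULL, height = NULL, where = "") {
  bad <- b$xmin < 0 | b$ymin < 0 | b$xmin >= b$xmax | b$ymin >= b$ymax
  if (!is.null(width))  bad <- bad | b$xmax > width
  if (!is.null(height)) bad <- bad | b$ymax > height
  if (any(bad))
    stop("invalid bounding box", if (nzchar(where)) paste0(" in ", where),
         ": row ", which(bad)[1], call. = FALSE)
  invisible(b)
}

# clip boxes to [0,width)x[0,height); drops boxes that collapse to zero area
clip_bbox <- function(b, width, height) {
  b$xmin <- pmax(b$xmin, 0); b$ymin <- pmax(b$ymin, 0)
  b$xmax <- pmin(b$xmax, width); b$ymax <- pmin(b$ymax, height)
  b[b$xmin < b$xmax & b$ymin < b$ymax, , drop = FALSE]
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Single-row box data.frames (or lists) with xmin/ymin/xmax/ymax.
#' @return IoU in [0, 1].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
  iy <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
  inter <- ix * iy
  if (inter == 0) return(0)
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (area_a + area_b - inter)
}

bbox_area <- function(b) (b$xmax - b$xmin) * (b$ymax - b$ymin)
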