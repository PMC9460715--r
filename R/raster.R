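# Raster helpers.
#
# Internal raster convention: numeric array dim c(height, width, channels),
# values in [0,1], channels RGB or RGBA — the layout png::readPNG returns.
# EBImage (width-major) is used for resampling and blurring via adapters.

raster_height <- function(img) dim(img)[1]
raster_width <- function(img) dim(img)[2]
raster_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3] else 1L

# promote gray / drop-dim inputs to h x w x nc
as_raster_array <- function(img, channels = 3L) {
  if (is.null(dim(img))) stop("not a raster", call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, channels), c(dim(img), channels))
  if (dim(img)[3] < channels) {
    extra <- array(1, c(dim(img)[1:2], channels - dim(img)[3]))
    img <- abind_channels(img, extra)
  }
  img
}

abind_channels <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

rgb_of <- function(img) as_raster_array(img, 3L)[, , 1:3, drop = FALSE]

alpha_of <- function(img) {
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img[, , 4] else
    matrix(1, raster_height(img), raster_width(img))
}

#' Read an image file as a raster array
#'
#' @param path PNG or JPEG file.
#' @return Numeric array, height x width x channels, values in [0,1].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    img <- from_ebimage(eb)
  }
  as_raster_array(img, if (length(dim(img)) == 3L && dim(img)[3] == 4L) 4L else 3L)
}

#' Write a raster array to a PNG file
#'
#' @param img Raster array (h x w x 3 or 4, values in [0,1]).
#' @param path Output path; directories are created.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clamp01(img), path)
  invisible(path)
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

# EBImage stores width-major (x, y, c)
to_ebimage <- function(img) {
  img <- as_raster_array(img, raster_channels(img))
  EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
}
from_ebimage <- function(eb) {
  a <- EBImage::imageData(eb)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  aperm(a, c(2, 1, 3))
}

# bilinear resize to h x w via EBImage
resize_raster <- function(img, height, width) {
  if (raster_height(img) == height && raster_width(img) == width) return(img)
  out <- from_ebimage(EBImage::resize(to_ebimage(img), w = width, h = height))
  clamp01(out)
}

blur_raster <- function(img, sigma = 2.0) {
  clamp01(from_ebimage(EBImage::gblur(to_ebimage(img), sigma = sigma)))
}

# crop by a 0-based half-open box
crop_raster <- function(img, box) {
  img[(box$ymin + 1):box$ymax, (box$xmin + 1):box$xmax, , drop = FALSE]
}

# paste fg (RGB or RGBA) onto bg at 0-based (x, y); alpha-composited.
# Alpha is binarized at 0.5 (mask semantics, no feathering).
paste_raster <- function(bg, fg, x, y, binarize_alpha = TRUE) {
  h <- raster_height(fg); w <- raster_width(fg)
  stopifnot(x >= 0, y >= 0,
            x + w <= raster_width(bg), y + h <= raster_height(bg))
  a <- alpha_of(fg)
  if (binarize_alpha) a <- (a >= 0.5) * 1
  rows <- (y + 1):(y + h); cols <- (x + 1):(x + w)
  fg_rgb <- rgb_of(fg)
  for (ch in 1:3) {
    bg[rows, cols, ch] <- fg_rgb[, , ch] * a + bg[rows, cols, ch] * (1 - a)
  }
  bg
}

#' Mean luma of an RGB raster
#'
#' Rec.601 weighted mean luminance on the 0..255 scale:
#' \code{0.299 R + 0.587 G + 0.114 B}.
#'
#' @param img Raster array with at least 3 channels.
#' @return Mean luma in [0, 255].
#' @export
mean_luma <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("mean_luma expects an RGB raster", call. = FALSE)
  255 * mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

# flat-color raster constructor (used by fixtures and tests)
solid_raster <- function(height, width, rgb = c(0.5, 0.5, 0.5), alpha = NULL) {
  nc <- if (is.null(alpha)) 3L else 4L
  img <- array(0, c(height, width, nc))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  if (!is.null(alpha)) img[, , 4] <- alpha
  img
}
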