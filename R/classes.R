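#' The eight occlusion classes
#'
#' An apple annotation carries one of eight occlusion labels describing what
#' hides the fruit: \code{N} (no occlusion), \code{L} (leaf), \code{F} (fruit),
#' \code{B} (branch), and the fused combinations \code{LF}, \code{BL},
#' \code{BF}, \code{BLF}. The order of the returned vector fixes the class
#' index 1..8 used for YOLO label files (zero-based there) and for the eight
#' per-class terms averaged by the mAP.
#'
#' @return Character vector of the eight class codes, in index order.
#' @export
#' @examples
#' occlusion_classes()
#' occlusion_class_index("BLF")
occlusion_classes <- function() {
  c("N", "L", "F", "B", "LF", "BL", "BF", "BLF")
}

#' @rdname occlusion_classes
#' @param code Character vector of class codes.
#' @return \code{occlusion_class_index}: integer index 1..8 of each code.
#' @export
occlusion_class_index <- function(code) {
  idx <- match(code, occlusion_classes())
  if (anyNA(idx)) {
    bad <- unique(code[is.na(idx)])
    stop("unknown occlusion class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

#' Illumination labels
#'
#' Images are partitioned into two illumination conditions: \code{"high"}
#' (sufficient daytime light) and \code{"low"} (backlight, evening, or
#' artificial night lighting).
#'
#' @return Character vector \code{c("high", "low")}.
#' @export
illumination_levels <- function() c("high", "low")

assert_illumination <- function(x) {
  if (!is.character(x) || length(x) != 1L || !x %in% illumination_levels())
    stop("illumination must be one of ",
         paste(illumination_levels(), collapse = "/"), call. = FALSE)
  x
}

#' Sub-dataset keys
#'
#' A sub-dataset is the slice of a detection dataset for one (region,
#' illumination) pair. Keys are formatted \code{"<REGION>_H"} /
#' \code{"<REGION>_L"}, e.g. \code{"ZY_H"} for the Zhaoyuan high-illumination
#' slice.
#'
#' @param region Region identifier string (e.g. \code{"ZY"}).
#' @param illumination \code{"high"} or \code{"low"}.
#' @return The key string.
#' @export
#' @examples
#' subdataset_key("ZY", "high")
#' parse_subdataset_key("PSR_L")
subdataset_key <- function(region, illumination) {
  illumination <- match.arg(illumination, illumination_levels())
  paste0(region, "_", if (illumination == "high") "H" else "L")
}

#' @rdname subdataset_key
#' @param key A key string as produced by \code{subdataset_key}.
#' @return \code{parse_subdataset_key}: list with \code{region} and
#'   \code{illumination}.
#' @export
parse_subdataset_key <- function(key) {
  if (!grepl("_[HL]$", key)) stop("malformed sub-dataset key: ", key, call. = FALSE)
  list(region = sub("_[HL]$", "", key),
       illumination = if (endsWith(key, "_H")) "high" else "low")
}
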