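#' Detection dataset container
#'
#' An \code{ob_dataset} holds a detection dataset in two aligned tables:
#' \code{images} (one row per image: \code{image_id}, \code{path},
#' \code{width}, \code{height}, \code{region}, and optionally
#' \code{illumination}) and \code{boxes} (one row per annotation box:
#' \code{image_id}, \code{cls}, \code{xmin}, \code{ymin}, \code{xmax},
#' \code{ymax}; coordinates 0-based half-open). Every box must name a known
#' image, carry one of the eight occlusion classes, and lie within its image.
#'
#' @param images data.frame of image records.
#' @param boxes data.frame of annotation boxes (may have zero rows).
#' @param name Dataset name.
#' @return An object of class \code{ob_dataset}.
#' @export
ob_dataset <- function(images, boxes = NULL, name = "dataset") {
  if (is.null(boxes))
    boxes <- data.frame(image_id = character(), cls = character(),
                        xmin = numeric(), ymin = numeric(),
                        xmax = numeric(), ymax = numeric())
  images <- as.data.frame(images, stringsAsFactors = FALSE)
  boxes <- as.data.frame(boxes, stringsAsFactors = FALSE)
  if (nrow(images) > 0) {
    need <- c("image_id", "path", "width", "height", "region")
    miss <- setdiff(need, names(images))
    if (length(miss)) stop("images lacks columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    if (anyDuplicated(images$image_id))
      stop("duplicate image_id in dataset", call. = FALSE)
    if (any(images$width <= 0 | images$height <= 0))
      stop("image with non-positive size", call. = FALSE)
  }
  if (nrow(boxes) > 0) {
    occlusion_class_index(boxes$cls)  # validates class codes
    unknown <- setdiff(boxes$image_id, images$image_id)
    if (length(unknown))
      stop("boxes reference unknown image_id: ", unknown[1], call. = FALSE)
    i <- match(boxes$image_id, images$image_id)
    validate_bbox(boxes, width = images$width[i], height = images$height[i],
                  where = "dataset boxes")
  }
  structure(list(images = images, boxes = boxes, name = name),
            class = "ob_dataset")
}

#' @export
print.ob_dataset <- function(x, ...) {
  cat("<ob_dataset>", x$name, "--", nrow(x$images), "images,",
      nrow(x$boxes), "boxes\n")
  if (nrow(x$boxes)) {
    tab <- table(factor(x$boxes$cls, levels = occlusion_classes()))
    print(tab)
  }
  invisible(x)
}

#' Number of images in a dataset
#' @param dataset An \code{ob_dataset}.
#' @return Integer count.
#' @export
n_images <- function(dataset) nrow(dataset$images)

#' Number of annotation boxes in a dataset
#' @param dataset An \code{ob_dataset}.
#' @return Integer count.
#' @export
n_boxes <- function(dataset) nrow(dataset$boxes)

# subset a dataset to a set of image ids, keeping boxes aligned
dataset_subset <- function(dataset, image_ids, name = dataset$name) {
  ob_dataset(dataset$images[dataset$images$image_id %in% image_ids, , drop = FALSE],
             dataset$boxes[dataset$boxes$image_id %in% image_ids, , drop = FALSE],
             name = name)
}

# concatenate datasets; image ids must stay unique
dataset_bind <- function(..., name = "combined") {
  ds <- list(...)
  ds <- ds[vapply(ds, Negate(is.null), logical(1))]
  imgs <- do.call(rbind, lapply(ds, function(d) {
    im <- d$images
    if (!"illumination" %in% names(im))
      im[["illumination"]] <- rep(NA_character_, nrow(im))
    im[c("image_id", "path", "width", "height", "region", "illumination")]
  }))
  boxes <- do.call(rbind, lapply(ds, function(d)
    d$boxes[c("image_id", "cls", "xmin", "ymin", "xmax", "ymax")]))
  ob_dataset(imgs, boxes, name = name)
}

#' Deterministic train/test split
#'
#' Partitions a dataset by image with a seeded uniform shuffle. The test set
#' size is \code{round-half-up(test_fraction * n_images)}; the canonical 3:7
#' test:train split of the occlusion dataset corresponds to
#' \code{test_fraction = 0.3}.
#'
#' @param dataset An \code{ob_dataset}.
#' @param test_fraction Fraction of images assigned to the test set, in (0,1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with elements \code{train} and \code{test}, both
#'   \code{ob_dataset}s, disjoint by image and jointly covering the input.
#' @export
#' @examples
#' d <- ob_dataset(data.frame(image_id = paste0("i", 1:10), path = "",
#'                            width = 10, height = 10, region = "ZY"))
#' s <- split_train_test(d, 0.3, seed = 1)
#' c(n_images(s$train), n_images(s$test))
split_train_test <- function(dataset, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- dataset$images$image_id
  n <- length(ids)
  if (n == 0)
    return(list(train = dataset_subset(dataset, character(), name = "train"),
                test = dataset_subset(dataset, character(), name = "test")))
  n_test <- floor(test_fraction * n + 0.5)  # round half up
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(ids, n)
  test_ids <- shuffled[seq_len(n_test)]
  list(train = dataset_subset(dataset, setdiff(ids, test_ids), name = "train"),
       test = dataset_subset(dataset, test_ids, name = "test"))
}

# save/restore the global RNG state so seeded helpers don't clobber callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Derive a module seed from a master seed
#'
#' All pipeline randomness flows from one master seed; per-stage seeds are
#' derived by hashing the stage label so stages are independently
#' reproducible.
#'
#' @param master Integer master seed.
#' @param label Stage label string.
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(master) * 48271 + h * 7919) %% 2147483647)
}
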