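#' Count annotation boxes per (sub-dataset, class) cell
#'
#' Builds the per-(region, illumination) class-count table from a partition
#' as returned by \code{\link{partition_by_illumination}}: one row per
#' sub-dataset key, columns for the image count, the total box count and each
#' of the eight occlusion classes.
#'
#' @param partition Named list of \code{ob_dataset}s keyed by sub-dataset key.
#' @return An \code{ob_count_table} (data.frame with columns \code{key},
#'   \code{n_images}, \code{total}, then one column per class).
#' @export
count_boxes <- function(partition) {
  cls <- occlusion_classes()
  rows <- lapply(names(partition), function(k) {
    d <- partition[[k]]
    tab <- table(factor(d$boxes$cls, levels = cls))
    out <- data.frame(key = k, n_images = nrow(d$images),
                      total = nrow(d$boxes))
    out[cls] <- as.integer(tab)
    out
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    out <- data.frame(key = character(), n_images = integer(),
                      total = integer())
    for (cc in cls) out[[cc]] <- integer(0)
    out
  }
  structure(tab, class = c("ob_count_table", "data.frame"))
}

#' @export
print.ob_count_table <- function(x, ...) {
  cat("<ob_count_table>", nrow(x), "sub-datasets\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read / write a class-count table as CSV
#'
#' The CSV has one row per sub-dataset and columns
#' \code{key,n_images,total,N,L,F,B,LF,BL,BF,BLF}.
#'
#' @param path CSV path.
#' @return \code{read_count_table}: an \code{ob_count_table}.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "n_images", "total", occlusion_classes())
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- tab$total != rowSums(tab[occlusion_classes()])
  if (any(bad))
    stop("row total != sum of class counts for key ", tab$key[bad][1],
         call. = FALSE)
  structure(tab[need], class = c("ob_count_table", "data.frame"))
}

#' @rdname read_count_table
#' @param table An \code{ob_count_table}.
#' @export
write_count_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Class-imbalance report
#'
#' Summarizes how skewed the class counts are: per-class totals and
#' percentage shares (one decimal, half-up), the ratio of the largest to the
#' smallest nonzero class total, and the ratio of the largest to the smallest
#' nonzero cell within the retained sub-datasets (those with at least
#' \code{min_boxes_to_retain} boxes). Ratios are reported both exactly and
#' truncated to an integer, the form usually quoted ("16 times", "195
#' times").
#'
#' @param table An \code{ob_count_table}.
#' @param min_boxes_to_retain Sub-datasets with fewer total boxes are
#'   excluded from the within-retained cell ratio (default 1000).
#' @return List with \code{class_totals}, \code{grand_total},
#'   \code{class_share} (percent), \code{ratio_class} and
#'   \code{ratio_retained_cell} (each a list with \code{exact} and
#'   \code{floor}), \code{retained_keys}, and \code{degenerate} flag.
#' @export
imbalance_report <- function(table, min_boxes_to_retain = 1000) {
  cls <- occlusion_classes()
  totals <- colSums(table[cls])
  grand <- sum(totals)
  if (grand == 0)
    return(list(class_totals = totals, grand_total = 0, class_share = NULL,
                ratio_class = NULL, ratio_retained_cell = NULL,
                retained_keys = character(), degenerate = TRUE))
  share <- round_half_up(100 * totals / grand, 1)
  nz <- totals[totals > 0]
  ratio_class <- list(exact = max(nz) / min(nz),
                      floor = floor(max(nz) / min(nz)))
  retained <- table$key[table$total >= min_boxes_to_retain]
  cells <- as.matrix(table[table$key %in% retained, cls, drop = FALSE])
  nzc <- cells[cells > 0]
  ratio_cell <- if (length(nzc))
    list(exact = max(nzc) / min(nzc), floor = floor(max(nzc) / min(nzc)))
  else NULL
  list(class_totals = totals, grand_total = grand, class_share = share,
       ratio_class = ratio_class, ratio_retained_cell = ratio_cell,
       retained_keys = retained, degenerate = FALSE)
}

#' Plan per-cell synthesis deficits toward a balance target
#'
#' Sub-datasets with fewer than \code{min_boxes_to_retain} boxes in total are
#' skipped (too little material to balance); among the retained sub-datasets
#' the balance target defaults to the largest single (key, class) cell count,
#' and every retained cell's deficit is \code{target - count} — the number of
#' instances to synthesize so that all retained cells end up equal.
#'
#' @param table An \code{ob_count_table}.
#' @param min_boxes_to_retain Minimum total boxes for a sub-dataset to be
#'   balanced (default 1000).
#' @param target Optional explicit target; must be at least the largest
#'   retained cell count. Default: that largest count.
#' @return An \code{ob_balance_plan}: list with \code{target},
#'   \code{retained_keys}, \code{skipped_keys}, and \code{deficits} (matrix,
#'   retained keys x 8 classes).
#' @export
make_balance_plan <- function(table, min_boxes_to_retain = 1000,
                              target = NULL) {
  cls <- occlusion_classes()
  retained <- table$key[table$total >= min_boxes_to_retain]
  skipped <- setdiff(table$key, retained)
  if (!length(retained))
    stop("no sub-dataset reaches min_boxes_to_retain = ",
         min_boxes_to_retain, call. = FALSE)
  cells <- as.matrix(table[match(retained, table$key), cls, drop = FALSE])
  rownames(cells) <- retained
  if (is.null(target)) target <- max(cells)
  if (target < max(cells))
    stop("target ", target, " is below the largest retained cell count ",
         max(cells), call. = FALSE)
  deficits <- target - cells
  structure(list(target = as.integer(target),
                 retained_keys = retained, skipped_keys = skipped,
                 counts = cells, deficits = deficits),
            class = "ob_balance_plan")
}

#' @export
print.ob_balance_plan <- function(x, ...) {
  cat("<ob_balance_plan> target", x$target, "per cell\n")
  cat("  retained:", paste(x$retained_keys, collapse = ", "), "\n")
  if (length(x$skipped_keys))
    cat("  skipped: ", paste(x$skipped_keys, collapse = ", "), "\n")
  cat("  deficits (to synthesize):\n")
  print(cbind(x$deficits, total = rowSums(x$deficits)))
  invisible(x)
}

#' Write / read a balance plan as JSON
#'
#' @param plan An \code{ob_balance_plan}.
#' @param path JSON path.
#' @return \code{read_balance_plan}: the plan.
#' @export
write_balance_plan <- function(plan, path) {
  x <- list(target = plan$target, retained_keys = plan$retained_keys,
            skipped_keys = plan$skipped_keys,
            counts = as.data.frame(cbind(key = rownames(plan$counts),
                                         as.data.frame(plan$counts))),
            deficits = as.data.frame(cbind(key = rownames(plan$deficits),
                                           as.data.frame(plan$deficits))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_balance_plan
#' @export
read_balance_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- occlusion_classes()
  counts <- as.matrix(x$counts[cls]); rownames(counts) <- x$counts$key
  deficits <- as.matrix(x$deficits[cls]); rownames(deficits) <- x$deficits$key
  structure(list(target = as.integer(x$target),
                 retained_keys = x$retained_keys,
                 skipped_keys = x$skipped_keys %||% character(),
                 counts = counts, deficits = deficits),
            class = "ob_balance_plan")
}
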