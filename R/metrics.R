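# Detection evaluation: greedy IoU matching, precision/recall, VOC-style
# per-class AP and the eight-class mAP (factor 0.125).

#' Match predictions to ground truth per class
#'
#' Within each class and image, predictions are taken in order of decreasing
#' confidence and each is matched greedily to the still-unmatched
#' ground-truth box of the same class with the highest IoU, provided that
#' IoU reaches \code{iou_threshold}. Matched predictions are true positives,
#' the rest false positives; unmatched ground truth boxes are false
#' negatives.
#'
#' @param gt data.frame of ground-truth boxes (image_id, cls, xmin, ymin,
#'   xmax, ymax), e.g. an \code{ob_dataset}'s \code{boxes} table.
#' @param preds data.frame of detections (image_id, cls, confidence, xmin,
#'   ymin, xmax, ymax).
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return List per class: \code{counts} (TP, FP, FN) and \code{flags} (the
#'   class's predictions sorted by decreasing confidence with a logical
#'   \code{tp} column), plus \code{n_gt}.
#' @export
match_detections <- function(gt, preds, iou_threshold = 0.5) {
  out <- list()
  for (cls in occlusion_classes()) {
    g <- gt[gt$cls == cls, , drop = FALSE]
    p <- preds[preds$cls == cls, , drop = FALSE]
    p <- p[order(-p$confidence), , drop = FALSE]
    tp <- logical(nrow(p))
    used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(p))) {
      cand <- which(!used & g$image_id == p$image_id[i])
      if (!length(cand)) next
      ious <- vapply(cand, function(j) bbox_iou(p[i, ], g[j, ]), numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        tp[i] <- TRUE
        used[cand[best]] <- TRUE
      }
    }
    p$tp <- tp
    out[[cls]] <- list(
      counts = list(TP = sum(tp), FP = sum(!tp), FN = nrow(g) - sum(tp)),
      flags = p, n_gt = nrow(g))
  }
  out
}

#' Precision and recall from match counts
#'
#' \code{P = TP / (TP + FP)} and \code{R = TP / (TP + FN)}. A zero
#' denominator yields 0 with attribute \code{undefined = TRUE} so empty
#' classes do not crash aggregate reports.
#'
#' @param counts List with TP, FP, FN.
#' @return Named numeric c(P =, R =), possibly flagged.
#' @export
#' @examples
#' precision_recall(list(TP = 8, FP = 2, FN = 2))  # P = R = 0.8
precision_recall <- function(counts) {
  undef <- FALSE
  P <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
  else { undef <- TRUE; 0 }
  R <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
  else { undef <- TRUE; 0 }
  out <- c(P = P, R = R)
  if (undef) attr(out, "undefined") <- TRUE
  out
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence ranking of the class's predictions (as matched by
#' \code{\link{match_detections}}), accumulating TP/FP to one
#' (recall, precision) point per prediction.
#'
#' @param flags Prediction table with a \code{tp} column, sorted by
#'   decreasing confidence.
#' @param n_gt Number of ground-truth boxes of the class.
#' @return data.frame with columns \code{recall}, \code{precision}.
#' @export
pr_curve <- function(flags, n_gt) {
  if (nrow(flags) == 0 || n_gt == 0)
    return(data.frame(recall = numeric(), precision = numeric()))
  ctp <- cumsum(flags$tp); cfp <- cumsum(!flags$tp)
  data.frame(recall = ctp / n_gt, precision = ctp / (ctp + cfp))
}

#' Average precision (area under the PR envelope)
#'
#' Integrates precision over recall. The default \code{"all"} method uses
#' all-point interpolation: precision is replaced by its running maximum
#' from the right (the envelope) and summed over every recall increment.
#' \code{"11point"} averages the envelope at recalls 0, 0.1, ..., 1.
#'
#' @param curve data.frame with recall and precision columns (recall
#'   non-decreasing).
#' @param method "all" (default) or "11point".
#' @return AP in [0, 1].
#' @export
#' @examples
#' average_precision(data.frame(recall = 0.5, precision = 1.0))  # 0.5
average_precision <- function(curve, method = c("all", "11point")) {
  method <- match.arg(method)
  if (nrow(curve) == 0) return(0)
  r <- c(0, curve$recall)
  p <- c(0, curve$precision)
  env <- rev(cummax(rev(p)))
  if (method == "all") {
    sum(diff(r) * env[-1])
  } else {
    pts <- seq(0, 1, by = 0.1)
    mean(vapply(pts, function(t) {
      ok <- curve$recall >= t
      if (any(ok)) max(env[-1][ok]) else 0
    }, numeric(1)))
  }
}

#' Eight-class mean average precision
#'
#' \code{mAP = 0.125 * sum(AP)} over the eight occlusion classes, i.e. their
#' arithmetic mean.
#'
#' @param per_class_ap Numeric vector of exactly 8 per-class AP values.
#' @return mAP in [0, 1].
#' @export
mean_average_precision <- function(per_class_ap) {
  if (length(per_class_ap) != 8L)
    stop("mAP is defined over exactly 8 per-class AP values", call. = FALSE)
  0.125 * sum(per_class_ap)
}

#' Evaluate detections against a dataset
#'
#' Produces one metrics row: aggregate precision and recall at a confidence
#' cutoff, per-class AP at the given IoU threshold, and the eight-class mAP.
#' (Aggregate P/R depend on a score cutoff because TP/FP counts do; the
#' cutoff is explicit and configurable.)
#'
#' @param dataset An \code{ob_dataset} (ground truth).
#' @param preds Detection data.frame (image_id, cls, confidence, box).
#' @param iou_threshold IoU threshold (default 0.5).
#' @param conf_threshold Confidence cutoff for aggregate P/R (default 0.5).
#' @param method AP interpolation method.
#' @return One-row data.frame: P, R, mAP, and AP_<class> for each class.
#' @export
evaluate_detections <- function(dataset, preds, iou_threshold = 0.5,
                                conf_threshold = 0.5, method = "all") {
  gt <- dataset$boxes
  m_all <- match_detections(gt, preds, iou_threshold)
  ap <- vapply(occlusion_classes(), function(cls) {
    average_precision(pr_curve(m_all[[cls]]$flags, m_all[[cls]]$n_gt),
                      method = method)
  }, numeric(1))
  kept <- preds[preds$confidence >= conf_threshold, , drop = FALSE]
  m_cut <- match_detections(gt, kept, iou_threshold)
  tot <- list(TP = sum(vapply(m_cut, function(x) x$counts$TP, numeric(1))),
              FP = sum(vapply(m_cut, function(x) x$counts$FP, numeric(1))),
              FN = sum(vapply(m_cut, function(x) x$counts$FN, numeric(1))))
  pr <- precision_recall(tot)
  row <- data.frame(P = pr[["P"]], R = pr[["R"]],
                    mAP = mean_average_precision(ap))
  row[paste0("AP_", occlusion_classes())] <- as.list(ap)
  row
}

#' Read detections from a CSV or JSON-lines file
#'
#' Columns/fields: image_id, cls, confidence, xmin, ymin, xmax, ymax.
#'
#' @param path File path (.csv or .jsonl/.json).
#' @return Detection data.frame.
#' @export
read_detections <- function(path) {
  ext <- tolower(tools::file_ext(path))
  d <- if (ext == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::stream_in(file(path), verbose = FALSE)
  need <- c("image_id", "cls", "confidence", "xmin", "ymin", "xmax", "ymax")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detections lack fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(d$confidence >= 0 & d$confidence <= 1))
  d[need]
}
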