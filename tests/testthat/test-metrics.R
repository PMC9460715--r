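test_that("greedy matching handles perfect, empty and partial detectors", {
  gt <- data.frame(image_id = "a", cls = "N",
                   xmin = c(0, 20, 40), ymin = 0,
                   xmax = c(10, 30, 50), ymax = 10)
  perfect <- cbind(gt, confidence = 1)
  m <- match_detections(gt, perfect)
  expect_equal(m$N$counts, list(TP = 3, FP = 0, FN = 0))
  none <- perfect[0, ]
  m0 <- match_detections(gt, none)
  expect_equal(m0$N$counts, list(TP = 0, FP = 0, FN = 3))
  # hand-worked 3 GT / 4 preds case: P1 hits G1 (IoU 1), P2 hits G2
  # (IoU 9/11), P3 re-hits the used G1 -> FP, P4 only reaches IoU 1/3 -> FP
  preds <- data.frame(image_id = "a", cls = "N",
                      confidence = c(0.9, 0.8, 0.7, 0.6),
                      xmin = c(0, 21, 0, 40), ymin = c(0, 0, 0, 5),
                      xmax = c(10, 31, 10, 50), ymax = c(10, 10, 10, 15))
  m2 <- match_detections(gt, preds)
  expect_equal(m2$N$counts, list(TP = 2, FP = 2, FN = 1))
  # conservation: TP+FN = |gt|, TP+FP = |preds|
  expect_equal(m2$N$counts$TP + m2$N$counts$FN, nrow(gt))
  expect_equal(m2$N$counts$TP + m2$N$counts$FP, nrow(preds))
})

test_that("precision and recall follow the TP/FP/FN arithmetic", {
  pr <- precision_recall(list(TP = 8, FP = 2, FN = 2))
  expect_equal(unname(pr), c(0.8, 0.8))
  pr0 <- precision_recall(list(TP = 0, FP = 5, FN = 0))
  expect_equal(pr0[["P"]], 0)
  expect_true(isTRUE(attr(pr0, "undefined")))
  set.seed(4)
  for (i in 1:20) {
    tp <- rpois(1, 10); fp <- rpois(1, 5); fn <- rpois(1, 5)
    pr <- precision_recall(list(TP = tp, FP = fp, FN = fn))
    if (tp + fp > 0) expect_equal(pr[["P"]], tp / (tp + fp))
    if (tp + fn > 0) expect_equal(pr[["R"]], tp / (tp + fn))
  }
})

test_that("average precision integrates the step envelope", {
  expect_equal(average_precision(data.frame(recall = c(1/3, 2/3, 1),
                                            precision = c(1, 1, 1))), 1)
  expect_equal(average_precision(data.frame(recall = 0.5, precision = 1)),
               0.5)
  expect_equal(average_precision(data.frame(recall = numeric(),
                                            precision = numeric())), 0)
  # independent oracle: AP = (1/n_gt) * sum over TPs of the max precision
  # at recall >= that TP's recall
  set.seed(12)
  for (i in 1:25) {
    n_gt <- sample(3:8, 1)
    tp <- sample(c(TRUE, FALSE), sample(4:12, 1), replace = TRUE)
    flags <- data.frame(tp = tp)
    curve <- pr_curve(flags, n_gt)
    got <- average_precision(curve)
    oracle <- 0
    for (k in which(tp)) {
      rk <- curve$recall[k]
      oracle <- oracle + max(curve$precision[curve$recall >= rk]) / n_gt
    }
    expect_equal(got, oracle)
  }
})

test_that("adding a correct lower-confidence detection never lowers AP", {
  set.seed(33)
  gt <- data.frame(image_id = "a", cls = "N",
                   xmin = seq(0, 120, by = 40), ymin = 0,
                   xmax = seq(20, 140, by = 40), ymax = 20)
  preds <- data.frame(image_id = "a", cls = "N",
                      confidence = c(0.9, 0.7, 0.5),
                      xmin = c(0, 41, 200), ymin = c(0, 0, 0),
                      xmax = c(20, 60, 220), ymax = c(20, 20, 20))
  ap <- function(p) {
    m <- match_detections(gt, p)
    average_precision(pr_curve(m$N$flags, m$N$n_gt))
  }
  base_ap <- ap(preds)
  extra <- rbind(preds, data.frame(image_id = "a", cls = "N",
                                   confidence = 0.1, xmin = 80, ymin = 0,
                                   xmax = 100, ymax = 20))
  expect_gte(ap(extra), base_ap)
})

test_that("mAP is the arithmetic mean of the eight class APs", {
  expect_equal(mean_average_precision(rep(1, 8)), 1)
  expect_equal(mean_average_precision(rep(0.5, 8)), 0.5)
  set.seed(2)
  aps <- runif(8)
  expect_equal(mean_average_precision(aps), mean(aps))
  expect_error(mean_average_precision(runif(5)), "exactly 8")
})

test_that("evaluation reports the Table-shaped metrics row", {
  w <- toy_world()
  preds <- generate_fixture_predictions(w$dataset, quality = 1)
  row <- evaluate_detections(w$dataset, preds)
  expect_equal(row$P, 1)
  expect_equal(row$R, 1)
  expect_equal(row$mAP, 1)
  expect_true(all(unlist(row[paste0("AP_", occlusion_classes())]) == 1))
})

test_that("detection files round-trip through CSV", {
  w <- toy_world()
  preds <- generate_fixture_predictions(w$dataset, quality = 0.8, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(preds, f, row.names = FALSE)
  back <- read_detections(f)
  expect_equal(back, preds[names(back)])
})
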