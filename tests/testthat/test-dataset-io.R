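test_that("VOC write/read round-trips annotations exactly", {
  w <- toy_world()
  d <- w$dataset
  out <- withr::local_tempdir()
  n <- write_voc(d, out)
  expect_equal(n, n_images(d))
  back <- read_voc(out, image_dir = dirname(d$images$path[1]),
                   regions = stats::setNames(d$images$region,
                                             d$images$image_id))
  expect_equal(n_images(back), n_images(d))
  key <- function(b) sort(paste(b$image_id, b$cls, b$xmin, b$ymin,
                                b$xmax, b$ymax))
  expect_identical(key(back$boxes), key(d$boxes))
})

test_that("empty annotation directory yields an empty dataset", {
  out <- withr::local_tempdir()
  d <- read_voc(out)
  expect_equal(n_images(d), 0)
  expect_equal(n_boxes(d), 0)
})

test_that("VOC reader rejects unknown classes and out-of-bounds boxes", {
  out <- withr::local_tempdir()
  d1 <- ob_dataset(data.frame(image_id = "a", path = "a.png", width = 100,
                              height = 100, region = "ZY"),
                   data.frame(image_id = "a", cls = "BLF", xmin = 10,
                              ymin = 10, xmax = 50, ymax = 60))
  write_voc(d1, out)
  xml <- readLines(file.path(out, "a.xml"))
  writeLines(gsub("BLF", "weird", xml), file.path(out, "a.xml"))
  expect_error(read_voc(out), "unknown class")
  writeLines(gsub("<xmax>50</xmax>", "<xmax>150</xmax>", xml),
             file.path(out, "a.xml"))
  expect_error(read_voc(out), "outside image bounds")
  clipped <- read_voc(out, on_invalid = "clip")
  expect_equal(clipped$boxes$xmax, 100)
})

test_that("YOLO lines carry normalized center/size coordinates", {
  out <- withr::local_tempdir()
  d <- ob_dataset(data.frame(image_id = c("full", "part"),
                             path = c("full.png", "part.png"),
                             width = c(100, 100), height = c(100, 200),
                             region = "ZY"),
                  data.frame(image_id = c("full", "part"),
                             cls = c("N", "L"),
                             xmin = c(0, 10), ymin = c(0, 10),
                             xmax = c(100, 50), ymax = c(100, 60)))
  write_yolo(d, out)
  full <- as.numeric(strsplit(readLines(file.path(out, "full.txt")), " ")[[1]])
  expect_equal(full, c(0, 0.5, 0.5, 1.0, 1.0))
  part <- as.numeric(strsplit(readLines(file.path(out, "part.txt")), " ")[[1]])
  # (10,10,50,60) on 100x200: cx=(10+50)/2/100, cy=(10+60)/2/200, w=40/100, h=50/200
  expect_equal(part, c(occlusion_class_index("L") - 1,
                       0.3, 0.175, 0.4, 0.25))
})

test_that("YOLO round-trip recovers pixel boxes within 0.5 px", {
  w <- toy_world()
  d <- w$dataset
  out <- withr::local_tempdir()
  write_yolo(d, out)
  back <- read_yolo(out, d$images)
  expect_equal(n_boxes(back), n_boxes(d))
  ord <- function(b) b[order(b$image_id, b$cls, b$xmin, b$ymin), ]
  a <- ord(d$boxes); b <- ord(back$boxes)
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    expect_lte(max(abs(a[[col]] - b[[col]])), 0.5)
})

test_that("dataset validation enforces class, bounds and id uniqueness", {
  imgs <- data.frame(image_id = "a", path = "a.png", width = 50,
                     height = 50, region = "ZY")
  expect_error(ob_dataset(imgs, data.frame(image_id = "a", cls = "Q",
                                           xmin = 0, ymin = 0, xmax = 10,
                                           ymax = 10)), "unknown occlusion")
  expect_error(ob_dataset(imgs, data.frame(image_id = "a", cls = "N",
                                           xmin = 0, ymin = 0, xmax = 60,
                                           ymax = 10)), "invalid bounding box")
  expect_error(ob_dataset(rbind(imgs, imgs)), "duplicate")
})

test_that("train/test split partitions images at the requested ratio", {
  imgs <- data.frame(image_id = paste0("i", 1:10), path = "", width = 10,
                     height = 10, region = "ZY")
  d <- ob_dataset(imgs)
  s <- split_train_test(d, 0.3, seed = 1)
  expect_equal(n_images(s$test), 3)
  expect_equal(n_images(s$train), 7)
  expect_length(intersect(s$train$images$image_id,
                          s$test$images$image_id), 0)
  s2 <- split_train_test(d, 0.3, seed = 1)
  expect_identical(sort(s2$test$images$image_id),
                   sort(s$test$images$image_id))
  s3 <- split_train_test(d, 0.3, seed = 2)
  expect_false(identical(sort(s3$test$images$image_id),
                         sort(s$test$images$image_id)))
})

test_that("split covers every image exactly once (multiset union)", {
  imgs <- data.frame(image_id = paste0("i", 1:1000), path = "", width = 10,
                     height = 10, region = rep(c("ZY", "QX"), 500))
  d <- ob_dataset(imgs)
  s <- split_train_test(d, 0.3, seed = 42)
  expect_identical(sort(c(s$train$images$image_id, s$test$images$image_id)),
                   sort(imgs$image_id))
  empty <- split_train_test(ob_dataset(imgs[0, ]), 0.3, seed = 1)
  expect_equal(n_images(empty$train) + n_images(empty$test), 0)
})
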