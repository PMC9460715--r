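test_that("count_boxes matches a linear scan and ignores record order", {
  w <- toy_world()
  tab <- count_boxes(w$partition)
  for (i in seq_len(nrow(tab))) {
    d <- w$partition[[tab$key[i]]]
    for (cls in occlusion_classes())
      expect_equal(tab[i, cls], sum(d$boxes$cls == cls))
    expect_equal(tab$n_images[i], nrow(d$images))
    expect_equal(tab$total[i], nrow(d$boxes))
  }
  # permutation invariance
  shuf <- lapply(w$partition, function(d) {
    d$boxes <- d$boxes[rev(seq_len(nrow(d$boxes))), ]
    d
  })
  tab2 <- count_boxes(shuf)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # recount equals the generating spec (fixture bijection)
  spec_tab <- w$spec$per_cell_counts
  for (i in seq_len(nrow(spec_tab)))
    for (cls in occlusion_classes())
      expect_equal(tab[tab$key == spec_tab$key[i], cls],
                   spec_tab[i, cls])
})

test_that("empty partition gives an all-zero table", {
  tab <- count_boxes(list())
  expect_equal(nrow(tab), 0)
  rep <- imbalance_report(tab)
  expect_true(rep$degenerate)
})

test_that("imbalance report shares and single-class degenerate case", {
  tab <- count_boxes(toy_world()$partition)
  rep <- imbalance_report(tab, min_boxes_to_retain = 1)
  expect_equal(sum(rep$class_totals), rep$grand_total)
  # shares recompute to one decimal, half-up
  manual <- floor(1000 * rep$class_totals / rep$grand_total + 0.5) / 10
  expect_equal(unname(rep$class_share), unname(manual))
  solo <- tab; solo[occlusion_classes()[-1]] <- 0
  solo$total <- solo$N
  rep2 <- imbalance_report(solo)
  expect_equal(unname(rep2$class_share[["N"]]), 100.0)
})

test_that("plan conserves counts: count + deficit = target in every cell", {
  set.seed(11)
  for (rep_i in 1:5) {
    cells <- matrix(rpois(24, 40), nrow = 3)
    tab <- data.frame(key = c("A_H", "A_L", "B_H"), n_images = 1,
                      total = rowSums(cells))
    tab[occlusion_classes()] <- cells
    tab <- structure(tab, class = c("ob_count_table", "data.frame"))
    plan <- make_balance_plan(tab, min_boxes_to_retain = 0)
    expect_equal(plan$counts + plan$deficits,
                 matrix(plan$target, 3, 8,
                        dimnames = dimnames(plan$counts)))
    expect_true(all(plan$deficits >= 0))
    expect_length(intersect(plan$retained_keys, plan$skipped_keys), 0)
  }
})

test_that("already-balanced table yields zero deficits", {
  tab <- data.frame(key = c("A_H", "B_H"), n_images = 1, total = 80)
  tab[occlusion_classes()] <- 10
  plan <- make_balance_plan(structure(tab, class = c("ob_count_table",
                                                     "data.frame")),
                            min_boxes_to_retain = 1)
  expect_equal(plan$target, 10L)
  expect_true(all(plan$deficits == 0))
})

test_that("raising the retention threshold never grows the retained set", {
  tab <- table2_counts()
  prev <- NULL
  for (thr in c(0, 100, 500, 1000, 9000, 20000)) {
    keys <- make_balance_plan(tab, min_boxes_to_retain = thr)$retained_keys
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  expect_error(make_balance_plan(tab, min_boxes_to_retain = 1e6),
               "no sub-dataset")
})

test_that("explicit target override is honored and validated", {
  tab <- table2_counts()
  plan <- make_balance_plan(tab, 1000, target = 12000)
  expect_equal(plan$target, 12000L)
  expect_equal(unname(plan$deficits["ZY_H", "B"]), 12000 - 10579)
  expect_error(make_balance_plan(tab, 1000, target = 5000), "below")
})

test_that("count table CSV and plan JSON round-trip", {
  tab <- count_boxes(toy_world()$partition)
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(tab, f)
  expect_equal(as.data.frame(read_count_table(f)), as.data.frame(tab))
  plan <- make_balance_plan(tab, min_boxes_to_retain = 10)
  pj <- withr::local_tempfile(fileext = ".json")
  write_balance_plan(plan, pj)
  back <- read_balance_plan(pj)
  expect_equal(back$target, plan$target)
  expect_equal(back$deficits, plan$deficits)
  expect_setequal(back$retained_keys, plan$retained_keys)
})
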