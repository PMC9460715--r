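test_that("edge entry points equal the boundary-lattice enumeration", {
  expect_equal(nrow(edge_entry_points(6)), 24)
  expect_equal(nrow(edge_entry_points(1)), 4)
  for (n in 2:10) {
    pts <- edge_entry_points(n)
    expect_equal(nrow(pts), 4 * n)
    all_pts <- expand.grid(row = 0:n, col = 0:n)
    oracle <- all_pts[all_pts$row %in% c(0, n) | all_pts$col %in% c(0, n), ]
    expect_setequal(paste(pts$row, pts$col),
                    paste(oracle$row, oracle$col))
    # row-major ordering
    expect_true(!is.unsorted(pts$row))
  }
})

test_that("valid endpoints match the exhaustive filter for all 24 starts", {
  starts <- edge_entry_points(6)
  all_pts <- expand.grid(row = 0:6, col = 0:6)
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    got <- valid_endpoints(s, 6)
    keep <- all_pts$row != s$row & all_pts$col != s$col &
      pmax(abs(all_pts$row - s$row), abs(all_pts$col - s$col)) > 3
    oracle <- all_pts[keep, ]
    expect_setequal(paste(got$row, got$col),
                    paste(oracle$row, oracle$col))
    expect_gt(nrow(got), 0)  # never empty on the 6x6 grid
  }
  # spot checks from a corner and an edge midpoint start
  ve <- valid_endpoints(list(row = 0, col = 0), 6)
  expect_true(all(ve$row >= 1 & ve$col >= 1))
  expect_true(all(pmax(ve$row, ve$col) >= 4))
  ve2 <- valid_endpoints(list(row = 0, col = 3), 6)
  expect_false("4,3" %in% paste(ve2$row, ve2$col, sep = ","))
  expect_true("6,6" %in% paste(ve2$row, ve2$col, sep = ","))
})

test_that("single-occluder synthesis only touches the paste rectangle", {
  set.seed(21)
  nc <- toy_n_crop(60, 60)
  el <- opaque_element("branch")
  crop <- synthesize_single_occluder(nc, el)
  expect_equal(crop$cls, "B")
  expect_equal(dim(crop$raster), dim(nc))
  pb <- crop$provenance$paste_box
  outside <- array(TRUE, dim(nc)[1:2])
  outside[(pb$ymin + 1):pb$ymax, (pb$xmin + 1):pb$xmax] <- FALSE
  for (ch in 1:3)
    expect_equal(crop$raster[, , ch][outside], nc[, , ch][outside])
  # leaf element gives class L
  leaf <- opaque_element("leaf")
  expect_equal(synthesize_single_occluder(nc, leaf)$cls, "L")
})

test_that("a fully transparent element leaves the crop unchanged", {
  set.seed(3)
  nc <- toy_n_crop(48, 48)
  ghost <- structure(list(raster = solid_raster(20, 20, alpha = 0),
                          kind = "leaf", illumination = "high",
                          source_id = "ghost"), class = "ob_element")
  crop <- synthesize_single_occluder(nc, ghost)
  expect_equal(crop$raster, nc)
})

test_that("fruit placements respect the overlap cap and centroid rule", {
  set.seed(17)
  oracle_gap <- 0; n_over <- 0; n_centered <- 0
  for (i in 1:10000) {
    pl <- sample_fruit_placement(60, 48)
    if (pl$overlap_fraction > 0.34) n_over <- n_over + 1
    # recompute the overlap from the rectangles (pixel-counting oracle)
    ox <- max(0, min(pl$corner[1] + 60, pl$n_offset[1] + 60) -
                max(pl$corner[1], pl$n_offset[1]))
    oy <- max(0, min(pl$corner[2] + 48, pl$n_offset[2] + 48) -
                max(pl$corner[2], pl$n_offset[2]))
    oracle_gap <- max(oracle_gap,
                      abs(pl$overlap_fraction - ox * oy / (60 * 48)))
    if (pl$corner[1] + 30 == pl$canvas[1] / 2 &&
        pl$corner[2] + 24 == pl$canvas[2] / 2)
      n_centered <- n_centered + 1
  }
  expect_equal(n_over, 0)
  expect_equal(n_centered, 0)
  expect_lt(oracle_gap, 1e-12)
})

test_that("corner (0,0) overlap equals the 4/36 cell-resolution value", {
  set.seed(1)
  repeat {
    pl <- sample_fruit_placement(60, 60)
    if (all(pl$corner == c(0, 0))) break
  }
  expect_equal(pl$overlap_fraction, 4 / 36)
})

test_that("fruit synthesis changes exactly the geometric intersection", {
  set.seed(8)
  nc <- toy_n_crop(60, 60, gray = 0.9)
  fruit <- opaque_element("fruit", 30, 30)
  crop <- synthesize_fruit_occlusion(nc, fruit)
  expect_equal(crop$cls, "F")
  expect_equal(dim(crop$raster), dim(nc))
  changed <- apply(abs(crop$raster - nc), c(1, 2), max) > 1e-9
  expect_equal(sum(changed), round(crop$provenance$overlap_fraction * 60 * 60))
  expect_lte(sum(changed) / (60 * 60), 0.34)
})

test_that("fused synthesis composes the single steps and tracks provenance", {
  w <- toy_world()
  set.seed(31)
  nc <- toy_n_crop(60, 60)
  blf <- synthesize_fused(nc, "BLF", w$pool, "high")
  expect_equal(blf$cls, "BLF")
  expect_length(blf$provenance$elements, 3)
  expect_match(blf$provenance$elements[1], "fruit")
  expect_match(blf$provenance$elements[2], "branch")
  expect_match(blf$provenance$elements[3], "leaf")
  # compositionality: BF equals fruit-then-branch under the same RNG stream
  set.seed(55)
  e1 <- sample_element(w$pool, "fruit", "high")
  s1 <- synthesize_fruit_occlusion(nc, e1)
  e2 <- sample_element(w$pool, "branch", "high")
  s2 <- synthesize_single_occluder(s1$raster, e2)
  set.seed(55)
  fused <- synthesize_fused(nc, "BF", w$pool, "high")
  expect_equal(fused$raster, s2$raster)
  # composite-element route uses one composite element
  set.seed(9)
  comp <- synthesize_fused(nc, "BL", w$pool, "high",
                           route = "composite_element")
  expect_equal(comp$cls, "BL")
  expect_length(comp$provenance$elements, 1)
  expect_error(synthesize_fused(nc, "B", w$pool, "high"), "not a fused")
})

test_that("synthesis is reproducible bit-for-bit under a fixed seed", {
  w <- toy_world()
  nc <- toy_n_crop(54, 66)
  set.seed(101); a <- synthesize_fused(nc, "BLF", w$pool, "low")
  set.seed(101); b <- synthesize_fused(nc, "BLF", w$pool, "low")
  expect_identical(a$raster, b$raster)
  expect_identical(a$provenance, b$provenance)
})

test_that("cyclic N extraction reuses boxes round-robin", {
  dir <- withr::local_tempdir()
  counts <- data.frame(key = "AA_H", N = 3, L = 0, F = 0, B = 0, LF = 0,
                       BL = 0, BF = 0, BLF = 0)
  ds <- generate_fixture_dataset(fixture_spec(counts, seed = 4), dir)
  set.seed(2)
  crops <- extract_n_crops(ds, "AA_H", 7)
  expect_length(crops, 7)
  sig <- vapply(crops, function(r) paste(format(sum(r), digits = 12),
                                         paste(dim(r), collapse = "x")),
                character(1))
  expect_equal(sort(as.integer(table(sig))), c(2, 2, 3))
  # crop size equals the source box size
  expect_true(all(vapply(crops, function(r) all(dim(r)[1:2] == c(40, 40)),
                         logical(1))))
  expect_length(extract_n_crops(ds, "AA_H", 0), 0)
  only_b <- data.frame(key = "BB_H", N = 0, L = 0, F = 0, B = 2, LF = 0,
                       BL = 0, BF = 0, BLF = 0)
  ds2 <- generate_fixture_dataset(fixture_spec(only_b, seed = 4),
                                  withr::local_tempdir())
  expect_error(extract_n_crops(ds2, "BB_H", 1), "no N boxes")
})
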