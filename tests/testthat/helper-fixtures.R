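# Shared toy fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

toy_counts <- function() {
  data.frame(key = c("ZY_H", "ZY_L", "QX_H", "QX_L"),
             N = c(8, 6, 5, 4), L = c(3, 2, 4, 2), F = c(2, 3, 1, 2),
             B = c(10, 4, 3, 3), LF = c(1, 2, 2, 1), BL = c(4, 3, 2, 2),
             BF = c(2, 1, 3, 1), BLF = c(1, 1, 1, 2))
}

# toy world: rendered dataset + partition + pool, cached across test files
toy_world <- function() {
  if (!is.null(.fixture_cache$world)) return(.fixture_cache$world)
  dir <- file.path(tempdir(), "occubal-toy-world")
  spec <- fixture_spec(toy_counts(), seed = 7)
  ds <- generate_fixture_dataset(spec, dir)
  world <- list(spec = spec, dataset = ds,
                partition = partition_by_illumination(ds),
                pool = generate_fixture_pool(spec))
  .fixture_cache$world <- world
  world
}

table2_counts <- function() {
  read_count_table(system.file("extdata/mtoa_table2.csv", package = "occubal"))
}

# random flat-color N crop
toy_n_crop <- function(h = 60, w = 60, gray = 0.6) {
  img <- solid_raster(h, w, rgb = c(gray, gray * 0.5, gray * 0.4))
  clamp01(img + array(stats::runif(h * w * 3, -0.02, 0.02), c(h, w, 3)))
}

# element with a fully opaque rectangular mask
opaque_element <- function(kind = "branch", h = 30, w = 30,
                           illumination = "high") {
  ob_element(solid_raster(h, w, rgb = c(0.4, 0.3, 0.1), alpha = 1),
             kind, illumination, source_id = "opaque")
}
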