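# Grid model, raster/vector/tracking I/O, and area accounting.

test_that("grid geometry follows the top-left origin convention", {
  g <- grid_spec(100, 900, 30, 5, 4)
  expect_equal(cell_centres_x(g), 100 + (1:4 - 0.5) * 30)
  expect_equal(cell_centres_y(g), 900 - (1:5 - 0.5) * 30)
  expect_error(grid_spec(0, 0, -1, 2, 2), "cell_size")
  expect_error(grid_spec(0, 0, 10, 0, 2), "positive")
  expect_error(class_catalogue(c("a", "a")), "unique")
})

test_that("integer rasters round-trip bit-exactly", {
  g <- tiny_grid(8)
  lab <- matrix(sample(c(1:10, NA), 64, replace = TRUE), 8, 8)
  hm <- habitat_map(lab, g)
  path <- file.path(withr::local_tempdir(), "hab")
  write_raster(hm, path)
  back <- read_raster(path)
  expect_identical(back$values, hm$values)
  expect_identical(as.character(back$catalogue), as.character(hm$catalogue))
  expect_equal(back$grid$origin_x, g$origin_x)
  expect_equal(back$grid$cell_size, g$cell_size)
})

test_that("proportion rasters round-trip on the simplex", {
  g <- tiny_grid(5)
  k <- 10
  raw <- array(stats::runif(5 * 5 * k), c(5, 5, k))
  arr <- sweep(raw, c(1, 2), apply(raw, c(1, 2), sum), "/")
  pr <- proportion_raster(arr, g)
  path <- file.path(withr::local_tempdir(), "prop")
  write_raster(pr, path)
  back <- read_raster(path, "proportion_raster")
  expect_lt(max(abs(back$values - pr$values)), 1e-6)
  sums <- apply(back$values, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("integrity maps preserve the score lattice through I/O", {
  im <- integrity_from_counts(c(3, 4, 5, 6, 7))
  path <- file.path(withr::local_tempdir(), "integ")
  write_raster(im, path)
  back <- read_raster(path)
  expect_setequal(unique(stats::na.omit(as.vector(back$values))),
                  c(0, 0.25, 0.5, 0.75, 1))
  expect_identical(back$scenario, "after")
})

test_that("geographic-CRS rasters are rejected", {
  g <- tiny_grid(4)
  g$crs <- "EPSG:4326"
  hm <- habitat_map(matrix(1L, 4, 4), g)
  path <- file.path(withr::local_tempdir(), "geo")
  write_raster(hm, path)
  expect_error(read_raster(path), "projected CRS required")
  expect_error(read_raster("/nonexistent/dir/x.asc"), "")
})

test_that("proportion raster band count must match the catalogue", {
  g <- tiny_grid(4)
  hm <- habitat_map(matrix(1L, 4, 4), g)
  path <- file.path(withr::local_tempdir(), "mislabeled")
  write_raster(hm, path)
  # rewrite the sidecar to claim a proportion raster with too few bands
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$kind <- "proportion_raster"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_raster(path), "band count")
})

test_that("tracking CSV reading drops bad rows and deduplicates", {
  csv <- file.path(withr::local_tempdir(), "trk.csv")
  writeLines(c("species,individual_id,x,y,date",
               "tapir,t1,100,200,2016-03-01",
               "tapir,t1,100,200,2016-03-01",   # exact duplicate
               "tapir,t2,150,250,2016-03-02",
               "deer,d1,300,400,2016-04-01",
               "deer,d2,310,410,2016-04-02"), csv)
  suppressMessages(tab <- read_tracking_csv(csv))
  expect_s3_class(tab, "tracking_table")
  expect_equal(nrow(tab), 4)
  # idempotent: re-reading clean data changes nothing
  clean <- file.path(withr::local_tempdir(), "clean.csv")
  write_tracking_csv(tab, clean)
  expect_equal(nrow(read_tracking_csv(clean)), 4)
})

test_that("records without identification are dropped with a warning", {
  csv <- file.path(withr::local_tempdir(), "trk2.csv")
  writeLines(c("species,individual_id,x,y",
               "tapir,t1,100,200",
               ",t9,10,20",                     # blank species
               "tapir,t1,notanumber,200"), csv) # bad coordinate
  expect_warning(tab <- read_tracking_csv(csv), "dropped")
  expect_equal(nrow(tab), 1)
})

test_that("tracking CSV contract: header and degenerate cases", {
  csv <- file.path(withr::local_tempdir(), "bad.csv")
  writeLines(c("species,x,y", "tapir,1,2"), csv)
  expect_error(read_tracking_csv(csv), "individual_id")
  empty <- file.path(withr::local_tempdir(), "empty.csv")
  writeLines("species,individual_id,x,y", empty)
  tab <- read_tracking_csv(empty)
  expect_equal(nrow(tab), 0)
  expect_s3_class(tab, "tracking_table")
})

test_that("non-ISO dates become NA timestamps with a warning", {
  csv <- file.path(withr::local_tempdir(), "dates.csv")
  writeLines(c("species,individual_id,x,y,date",
               "tapir,t1,1,2,2016-05-01",
               "tapir,t1,3,4,05/02/2016"), csv)
  expect_warning(tab <- read_tracking_csv(csv), "ISO")
  expect_identical(is.na(tab$timestamp), c(FALSE, TRUE))
})

test_that("boundary polygons validate, measure area, and test membership", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  b <- boundary_polygon(sq)
  expect_equal(b$area_km2, 1)
  expect_true(boundary_contains(b, 500, 500))
  expect_false(boundary_contains(b, 1500, 500))
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(boundary_polygon(bowtie), "self-intersects")
  # hole excluded by even-odd rule
  holed <- boundary_polygon(list(list(sq, rbind(c(400, 400), c(600, 400),
                                                c(600, 600), c(400, 600)))))
  expect_equal(holed$area_km2, 1 - 0.04)
  expect_false(boundary_contains(holed, 500, 500))
})

test_that("boundary GeoJSON round-trips", {
  sq <- rbind(c(0, 0), c(3000, 0), c(3000, 3000), c(0, 3000))
  b <- boundary_polygon(sq)
  path <- file.path(withr::local_tempdir(), "b.geojson")
  write_geojson(b, path)
  back <- read_boundary(path)
  expect_equal(back$area_km2, 9)
  expect_true(boundary_contains(back, 1500, 1500))
})

test_that("area_summary: uniform label over a 1 km2 boundary at 30 m cells", {
  n <- 40                                     # 1200 m square grid
  g <- grid_spec(0, 1200, 30, n, n)
  hm <- habitat_map(matrix(8L, n, n), g)
  b <- boundary_polygon(rbind(c(100, 100), c(1100, 100),
                              c(1100, 1100), c(100, 1100)))
  tab <- area_summary(hm, b)
  grass <- tab[tab$label == "tall grassland", ]
  # centre-rule discretisation of a 1 km square at 30 m cells
  expect_equal(grass$area_km2, 1, tolerance = 0.05)
  expect_equal(grass$percent, 100)
  # labels partition the mapped area (within one cell)
  expect_lt(abs(sum(tab$area_km2[tab$label != "Total"]) -
                  tab$area_km2[tab$label == "Total"]), cell_area_km2(g))
})

test_that("area_summary errors on an empty boundary intersection", {
  hm <- habitat_map(matrix(1L, 4, 4), tiny_grid(4))
  far <- boundary_polygon(rbind(c(1e6, 1e6), c(1e6 + 10, 1e6),
                                c(1e6 + 10, 1e6 + 10), c(1e6, 1e6 + 10)))
  expect_error(area_summary(hm, far), "empty intersection")
})
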