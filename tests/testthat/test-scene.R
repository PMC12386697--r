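test_that("scene write/read round-trips bands, mask and transform", {
  set.seed(7)
  h <- 20; w <- 16
  bands <- lapply(1:5, function(i) matrix(runif(h * w, -0.02, 1.1), h, w))
  names(bands) <- rifasel:::BAND_NAMES
  mask <- matrix(FALSE, h, w); mask[1, 1:3] <- TRUE
  sc <- suppressWarnings(reflectance_scene(
    bands, nodata_mask = mask,
    transform = list(x0 = 100, dx = 0.5, y0 = 50, dy = -0.5),
    crs = "EPSG:32651"))
  path <- tempfile(fileext = ".tif")
  write_scene(sc, path)
  back <- read_scene(path)
  for (b in rifasel:::BAND_NAMES) {
    expect_equal(back$bands[[b]][!mask], sc$bands[[b]][!mask],
                 tolerance = 1e-7)
    expect_true(all(is.na(back$bands[[b]][mask])))
  }
  expect_equal(back$nodata_mask, mask)
  expect_equal(back$transform$dx, 0.5)
  expect_equal(back$crs, "EPSG:32651")
})

test_that("plain multiband rasters honor the band map and its bounds", {
  h <- 8; w <- 8
  dirs <- lapply(1:5, function(i) matrix(i / 10, h, w))
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(dirs, path, bits.per.sample = 32L)
  sc <- read_scene(path, band_map = c(blue = 5, green = 4, red = 3,
                                      rededge = 2, nir = 1))
  expect_equal(sc$height, h)
  expect_equal(sc$bands$blue[1, 1], 0.5, tolerance = 1e-6)
  expect_equal(sc$bands$nir[1, 1], 0.1, tolerance = 1e-6)
  # 4-band file with a map pointing at band 5 -> configuration error
  path4 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(dirs[1:4], path4, bits.per.sample = 32L)
  expect_error(read_scene(path4), "out of range")
  expect_error(read_scene(path, band_map = c(blue = 1, green = 2, red = 3,
                                             rededge = 4)),
               "misses band")
})

test_that("scene validation flags shape mismatches and odd reflectance", {
  b <- lapply(1:5, function(i) matrix(0.1, 5, 5))
  names(b) <- rifasel:::BAND_NAMES
  bad <- b; bad$nir <- matrix(0.1, 4, 5)
  expect_error(reflectance_scene(bad), "shapes differ")
  expect_error(reflectance_scene(b[1:4]), "missing band")
  b$red[2, 2] <- 1.9   # artifact: warn, do not error
  expect_warning(reflectance_scene(b), "outside")
})

test_that("axis-aligned polygons rasterize by the pixel-center rule", {
  sc <- tiny_scene()
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(class_id = 2, id = "sq"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(2, 3), list(5, 3), list(5, 6), list(2, 6),
                list(2, 3)))))))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  rois <- read_rois(path, sc)
  expect_length(rois$rois, 1)
  # a 3x3 block: columns 3..5, rows 4..6
  expect_length(rois$rois[[1]]$cells, 9)
  rr <- ((rois$rois[[1]]$cells - 1) %% sc$height) + 1
  cc <- ((rois$rois[[1]]$cells - 1) %/% sc$height) + 1
  expect_setequal(unique(rr), 4:6)
  expect_setequal(unique(cc), 3:5)
})

test_that("out-of-extent polygons are dropped with a warning", {
  sc <- tiny_scene()
  feat <- function(cls, id, x0, y0) list(
    type = "Feature", properties = list(class_id = cls, id = id),
    geometry = list(type = "Polygon", coordinates = list(
      list(list(x0, y0), list(x0 + 2, y0), list(x0 + 2, y0 + 2),
           list(x0, y0 + 2), list(x0, y0)))))
  gj <- list(type = "FeatureCollection",
             features = list(feat(1, "in", 2, 2), feat(2, "out", 50, 50)))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_warning(rois <- read_rois(path, sc), "dropped")
  expect_length(rois$rois, 1)
  expect_equal(rois$rois[[1]]$id, "in")
})

test_that("invalid class attributes are rejected", {
  sc <- tiny_scene()
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(class_id = 9),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(1, 1), list(3, 1), list(3, 3), list(1, 3),
                list(1, 1)))))))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rois(path, sc), "class_id")
})

test_that("overlapping ROIs of different classes are both retained", {
  sc <- tiny_scene()
  feat <- function(cls, id, x0, y0, s) list(
    type = "Feature", properties = list(class_id = cls, id = id),
    geometry = list(type = "Polygon", coordinates = list(
      list(list(x0, y0), list(x0 + s, y0), list(x0 + s, y0 + s),
           list(x0, y0 + s), list(x0, y0)))))
  gj <- list(type = "FeatureCollection",
             features = list(feat(1, "a", 1, 1, 4), feat(6, "b", 3, 3, 4)))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  rois <- read_rois(path, sc)
  expect_length(rois$rois, 2)
  overlap <- intersect(rois$rois[[1]]$cells, rois$rois[[2]]$cells)
  # rasterized independently: shared pixels belong to both
  expect_length(overlap, 4)
})

test_that("a written ROI outline re-rasterizes to its own mask", {
  sc <- tiny_scene()
  cells <- sort(c(14, 15, 26, 27, 38, 50))  # irregular mask
  rois <- roi_set(list(list(id = "m", class_id = 1, cells = cells)),
                  sc$height, sc$width)
  path <- tempfile(fileext = ".geojson")
  write_rois(rois, path)
  back <- read_rois(path, sc)
  expect_equal(back$rois[[1]]$cells, cells)
  expect_equal(back$rois[[1]]$class_id, 1L)
})

test_that("roi_set enforces unique ids and the class range", {
  expect_error(roi_set(list(list(id = "a", class_id = 1, cells = 1),
                            list(id = "a", class_id = 2, cells = 2)),
                       5, 5), "unique")
  expect_error(roi_set(list(list(id = "a", class_id = 7, cells = 1)),
                       5, 5), "1..6")
  expect_error(roi_set(list(list(id = "a", class_id = 3,
                                 cells = integer(0))), 5, 5), "no pixels")
})
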