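test_that("component labeling agrees with a flood-fill oracle", {
  withr::local_seed(41)
  for (rep in 1:8) {
    m <- matrix(stats::runif(30 * 30) < 0.35, 30, 30)
    ps <- mask_to_polygons(m, min_area = 0)
    expect_identical(length(ps$polygons), max(flood_label(m)))
    # with no closing and no area filter, total area = true pixel count
    expect_identical(total_area(ps), as.numeric(sum(m)))
  }
})

test_that("rectangles trace to exact lattice polygons", {
  m <- matrix(FALSE, 20, 20); m[3:12, 5:14] <- TRUE
  ps <- mask_to_polygons(m, min_area = 0)
  expect_length(ps$polygons, 1)
  p <- ps$polygons[[1]]
  expect_equal(p$area, 100)
  expect_identical(nrow(p$exterior), 4L)
  expect_setequal(apply(p$exterior, 1, paste, collapse = ","),
                  c("4,2", "14,2", "14,12", "4,12"))
  expect_length(p$holes, 0)
  # empty mask
  expect_length(mask_to_polygons(matrix(FALSE, 4, 4))$polygons, 0)
})

test_that("diagonal pixels split under 4-connectivity; holes are rings", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_length(mask_to_polygons(m, min_area = 0)$polygons, 2)
  donut <- matrix(FALSE, 12, 12)
  donut[2:10, 2:10] <- TRUE; donut[5:7, 5:7] <- FALSE
  pd <- mask_to_polygons(donut, min_area = 0)
  expect_length(pd$polygons, 1)
  expect_length(pd$polygons[[1]]$holes, 1)
  expect_equal(pd$polygons[[1]]$area, 81 - 9)
})

test_that("polygonization then rasterization is the identity on masks", {
  withr::local_seed(42)
  for (rep in 1:8) {
    m <- matrix(stats::runif(24 * 24) < 0.4, 24, 24)
    ps <- mask_to_polygons(m, min_area = 0)
    back <- rasterize_polygons(ps, c(0, 0, 24, 24), 1)
    expect_identical(unname(back), unname(m))
  }
  # and on scaled/shifted lattice rectangles
  ps <- mask_to_polygons(matrix(TRUE, 3, 3), origin = c(64, 128),
                         scale = 16, min_area = 0)
  expect_equal(total_area(ps), (3 * 16)^2)
  r <- rasterize_polygons(ps, c(64, 128, 112, 176), 1)
  expect_true(all(r))
})

test_that("min_area and closing post-process components as configured", {
  m <- matrix(FALSE, 24, 24)
  m[2:19, 2:19] <- TRUE          # area 324
  m[22, 22] <- TRUE              # isolated speck
  ps <- mask_to_polygons(m, min_area = 256)
  expect_length(ps$polygons, 1)
  expect_equal(ps$polygons[[1]]$area, 324)
  # min_area is in level-0 units: at scale 4 the speck is 16 px^2
  expect_length(mask_to_polygons(m, scale = 4, min_area = 256)$polygons, 1)
  expect_length(mask_to_polygons(m, scale = 4, min_area = 16)$polygons, 2)
  expect_length(mask_to_polygons(m, scale = 1, min_area = 2)$polygons, 1)
  # closing bridges a 1-px gap
  g <- matrix(FALSE, 10, 10); g[4:6, 2:4] <- TRUE; g[4:6, 6:8] <- TRUE
  expect_length(mask_to_polygons(g, min_area = 0)$polygons, 2)
  expect_length(mask_to_polygons(g, min_area = 0,
                                 closing_radius = 1)$polygons, 1)
})

test_that("merging unions polygons across patch boundaries", {
  a <- mask_to_polygons(matrix(TRUE, 10, 10), origin = c(0, 0),
                        min_area = 0, slide = "s")
  b <- mask_to_polygons(matrix(TRUE, 10, 10), origin = c(10, 0),
                        min_area = 0, slide = "s")
  mg <- merge_patch_polygons(list(a, b))
  expect_length(mg$polygons, 1)
  expect_equal(total_area(mg), 200)
  # disjoint parts: unchanged counts and areas
  c2 <- mask_to_polygons(matrix(TRUE, 5, 5), origin = c(40, 40),
                         min_area = 0, slide = "s")
  mg2 <- merge_patch_polygons(list(a, c2))
  expect_length(mg2$polygons, 2)
  expect_equal(total_area(mg2), 125)
  # duplicates collapse (idempotent union)
  mg3 <- merge_patch_polygons(list(a, a))
  expect_equal(total_area(mg3), 100)
  expect_error(merge_patch_polygons(list(
    a, mask_to_polygons(matrix(TRUE, 2, 2), min_area = 0, slide = "t"))),
    "different slides")
})

test_that("GeoJSON round trips preserve vertices exactly", {
  withr::local_seed(43)
  f <- withr::local_tempfile(fileext = ".geojson")
  # empty set -> zero features
  write_polygons(polygon_set(slide = "e"), f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(doc$type, "FeatureCollection")
  expect_length(doc$features, 0)
  expect_length(read_polygons(f)$polygons, 0)
  # 50 random rectangles, fractional coordinates allowed
  polys <- lapply(1:50, function(i) {
    x0 <- stats::runif(1, 0, 500); y0 <- stats::runif(1, 0, 500)
    w <- stats::runif(1, 1, 80); h <- stats::runif(1, 1, 80)
    ring <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
    list(exterior = ring, holes = list(), area = w * h)
  })
  ps <- polygon_set(polys, slide = "rects", role = "predicted")
  write_polygons(ps, f)
  back <- read_polygons(f)
  expect_length(back$polygons, 50)
  for (i in 1:50)
    expect_identical(back$polygons[[i]]$exterior, polys[[i]]$exterior)
  expect_identical(back$slide, "rects")
  expect_identical(back$role, "predicted")
})

test_that("QuPath-style annotations with holes and MultiPolygons parse", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{
    "type": "FeatureCollection",
    "features": [{
      "type": "Feature",
      "geometry": {"type": "Polygon", "coordinates": [
        [[0,0],[40,0],[40,40],[0,40],[0,0]],
        [[10,10],[20,10],[20,20],[10,20],[10,10]]
      ]},
      "properties": {"objectType": "annotation",
                     "classification": {"name": "Tumor"}}
    }, {
      "type": "Feature",
      "geometry": {"type": "MultiPolygon", "coordinates": [
        [[[60,0],[70,0],[70,10],[60,10],[60,0]]],
        [[[80,0],[90,0],[90,10],[80,10],[80,0]]]
      ]},
      "properties": {}
    }]
  }', f)
  ps <- read_polygons(f)
  expect_length(ps$polygons, 3)
  expect_length(ps$polygons[[1]]$holes, 1)
  expect_equal(ps$polygons[[1]]$area, 1600 - 100)
  expect_equal(ps$polygons[[2]]$area, 100)
  # the hole is excluded when rasterizing
  r <- rasterize_polygons(ps, c(0, 0, 40, 40), 1)
  expect_false(r[15, 15])
  expect_true(r[5, 5])
  # malformed documents fail with the feature index
  bad <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type": "FeatureCollection",
               "features": [{"type": "Feature", "properties": {}}]}', bad)
  expect_error(read_polygons(bad), "feature 1")
  writeLines('{"type": "Thing"}', bad)
  expect_error(read_polygons(bad), "FeatureCollection")
})

test_that("truth GeoJSON from the simulator round trips unchanged", {
  out <- generate_slide(synthetic_slide_spec(
    size = 128, anomalies = list(anomaly_disc(64, 60, 20)), seed = 44))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(out$truth, f)
  back <- read_polygons(f)
  expect_identical(back$polygons[[1]]$exterior,
                   out$truth$polygons[[1]]$exterior)
  expect_identical(back$slide, out$truth$slide)
})
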