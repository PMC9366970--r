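test_that("a single point target area yields a disc of area pi r^2", {
  b <- build_buffer(target_areas("p", "a1", x = 10, y = -20), radius_m = 250)
  expect_equal(buffer_area(b), pi * 250^2, tolerance = 1e-3 / 100)
})

test_that("disc-union area matches closed forms for two discs", {
  # far apart: disjoint discs, area adds
  far <- build_buffer(target_areas("p", c("a", "b"), x = c(0, 1000),
                                   y = c(0, 0)), radius_m = 250)
  expect_equal(buffer_area(far), 2 * pi * 250^2, tolerance = 1e-9)
  # overlapping: union = 2 pi r^2 - lens (closed-form oracle)
  set.seed(4)
  for (d in c(100, 250, 400, 499)) {
    b <- build_buffer(target_areas("p", c("a", "b"), x = c(0, d), y = c(0, 0)),
                      radius_m = 250)
    expect_equal(buffer_area(b), two_disc_union_area(d, 250), tolerance = 1e-9)
    expect_lt(buffer_area(b), 2 * pi * 250^2)
  }
})

test_that("build_buffer validates input and is idempotent under duplication", {
  expect_error(build_buffer(target_areas("p", "a", x = 1, y = 1)[0, ]),
               class = "pa_structural_error")
  expect_error(target_areas("p", "a", x = Inf, y = 0),
               class = "pa_structural_error")
  two_parks <- target_areas(c("p", "q"), c("a", "b"), x = c(0, 1), y = c(0, 1))
  expect_error(build_buffer(two_parks), class = "pa_structural_error")
  expect_error(build_buffer(target_areas("p", "a", x = 0, y = 0), radius_m = 0),
               class = "pa_structural_error")
  one <- build_buffer(target_areas("p", "a", x = 5, y = 5), 250)
  dup <- build_buffer(target_areas("p", c("a", "a2", "a3"),
                                   x = rep(5, 3), y = rep(5, 3)), 250)
  expect_equal(buffer_area(dup), buffer_area(one), tolerance = 1e-12)
  expect_equal(buffer_contains(dup, c(5, 300), c(5, 5)),
               buffer_contains(one, c(5, 300), c(5, 5)))
})

test_that("containment is closed at the boundary and exact in between", {
  b <- build_buffer(target_areas("p", "a", x = 0, y = 0), 250)
  expect_true(buffer_contains(b, 0, 0))     # the target point itself
  expect_true(buffer_contains(b, 250, 0))   # on the boundary
  expect_false(buffer_contains(b, 251, 0))  # 251 m away
})

test_that("select_in_buffer matches the brute-force distance rule", {
  set.seed(15)
  areas <- target_areas("p", sprintf("a%d", 1:4),
                        x = runif(4, 0, 600), y = runif(4, 0, 600))
  b <- build_buffer(areas, 250)
  est <- random_establishments(400, frac = 0, extent = 1200)
  sel <- select_in_buffer(est, b)
  ax <- vapply(areas$geometry, function(g) g$coords[["x"]], numeric(1))
  ay <- vapply(areas$geometry, function(g) g$coords[["y"]], numeric(1))
  keep <- vapply(seq_len(nrow(est)), function(i) {
    min(sqrt((est$x[[i]] - ax)^2 + (est$y[[i]] - ay)^2)) <= 250 + 1e-9
  }, logical(1))
  expect_equal(sel$id, est$id[keep]) # same rows, input order preserved
})

test_that("selection grows monotonically with the radius", {
  set.seed(21)
  for (i in 1:10) {
    areas <- target_areas("p", sprintf("a%d", 1:3),
                          x = runif(3, 0, 500), y = runif(3, 0, 500))
    est <- random_establishments(150, frac = 0, extent = 1000)
    r1 <- runif(1, 50, 300)
    r2 <- r1 + runif(1, 10, 300)
    s1 <- select_in_buffer(est, build_buffer(areas, r1))
    s2 <- select_in_buffer(est, build_buffer(areas, r2))
    expect_true(all(s1$id %in% s2$id))
  }
})

test_that("a coordinate-system mismatch between layers is refused", {
  est <- random_establishments(5, frac = 0)
  attr(est, "crs") <- "EPSG:2263"
  b <- build_buffer(target_areas("p", "a", x = 0, y = 0), 250)
  attr(b, "crs") <- "EPSG:32618"
  expect_error(select_in_buffer(est, b), class = "pa_structural_error")
})

test_that("polygon target areas dilate with exact containment", {
  sq <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), 4, 2, byrow = TRUE)
  areas <- target_areas("p", "a", geometry = list(sq))
  b <- build_buffer(areas, 50)
  expect_true(buffer_contains(b, 50, 50))    # inside the polygon
  expect_true(buffer_contains(b, 150, 50))   # 50 m off the edge
  expect_false(buffer_contains(b, 151, 50))
  expect_false(buffer_contains(b, 136, 136)) # past the rounded corner
  expect_true(buffer_contains(b, 135, 135))  # sqrt(2)*35 < 50 from the corner
  # grid area close to the closed form for a convex polygon dilation
  expected <- 100^2 + 4 * 100 * 50 + pi * 50^2
  expect_equal(buffer_area(b), expected, tolerance = 0.005)
})

test_that("GeoJSON target areas round-trip and buffers export as polygons", {
  areas <- target_areas(c("p1", "p1", "p2"), c("a1", "a2", "b1"),
                        x = c(0, 120, 900), y = c(0, 50, 900))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_target_areas(areas, path)
  back <- read_target_areas(path)
  expect_equal(back$park_id, areas$park_id)
  expect_equal(back$area_id, areas$area_id)
  for (i in seq_len(nrow(areas))) {
    expect_equal(back$geometry[[i]]$coords, areas$geometry[[i]]$coords)
  }
  bufs <- lapply(split(areas, areas$park_id), build_buffer, radius_m = 250)
  bpath <- withr::local_tempfile(fileext = ".geojson")
  write_buffers(bufs, bpath)
  gj <- jsonlite::read_json(bpath)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2L)
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
  expect_error(read_target_areas(file.path(tempdir(), "missing.geojson")),
               class = "pa_structural_error")
})

test_that("local projection agrees with geodesic distances at city scale", {
  skip_if_not_installed("geosphere")
  origin <- c(-73.98, 40.73) # lower Manhattan
  set.seed(2)
  lon <- origin[1] + runif(20, -0.05, 0.05)
  lat <- origin[2] + runif(20, -0.05, 0.05)
  xy <- lonlat_to_local(lon, lat, origin)
  for (k in 1:10) {
    ij <- sample(20, 2)
    planar <- sqrt(diff(xy$x[ij])^2 + diff(xy$y[ij])^2)
    geo <- geosphere::distGeo(c(lon[ij[1]], lat[ij[1]]),
                              c(lon[ij[2]], lat[ij[2]]))
    expect_equal(planar, geo, tolerance = 0.005)
  }
})
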