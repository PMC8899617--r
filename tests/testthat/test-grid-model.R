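test_that("grid and time axis constructors enforce their invariants", {
  g <- tiny_grid(4, 6)
  expect_equal(grid_lats(g), c(1.75, 1.25, 0.75, 0.25))
  expect_equal(grid_lons(g)[1:2], c(10.25, 10.75))
  expect_error(grid_spec(2, 2, 0, 0, resolution = -1), "resolution")
  expect_error(grid_spec(2, 2, 90, 0, resolution = 0.5), "latitude")

  ta <- time_axis(seq(130, 10, by = -1))
  expect_equal(ta$step, 1)
  expect_equal(ta$span, 120)
  expect_error(time_axis(c(130, 129, 127)), "non-uniform")
  expect_error(time_axis(c(130, 131, 130)), "monotone")
  expect_error(time_axis(5), "at least 2")
})

test_that("land is defined as non-missing in every slice", {
  v <- array(500, dim = c(4, 4, 3))
  v[, 2, 2] <- NA       # one column missing in a single slice
  v[1, 1, ] <- NA       # one cell missing everywhere
  cube <- precip_cube(v, tiny_grid(), tiny_time())
  land <- land_mask(cube)
  # loop oracle: count non-missing slices per cell
  for (r in 1:4) for (c in 1:4) {
    expect_identical(land[r, c], sum(!is.na(v[r, c, ])) == 3L)
  }
  expect_false(any(land[, 2]))
  expect_equal(sum(land), 16 - 4 - 1)
})

test_that("negative precipitation is rejected", {
  v <- array(500, dim = c(2, 2, 2))
  v[1, 1, 1] <- -3
  expect_error(precip_cube(v, tiny_grid(2, 2), tiny_time(2)),
               "non-negative")
})

test_that("cell areas follow spherical geometry", {
  # mirrored latitudes and the cos(latitude) ratio
  g <- grid_spec(2, 1, lat_origin = 30, lon_origin = 0, resolution = 0.5)
  a30 <- cell_areas(g)[1, 1]
  gs <- grid_spec(2, 1, lat_origin = -29.5, lon_origin = 0, resolution = 0.5)
  expect_equal(cell_areas(gs)[2, 1], a30, tolerance = 1e-12)

  g2 <- grid_spec(121, 1, lat_origin = 60, lon_origin = 0, resolution = 0.5)
  a <- cell_areas(g2)
  ratio <- a[1, 1] / a[121, 1]     # 60N vs equator
  expect_equal(ratio, cos(60 * pi / 180), tolerance = 0.01)

  # full-sphere total within 0.1% of 4*pi*R^2
  gg <- grid_spec(180, 360, lat_origin = 89.5, lon_origin = -179.5,
                  resolution = 1)
  expect_equal(sum(cell_areas(gg)), 4 * pi * 6371^2,
               tolerance = 0.001)
})

test_that("area_fraction weights by area and reports counts", {
  g <- grid_spec(121, 1, lat_origin = 60, lon_origin = 0, resolution = 0.5)
  a <- cell_areas(g)
  # two-cell domain at 60N and equator; mask = equatorial cell
  domain <- matrix(FALSE, 121, 1); domain[c(1, 121), 1] <- TRUE
  mask <- matrix(FALSE, 121, 1); mask[121, 1] <- TRUE
  fr <- area_fraction(mask, a, domain)
  expect_equal(fr$area_fraction, 1 / 1.5, tolerance = 0.01)
  expect_equal(fr$count_fraction, 0.5)

  expect_equal(area_fraction(domain, a, domain)$area_fraction, 1)
  none <- matrix(FALSE, 121, 1)
  expect_equal(area_fraction(none, a, domain)$area_fraction, 0)
  expect_error(area_fraction(mask, a, none), "empty domain")
  expect_error(area_fraction(domain, a, mask), "outside the domain")
})

test_that("area_fraction is monotone and count/area agree on one latitude band", {
  g <- tiny_grid(1, 10)
  a <- cell_areas(g)
  domain <- matrix(TRUE, 1, 10)
  set.seed(11)
  mask <- matrix(FALSE, 1, 10)
  prev <- 0
  for (i in sample(10)) {
    mask[1, i] <- TRUE
    fr <- area_fraction(mask, a, domain)
    expect_gte(fr$area_fraction, prev)
    expect_equal(fr$area_fraction, fr$count_fraction)  # single-band grid
    prev <- fr$area_fraction
  }
})

test_that("precipitation cubes round-trip bit-identically through disk", {
  set.seed(42)
  cube <- random_precip_cube(5, 6, 4)
  cube$values[1, , ] <- NA   # sea row
  cube <- precip_cube(cube$values, cube$grid, cube$time)
  path <- withr::local_tempfile(fileext = ".csv")
  write_precip_cube(cube, path)
  back <- read_precipitation_cube(path)
  expect_identical(back$values, cube$values)
  expect_equal(back$grid, cube$grid)
  expect_equal(back$time, cube$time)
  expect_error(read_precipitation_cube(path, variable_name = "temp"),
               "missing variable")
})

test_that("cube files with a broken time axis are rejected with a diagnostic", {
  cube <- tiny_cube(2, 2, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_precip_cube(cube, path)
  txt <- readLines(path)
  txt[grepl("^# ages=", txt)] <- "# ages=130,129,127"
  writeLines(txt, path)
  expect_error(read_precipitation_cube(path), "non-uniform time axis")
})

test_that("biome cubes validate codes against the legend", {
  codes <- array(rep(1:16, length.out = 4 * 4 * 3), dim = c(4, 4, 3))
  legend16 <- read_biome_legend(system.file("extdata", "biome_legend_16.csv",
                                            package = "refugia"))
  expect_equal(nrow(legend16), 16)
  bc <- biome_cube(codes, tiny_grid(), tiny_time(), legend16)
  expect_s3_class(bc, "biome_cube")

  codes[1, 1, 1] <- 99L
  expect_error(biome_cube(codes, tiny_grid(), tiny_time(), legend16), "99")

  # legend superset of observed codes is fine, unused entries retained
  small <- array(1L, dim = c(2, 2, 2))
  bc2 <- biome_cube(small, tiny_grid(2, 2), tiny_time(2), legend16)
  expect_equal(nrow(bc2$legend), 16)
})

test_that("biome cube + legend round-trip through disk", {
  codes <- random_biome_codes(4, 5, 3, k = 4)
  codes[, 1, ] <- NA
  bc <- tiny_biome(codes, legend = simple_legend(4),
                   grid = tiny_grid(4, 5), time = tiny_time(3))
  p <- withr::local_tempfile(fileext = ".csv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_biome_cube(bc, p, lp)
  back <- read_biome_cube(p, lp)
  expect_identical(back$codes, bc$codes)
  expect_equal(back$legend, bc$legend)
})

test_that("rasters round-trip including nodata cells", {
  g <- tiny_grid(3, 4)
  layer <- matrix(runif(12, -5, 5), 3, 4)
  layer[2, 3] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  write_raster(layer, p, g)
  back <- read_raster(p)
  expect_equal(back$values, layer, tolerance = 1e-12)
  expect_equal(back$nodata, -9999)
  expect_equal(back$grid, g)

  m <- matrix(c(TRUE, FALSE, NA, TRUE, FALSE, TRUE), 2, 3)
  g2 <- tiny_grid(2, 3)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(m, p2, g2)
  back2 <- read_raster(p2, logical_layer = TRUE)
  expect_identical(back2$values, m)
  expect_equal(back2$nodata, 255)
})

test_that("point-in-cell lookup uses half-open [south, north) x [west, east)", {
  g <- tiny_grid(4, 4)  # lat centres 1.75..0.25, lon centres 10.25..11.75
  # cell centres map to their own cell
  idx <- cell_index(g, c(1.75, 0.25), c(10.25, 11.75))
  expect_equal(unname(idx[1, ]), c(1, 1))
  expect_equal(unname(idx[2, ]), c(4, 4))
  # shared horizontal edge at 1.5 belongs to the northern cell (row 1)
  expect_equal(unname(cell_index(g, 1.5, 10.25)[1, ]), c(1, 1))
  # shared vertical edge at 10.5 belongs to the eastern cell (col 2)
  expect_equal(unname(cell_index(g, 1.75, 10.5)[1, ]), c(1, 2))
  # outside the grid -> NA
  expect_true(all(is.na(cell_index(g, 50, 10.25)[1, ])))
  expect_true(all(is.na(cell_index(g, 1.75, 9)[1, ])))
  # top edge (north edge of row 1) is excluded
  expect_true(all(is.na(cell_index(g, 2.0, 10.25)[1, ])))
})
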