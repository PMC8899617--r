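site_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(site = r[[1]], horizon = r[[2]], age_central = r[[3]],
               age_min = r[[4]], age_max = r[[5]], lat = r[[6]],
               lon = r[[7]], region = r[[8]], stringsAsFactors = FALSE)
  }))
}

write_sites <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, p, row.names = FALSE)
  p
}

two_level_masks <- function(grid = tiny_grid(4, 4)) {
  narrow <- matrix(FALSE, 4, 4); narrow[2:3, 2:3] <- TRUE
  broad <- matrix(FALSE, 4, 4); broad[1:4, 2:4] <- TRUE
  broad <- broad | narrow
  list(
    narrow = structure(list(grid = grid, level = "narrow", mask = narrow,
                            thresholds = threshold_pair(248, 1403)),
                       class = "refugia_mask"),
    broad = structure(list(grid = grid, level = "broad", mask = broad,
                           thresholds = threshold_pair(127, 3286)),
                      class = "refugia_mask")
  )
}

test_that("site tables load with validation and row-level rejection", {
  good <- site_rows(
    list("A", "h1", 50, 45, 55, 1.3, 10.3, "north"),
    list("A", "h2", 80, 75, 90, 1.3, 10.3, "north"),
    list("B", "h1", 20, 18, 22, 0.4, 11.4, "south"))
  tab <- load_site_table(write_sites(good))
  expect_equal(nrow(tab), 3)

  # age_min > age_max row is rejected with a warning naming the row
  bad <- good; bad$age_min[2] <- 95
  expect_warning(tab <- load_site_table(write_sites(bad)), "rows 2")
  expect_equal(nrow(tab), 2)

  # missing central age filled with the interval midpoint
  mid <- good; mid$age_central[1] <- NA
  tab <- load_site_table(write_sites(mid))
  expect_equal(tab$age_central[1], 50)

  expect_error(load_site_table(write_sites(good[, -3])), "missing column")
  expect_warning(load_site_table(write_sites(good[0, ])), "empty")
})

test_that("Late Pleistocene filter is inclusive at both window edges", {
  tab <- site_rows(
    list("A", "h1", 140, 130, 150, 1, 10.3, "north"),
    list("A", "h2", 130, 120, 140, 1, 10.3, "north"),
    list("A", "h3", 10, 8, 12, 1, 10.3, "north"),
    list("A", "h4", 9.5, 8, 11, 1, 10.3, "north"))
  out <- filter_late_pleistocene(tab)
  expect_equal(out$horizon, c("h2", "h3"))
})

test_that("zone assignment uses mask precedence and matches a per-record oracle", {
  msk <- two_level_masks()
  g <- msk$narrow$grid
  tab <- site_rows(
    list("N", "h", 50, 45, 55, grid_lats(g)[2], grid_lons(g)[2], "north"),
    list("B", "h", 50, 45, 55, grid_lats(g)[1], grid_lons(g)[4], "north"),
    list("O", "h", 50, 45, 55, grid_lats(g)[4], grid_lons(g)[1], "south"))
  asn <- assign_refugia_zone(tab, msk$narrow, msk$broad)
  expect_equal(asn$zone, c("narrow", "broad", "beyond"))

  set.seed(601)
  lat <- runif(80, min(grid_lats(g)) - 0.2, max(grid_lats(g)) + 0.2)
  lon <- runif(80, min(grid_lons(g)) - 0.2, max(grid_lons(g)) + 0.2)
  keep <- !is.na(cell_index(g, lat, lon)[, 1])
  tab <- data.frame(site = "s", horizon = "h", age_central = 50,
                    age_min = 45, age_max = 55,
                    lat = lat[keep], lon = lon[keep], region = "north")
  asn <- assign_refugia_zone(tab, msk$narrow, msk$broad)
  oracle <- vapply(seq_len(nrow(tab)), function(i) {
    oracle_zone(tab$lat[i], tab$lon[i], g, msk$narrow$mask, msk$broad$mask)
  }, character(1))
  expect_identical(asn$zone, oracle)

  # zone counts partition the record set
  zc <- zone_counts(asn)
  expect_equal(zc$narrow[1] + zc$broad[1] + zc$beyond[1], zc$total[1])
  expect_equal(zc$total[1], nrow(tab))

  # points off the grid are an error listing the record
  tab$lat[1] <- 89
  expect_error(assign_refugia_zone(tab, msk$narrow, msk$broad),
               "outside the grid")

  # non-nested masks rejected
  msk$narrow$mask[1, 1] <- TRUE
  expect_error(assign_refugia_zone(tab, msk$narrow, msk$broad), "nested")
})

test_that("occupation histograms bin [10,20)...[120,130] and conserve counts", {
  msk <- two_level_masks()
  g <- msk$narrow$grid
  mk <- function(ages) {
    data.frame(site = "s", horizon = "h", age_central = ages,
               age_min = ages - 1, age_max = ages + 1,
               lat = grid_lats(g)[2], lon = grid_lons(g)[2],
               region = rep(c("north", "south"), length.out = length(ages)))
  }
  asn <- assign_refugia_zone(mk(c(15, 15, 25)), msk$narrow, msk$broad)
  h <- occupation_histogram(asn)
  get <- function(lo) sum(h$n[h$bin_lower == lo])
  expect_equal(get(10), 2)
  expect_equal(get(20), 1)
  expect_equal(sum(h$n), 3)

  # edge ages: 130 goes in the closed top bin, 10 in the first
  asn <- assign_refugia_zone(mk(c(10, 130, 120, 19.999)), msk$narrow, msk$broad)
  h <- occupation_histogram(asn)
  expect_equal(get(10), 2)
  expect_equal(get(120), 2)

  # marginal over zones equals the zone-blind histogram
  set.seed(602)
  asn <- assign_refugia_zone(mk(runif(60, 10, 130)), msk$narrow, msk$broad)
  h <- occupation_histogram(asn)
  marg <- tapply(h$n, h$bin_lower, sum)
  plain <- hist(asn$age_central, breaks = seq(10, 130, 10), plot = FALSE)$counts
  expect_equal(as.integer(marg[order(as.numeric(names(marg)))]), plain)
  expect_equal(sum(h$n), 60)

  # empty input -> all-zero table
  h0 <- occupation_histogram(asn[0, ])
  expect_true(all(h0$n == 0))
})

test_that("continuity gaps: touching dated ranges leave exactly the printed gap", {
  # ranges 92-70 ka and 69-58 ka: a single 1-kyr gap at 70-69 ka
  recs <- data.frame(age_min = c(70, 58), age_max = c(92, 69))
  gaps <- continuity_gaps(recs)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$gap_start, 69)
  expect_equal(gaps$gap_end, 70)
  expect_equal(gaps$duration_kyr, 1)

  # overlapping ranges leave no gap
  recs <- data.frame(age_min = c(40, 30), age_max = c(50, 45))
  expect_equal(nrow(continuity_gaps(recs, window = c(30, 50))), 0)

  # three disjoint intervals -> two gaps, checked against a sweep oracle
  recs <- data.frame(age_min = c(20, 50, 90), age_max = c(30, 70, 110))
  gaps <- continuity_gaps(recs)
  expect_equal(nrow(gaps), 2)
  expect_equal(gaps$gap_start, c(30, 70))
  expect_equal(gaps$gap_end, c(50, 90))
  expect_equal(sum(gaps$duration_kyr),
               oracle_gaps_total(recs$age_min, recs$age_max, c(20, 110)),
               tolerance = 0.01)

  # covered + gaps = window length; order of records is irrelevant
  set.seed(603)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    lo <- runif(n, 10, 120); hi <- lo + runif(n, 1, 15)
    recs <- data.frame(age_min = lo, age_max = hi)
    g1 <- continuity_gaps(recs, window = c(10, 130))
    g2 <- continuity_gaps(recs[sample(n), ], window = c(10, 130))
    expect_equal(g1, g2)
    expect_equal(sum(g1$duration_kyr),
                 oracle_gaps_total(lo, hi, c(10, 130)), tolerance = 0.05)
  }
})
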