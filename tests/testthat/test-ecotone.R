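of_from_codes <- function(codes, forest_from = 3) {
  k <- max(codes, na.rm = TRUE)
  bc <- tiny_biome(codes, legend = simple_legend(k, forest_from),
                   grid = tiny_grid(dim(codes)[1], dim(codes)[2]),
                   time = tiny_time(dim(codes)[3]))
  reclassify_open_forest(bc)
}

test_that("open/forest reclassification follows the lookup exactly", {
  codes <- array(c(1, 2, 3, 4), dim = c(2, 2, 1))
  codes <- array(rep(codes, 2), dim = c(2, 2, 2))
  ofc <- of_from_codes(codes, forest_from = 3)
  expect_equal(ofc$class[1, 1, 1], 1L)  # code 1 open
  expect_equal(ofc$class[1, 2, 1], 2L)  # code 3 forest

  set.seed(501)
  codes <- random_biome_codes(4, 4, 5, k = 4)
  ofc <- of_from_codes(codes, forest_from = 3)
  lk <- c("1" = "open", "2" = "open", "3" = "forest", "4" = "forest")
  for (r in 1:4) for (c in 1:4) for (t in 1:5) {
    expect_equal(ofc$class[r, c, t],
                 if (lk[as.character(codes[r, c, t])] == "open") 1L else 2L)
  }

  # unmapped code fails with a diagnostic
  bc <- tiny_biome(codes, legend = simple_legend(4),
                   grid = tiny_grid(4, 4), time = tiny_time(5))
  expect_error(reclassify_open_forest(bc, lookup = c("1" = "open")),
               "does not map")
})

test_that("stability classes split stable/changing with majority labelling", {
  always_forest <- of_from_codes(array(3L, dim = c(1, 1, 4)))
  expect_equal(stability_class(always_forest)[1, 1], "stable_forest")

  always_open <- of_from_codes(array(1L, dim = c(1, 1, 4)))
  expect_equal(stability_class(always_open)[1, 1], "stable_open")

  # 70% open / 30% forest -> changing_open
  v <- c(rep(1L, 7), rep(3L, 3))
  expect_equal(stability_class(of_from_codes(array(v, c(1, 1, 10))))[1, 1],
               "changing_open")
  # majority forest
  v <- c(rep(1L, 3), rep(3L, 7))
  expect_equal(stability_class(of_from_codes(array(v, c(1, 1, 10))))[1, 1],
               "changing_forest")
  # exact tie -> changing_open by convention
  v <- c(1L, 3L)
  expect_equal(stability_class(of_from_codes(array(v, c(1, 1, 2))))[1, 1],
               "changing_open")
})

test_that("stable cells have zero open/forest transitions", {
  set.seed(502)
  codes <- random_biome_codes(6, 6, 8, k = 4)
  ofc <- of_from_codes(codes)
  stab <- stability_class(ofc)
  of_bc <- tiny_biome(ofc$class, legend = simple_legend(2, forest_from = 2),
                      grid = tiny_grid(6, 6), time = tiny_time(8))
  trans <- transition_count(of_bc)
  stable <- stab %in% c("stable_open", "stable_forest")
  expect_true(all(trans[matrix(stable, 6, 6)] == 0L))
  expect_true(all(trans[matrix(!stable, 6, 6)] > 0L))
})

test_that("ecotone slices flag 3x3 windows containing both classes", {
  # uniform open grid: no ecotone anywhere
  uni <- matrix(1L, 4, 4)
  expect_true(all(ecotone_slice(uni) == FALSE))

  # vertical open|forest split: only the two boundary-adjacent columns
  split <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 2))
  eco <- ecotone_slice(split)
  expect_true(all(eco[, 2:3]))
  expect_true(all(!eco[, c(1, 4)]))

  # swapping labels leaves the ecotone mask unchanged
  swapped <- ifelse(split == 1L, 2L, 1L)
  expect_identical(ecotone_slice(swapped), eco)

  # sea neighbours are ignored; sea cells carry NA
  sp <- split; sp[1, ] <- NA
  eco2 <- ecotone_slice(sp)
  expect_true(all(is.na(eco2[1, ])))
  expect_true(all(eco2[2:4, 2:3]))

  set.seed(503)
  for (i in 1:30) {
    m <- matrix(sample(c(1L, 2L, NA), 49, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), 7, 7)
    expect_identical(ecotone_slice(m), oracle_ecotone_slice(m))
  }
})

test_that("ecotone persistence fractions and classes follow the definitions", {
  # a boundary that never moves: boundary cells are persistent
  codes <- array(rep(cbind(matrix(1L, 4, 2), matrix(3L, 4, 2)), 5),
                 dim = c(4, 4, 5))
  ofc <- of_from_codes(codes)
  ep <- ecotone_persistence(ofc)
  expect_true(all(ep$class[, 2:3] == "persistent"))
  expect_true(all(ep$fraction[, 2:3] == 1))
  expect_true(all(ep$class[, c(1, 4)] == "never"))

  # ecotonal in 60 of 121 slices -> fraction just under 0.5 -> intermittent
  n_t <- 121
  codes <- array(1L, dim = c(1, 2, n_t))
  codes[1, 2, 1:60] <- 3L
  ep <- ecotone_persistence(of_from_codes(codes))
  expect_equal(ep$fraction[1, 1], 60 / 121)
  expect_equal(ep$class[1, 1], "intermittent")

  # 61 of 121 crosses one half -> at_least_half
  codes[1, 2, 1:61] <- 3L
  ep <- ecotone_persistence(of_from_codes(codes))
  expect_equal(ep$class[1, 1], "at_least_half")

  # class boundaries are exact on the counts
  expect_true(all(ep$fraction >= 0 & ep$fraction <= 1, na.rm = TRUE))
})

test_that("label-swap symmetry holds for the full ecotone pipeline", {
  set.seed(504)
  codes <- random_biome_codes(6, 6, 6, k = 4)
  ofc <- of_from_codes(codes)
  swapped <- ofc
  swapped$class <- ifelse(ofc$class == 1L, 2L, 1L)
  ep1 <- ecotone_persistence(ofc)
  ep2 <- ecotone_persistence(swapped)
  expect_identical(ep1$fraction, ep2$fraction)
  expect_identical(ep1$class, ep2$class)
})

test_that("a persistent ecotone cell always sees the other class in its window", {
  set.seed(505)
  codes <- random_biome_codes(8, 8, 5, k = 2)  # k=2: open=1 is code<3
  ofc <- of_from_codes(codes, forest_from = 2)
  ep <- ecotone_persistence(ofc)
  pers <- which(ep$class == "persistent", arr.ind = TRUE)
  for (i in seq_len(nrow(pers))) {
    r <- pers[i, 1]; c <- pers[i, 2]
    for (t in 1:5) {
      win <- ofc$class[max(1, r - 1):min(8, r + 1),
                       max(1, c - 1):min(8, c + 1), t]
      expect_true(any(win != ofc$class[r, c, t]))
    }
  }
})
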