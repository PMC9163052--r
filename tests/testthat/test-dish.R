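# Dish geometry, initial patterns, neighbourhoods, IO and injuries.

test_that("circular dish has the discrete disk geometry and pattern", {
  spec <- pattern_spec("circle", 20, 10)
  d <- build_dish(spec, seed = 3)
  c0 <- 21
  dist <- sqrt(outer((seq_len(41) - c0)^2, (seq_len(41) - c0)^2, `+`))
  expect_equal(sum(d$valid), sum(dist <= 20))
  # region labels partition the valid mask exactly
  expect_true(all((d$region > 0) == d$valid))
  # inner-disk non-dividing occupants are all A; outer all B
  inner <- d$region == 1L
  occ_inner <- d$occ[inner & !(d$occ %in% c(1L, 2L))]
  expect_true(all(occ_inner == 3L))
  occ_outer <- d$occ[d$region == 2L & !(d$occ %in% c(1L, 2L))]
  expect_true(all(occ_outer == 4L))
  # signals loaded by region
  expect_true(all(d$s1[inner] == 100L))
  expect_true(all(d$s2[inner] == 0L))
  # occupancy/validity/signal invariants
  expect_true(all(d$occ[!d$valid] == 0L))
  expect_true(all(d$s1[!d$valid] == 0L) && all(d$s2[!d$valid] == 0L))
  expect_true(all(d$s1 >= 0) && all(d$s2 >= 0))
})

test_that("dividing fractions control the scattered cells", {
  d <- build_dish(pattern_spec("circle", 12, 6,
                               dividing_fraction_S = 0,
                               dividing_fraction_P = 0.1), seed = 2)
  cen <- dish_census(d)
  expect_equal(cen$n_S, 0)
  expect_equal(cen$n_P, round(0.1 * sum(d$valid)))
  d2 <- build_dish(pattern_spec("circle", 12, 6, dividing_fraction_S = 0,
                                dividing_fraction_P = 0), seed = 2)
  expect_equal(dish_census(d2)$n_S + dish_census(d2)$n_P, 0)
})

test_that("dish construction is reproducible under a fixed seed", {
  a <- build_dish(pattern_spec("circle", 10, 5), seed = 77)
  b <- build_dish(pattern_spec("circle", 10, 5), seed = 77)
  expect_identical(a, b)
})

test_that("polygonal geometries partition as designed", {
  sq <- build_dish(pattern_spec("square", 20), seed = 1)
  expect_equal(dim(sq$valid), c(20L, 20L))
  expect_true(all(sq$valid))
  expect_equal(sum(sq$region == 1L), 100) # 10 x 10 inner square
  rect <- build_dish(pattern_spec("rectangle", 20), seed = 1)
  expect_equal(dim(rect$valid), c(10L, 20L))
  tri <- build_dish(pattern_spec("triangle", 21), seed = 1)
  expect_true(sum(tri$valid) < 21 * 21 / 2 + 21) # raster half-square
  expect_true(all(tri$region[tri$valid] %in% 1:2))
  expect_gt(sum(tri$region == 1L), 0)
})

test_that("label matrices round-trip through files and dishes", {
  lm <- matrix(0L, 9, 9)
  lm[3:7, 3:7] <- 2L
  lm[4:6, 4:6] <- 1L
  path <- withr::local_tempfile(fileext = ".txt")
  write_label_matrix(lm, path)
  expect_identical(read_label_matrix(path), lm)
  d <- build_dish(pattern_spec("labelfile", label_matrix = lm), seed = 5)
  expect_identical(d$region, lm)
  # full dish snapshot round trip
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_dish_snapshot(d, p2)
  d2 <- read_dish_snapshot(p2)
  for (f in c("occ", "x", "y", "div", "s1", "s2", "region")) {
    expect_identical(d2[[f]], d[[f]], info = f)
  }
  expect_identical(d2$valid, d$valid)
})

test_that("neighbourhoods respect dish boundaries and adjacency kind", {
  sq <- build_dish(pattern_spec("square", 10), seed = 1)
  expect_equal(nrow(neighbors(sq, c(5, 5), "full8")), 8)
  expect_equal(nrow(neighbors(sq, c(5, 5), "orthogonal4")), 4)
  expect_equal(nrow(neighbors(sq, c(1, 1), "orthogonal4")), 2) # corner
  expect_equal(nrow(neighbors(sq, c(1, 1), "full8")), 3)
  circ <- build_dish(pattern_spec("circle", 6, 3), seed = 1)
  # a valid mesh on the rim has fewer than 8 in-dish neighbours
  rim <- which(circ$valid)[1]
  m <- c((rim - 1) %% circ$height + 1, (rim - 1) %/% circ$height + 1)
  nb <- neighbors(circ, m, "full8")
  expect_true(all(circ$valid[nb]))
  expect_lt(nrow(nb), 8)
})

test_that("random empty mesh is uniform over the empty meshes", {
  d <- build_dish(pattern_spec("square", 8,
                               dividing_fraction_S = 0,
                               dividing_fraction_P = 0), seed = 1)
  # free 16 meshes, leave the rest occupied
  free <- sample(which(d$valid), 16)
  d$occ[] <- 4L
  d$occ[free] <- 0L
  set.seed(42)
  draws <- replicate(8000, {
    m <- random_empty_mesh(d)
    (m[2] - 1) * d$height + m[1]
  })
  tab <- table(factor(draws, levels = free))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  d$occ[free] <- 4L
  expect_null(random_empty_mesh(d)) # full dish: movement is a no-op
})

test_that("injuries remove exactly the occupants of the region", {
  d <- build_dish(pattern_spec("circle", 10, 5), seed = 4)
  n0 <- sum(d$occ > 0)
  spec <- injury_spec("circle", center = c(11, 11), size = 4, trigger = 1)
  reg <- stemdish:::injury_region(d, spec)
  hit <- sum(d$occ[reg] > 0)
  d2 <- apply_injury(d, spec)
  expect_equal(sum(d2$occ > 0), n0 - hit)
  expect_identical(d2$s1, d$s1) # signal molecules stay in place
  # whole-dish injury empties the dish
  d3 <- apply_injury(d, injury_spec("mask", mask = d$valid, trigger = 1))
  expect_equal(sum(d3$occ > 0), 0)
  # disjoint region leaves the dish unchanged
  far <- injury_spec("rect", center = c(1, 1), size = c(1, 1), trigger = 1)
  d4 <- apply_injury(d, far)
  expect_lte(sum(d$occ > 0) - sum(d4$occ > 0), 1)
})
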