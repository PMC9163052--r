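# Deterministic switch layer: drift fields, signal effect, fixed points,
# basins and fate classification.

test_that("stem drift matches the Hill form at reference points", {
  d0 <- stem_drift(0, 0)
  expect_equal(c(d0$rate_x, d0$rate_y), c(85, 100))
  # x = 0, y large: Hill repression kills X synthesis, Y synthesis at max
  dl <- stem_drift(0, 1e6)
  expect_lt(dl$rate_x, 1e-6)
  expect_equal(dl$rate_y + 1e6, 100) # production term at max, decay linear
  # hand-computed at (45, 45): Hill terms are exactly 1/2
  dm <- stem_drift(45, 45)
  expect_equal(dm$rate_x, 85 / 2 - 45)
  expect_equal(dm$rate_y, 100 / 2 - 45)
  expect_error(stem_drift(-1, 0), "non-negative")
})

test_that("progenitor drift includes self-activation and signal effect", {
  d0 <- progenitor_drift(0, 0)
  expect_equal(c(d0$rate_x, d0$rate_y), c(30, 30))
  # saturated activation: production -> (alpha + eps) + iota * rep(y)
  p <- tristable_params(eps_x = 10)
  dl <- progenitor_drift(1e5, 0, p)
  prod_x <- dl$rate_x + 0.38 * 1e5
  expect_equal(prod_x, (30 + 10) + 30, tolerance = 1e-6)
})

test_that("signal effect is the continuous saturating piecewise form", {
  expect_equal(signal_effect(0), 0)
  expect_equal(signal_effect(30), 10) # saturated branch, a = 10, b = 15
  expect_equal(signal_effect(15), 10) # both branches agree at s = b
  s <- 0:60
  v <- signal_effect(s)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 10))
  expect_error(signal_effect(-1), "non-negative")
})

test_that("signal reaction rates follow the reaction-diffusion terms", {
  r0 <- signal_reaction_rates(0, 0)
  expect_equal(r0$prod1, 220)
  expect_equal(r0$deg1, 0)
  rl <- signal_reaction_rates(0, 1e6)
  expect_lt(rl$prod1, 1e-6)
  # D = 0 ODE pair is bistable: each species near alpha/k or near 0
  fp <- find_fixed_points("signal")
  st <- fp[fp$stable, ]
  expect_equal(nrow(st), 2)
  expect_true(all(abs(pmax(st$x, st$y) - 220 / 0.5) < 1))
  expect_true(all(pmin(st$x, st$y) < 1))
})

test_that("fixed-point counts and Jacobian stability match the design", {
  fs <- find_fixed_points("stem")
  expect_equal(sum(fs$stable), 2)
  expect_true(all(fs$eig_max_re[fs$stable] < 0))
  st <- fs[fs$stable, ]
  expect_true(any(st$x > 10 * st$y))       # x-dominant (S)
  expect_true(any(st$y > 10 * st$x))       # y-dominant (P)
  fp <- find_fixed_points("progenitor")
  expect_equal(sum(fp$stable), 3)
  expect_true(all(fp$eig_max_re[fp$stable] < 0))
  bal <- fp[fp$stable & abs(fp$x - fp$y) < 1, ]
  expect_equal(nrow(bal), 1) # balanced attractor present
})

test_that("fate classification is consistent with basin geometry", {
  expect_equal(as.character(classify_fate(200, 0, "stem")), "S")
  expect_equal(as.character(classify_fate(0, 200, "stem")), "P")
  expect_equal(as.character(classify_fate(0, 200, "progenitor")), "B")
  expect_equal(as.character(classify_fate(200, 0, "progenitor")), "A")
  expect_equal(as.character(classify_fate(80, 80, "progenitor")), "P")
  # idempotence: a state at a stable fixed point classifies as itself
  fp <- find_fixed_points("progenitor")
  st <- fp[fp$stable, ]
  lab <- classify_fate(round(st$x), round(st$y), "progenitor")
  expect_equal(as.character(lab[abs(st$x - st$y) < 1]), "P")
})

test_that("basin maps have the expected label structure", {
  sm <- basin_map("stem", resolution = 51)
  expect_setequal(unique(as.vector(sm$grid)), c(1L, 2L))
  pm <- basin_map("progenitor", resolution = 51)
  expect_setequal(unique(as.vector(pm$grid)), c(2L, 3L, 4L))
  # three-region structure: balanced region flanked by dominant regions
  mid <- round(ncol(pm$grid) * 0.4)
  expect_equal(pm$grid[mid, mid], 2L)                 # diagonal: P
  expect_equal(pm$grid[nrow(pm$grid), 1], 3L)          # x axis: A
  expect_equal(pm$grid[1, ncol(pm$grid)], 4L)          # y axis: B
  # symmetric parameters: map symmetric under (x, y) -> (y, x) up to
  # the tie-broken boundary (labels swap A <-> B)
  g <- pm$grid
  gs <- t(g)
  swapped <- gs
  swapped[gs == 3L] <- 4L
  swapped[gs == 4L] <- 3L
  expect_gt(mean(g == swapped), 0.98)
})

test_that("raising eps_x grows the A basin monotonically", {
  res <- 41
  n_A <- vapply(c(0, 5, 10), function(e) {
    m <- basin_map("progenitor", tristable_params(eps_x = e),
                   extent = 200, resolution = res)
    sum(m$grid == 3L)
  }, double(1))
  expect_true(all(diff(n_A) >= 0))
  expect_gt(n_A[3], n_A[1])
})

test_that("basin sampling returns states that classify to the label", {
  sm <- basin_map("stem", resolution = 76)
  set.seed(5)
  draws <- sample_from_basin(200, "P", map = sm)
  lab <- classify_fate(draws$x, draws$y, "stem")
  expect_true(all(lab == "P"))
  # seeded reproducibility
  set.seed(9); a <- sample_from_basin(10, "S", map = sm)
  set.seed(9); b <- sample_from_basin(10, "S", map = sm)
  expect_identical(a, b)
  expect_error(sample_from_basin(1, "A", map = sm), "empty")
})

test_that("density-dependent synthesis rate is anchored and decreasing", {
  expect_equal(iota_xs_of_n(100, 85, 100), 85)
  expect_equal(iota_xs_of_n(50, 85, 100), 85) # at or below calibration
  n <- seq(100, 2000, by = 50)
  v <- iota_xs_of_n(n, 85, 100)
  expect_true(all(diff(v) < 0))
  expect_lt(iota_xs_of_n(1e8, 85, 100), 1e-3) # vanishes in the limit
})

test_that("drift evaluations stay finite on extreme states", {
  d <- stem_drift(c(0, 1e6, 3), c(1e6, 0, 4))
  expect_true(all(is.finite(c(d$rate_x, d$rate_y))))
  d2 <- progenitor_drift(c(0, 1e6), c(1e6, 1e6))
  expect_true(all(is.finite(c(d2$rate_x, d2$rate_y))))
})
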