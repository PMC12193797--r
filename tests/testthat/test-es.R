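test_that("water yield is the water balance, clamped and division-free", {
  p <- const_raster(matrix(c(1000, 500, 0, 300), 2, 2))
  a <- const_raster(matrix(c(400, 600, 0, 300), 2, 2))
  y <- water_yield(p, a)
  expect_equal(y$values, matrix(c(600, 0, 0, 0), 2, 2))  # AET > P clamps to 0
  # AET = 0 -> Y = P
  expect_equal(water_yield(p, const_raster(0, 2, 2))$values, p$values)
  # conservation identity over the whole grid
  expect_equal(sum(y$values), sum(p$values) - sum(pmin(a$values, p$values)))
  expect_error(water_yield(const_raster(-1, 2, 2), a), ">= 0")
})

test_that("carbon stock sums the four pools by class", {
  wood <- cat_raster(matrix(2L, 3, 3), cell_size = 100)
  tab <- carbon_density_table()
  cs <- carbon_stock(wood, tab)
  expect_true(all(cs$values == with(tab[tab$class == "woodland", ],
                                    above + below + soil + dead)))
  # all-zero table -> zero raster
  z <- carbon_density_table(above = stats::setNames(rep(0, 6), names(lu_classes)),
                            below = stats::setNames(rep(0, 6), names(lu_classes)),
                            soil = stats::setNames(rep(0, 6), names(lu_classes)),
                            dead = stats::setNames(rep(0, 6), names(lu_classes)))
  expect_true(all(carbon_stock(wood, z)$values == 0))

  # mixed 10-cell toy, hand-summed total
  m <- cat_raster(matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L), 2, 5),
                  cell_size = 100)
  cs2 <- carbon_stock(m, tab)
  d <- with(tab, stats::setNames((above + below + soil + dead) * mult, class))
  expect_equal(sum(cs2$values), 3 * d[["cropland"]] + 7 * d[["woodland"]])

  # regional total is invariant under count-preserving relabeling
  perm <- cat_raster(matrix(c(2L, 2L, 1L, 2L, 1L, 2L, 2L, 2L, 1L, 2L), 2, 5),
                     cell_size = 100)
  expect_equal(sum(carbon_stock(perm, tab)$values), sum(cs2$values))

  # class missing from the table is named in the error
  bad <- tab[tab$class != "woodland", ]
  expect_error(carbon_stock(m, bad), "woodland")
})

test_that("threat degradation matches the brute-force pairwise oracle", {
  cfg <- habitat_config(threats = list(
    list(source = "builtup", weight = 1, d_max = 250, decay = "linear",
         sensitivity = c(cropland = 0.5, woodland = 0.9, grassland = 0.6,
                         water = 0.7, builtup = 0, unused = 0.3)),
    list(source = "cropland", weight = 0.4, d_max = 400, decay = "exponential",
         sensitivity = c(cropland = 0, woodland = 0.6, grassland = 0.4,
                         water = 0.5, builtup = 0, unused = 0.2))))
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(12L, 24L, 32L)[seed]
    lulc <- cat_raster(matrix(sample(1:6, n * n, replace = TRUE,
                                     prob = c(.3, .3, .2, .05, .1, .05)), n, n))
    got <- threat_degradation(lulc, cfg)
    expect_lt(max(abs(got$values - degradation_oracle(lulc, cfg))), 1e-9)
  }
})

test_that("degradation kernel endpoints behave: zero beyond d_max, maximal at the source", {
  v <- matrix(2L, 9, 9); v[5, 5] <- 5L  # one built-up cell in woodland
  lulc <- cat_raster(v, cell_size = 100)
  cfg <- habitat_config(threats = list(
    list(source = "builtup", weight = 1, d_max = 200, decay = "linear",
         sensitivity = c(cropland = 1, woodland = 1, grassland = 1,
                         water = 1, builtup = 1, unused = 1))))
  D <- threat_degradation(lulc, cfg)$values
  expect_equal(D[5, 7], 0)            # exactly at d_max (2 cells)
  expect_equal(D[1, 1], 0)            # far beyond
  expect_equal(max(D), D[5, 5])       # distance 0 is maximal
  expect_equal(D[5, 6], 0.5)          # halfway down the linear kernel

  # no threat cells at all -> zero raster
  none <- cat_raster(matrix(2L, 9, 9), cell_size = 100)
  expect_true(all(threat_degradation(none, cfg)$values == 0))
})

test_that("habitat quality saturates as designed and stays in [0, 1]", {
  lulc <- cat_raster(matrix(2L, 4, 4), cell_size = 100)
  H <- habitat_config()$habitat[["woodland"]]
  cfg0 <- habitat_config(k = 1)
  # D = 0 -> Q = H_j
  q0 <- habitat_quality(lulc, cfg0, degradation = const_raster(0, 4, 4, 100))
  expect_true(all(q0$values == H))
  # D = k -> Q = H_j / 2 (half-saturation)
  qk <- habitat_quality(lulc, cfg0, degradation = const_raster(1, 4, 4, 100))
  expect_equal(qk$values, matrix(H / 2, 4, 4))
  # strictly decreasing in D
  ds <- seq(0, 5, by = 0.25)
  qs <- vapply(ds, function(d) {
    habitat_quality(lulc, cfg0, degradation = const_raster(d, 4, 4, 100))$values[1, 1]
  }, 0)
  expect_true(all(diff(qs) < 0))
  expect_true(all(qs >= 0 & qs <= 1))
  expect_error(habitat_quality(lulc, habitat_config(k = 0),
                               degradation = const_raster(1, 4, 4, 100)), "k")
})

test_that("soil retention follows RUSLE with the cover-practice discount", {
  lulc <- cat_raster(matrix(1L, 2, 2), cell_size = 30)
  f <- rusle_factors(R = const_raster(100, 2, 2), K_soil = const_raster(0.3, 2, 2),
                     LS = const_raster(2, 2, 2),
                     C_cover = c(cropland = 0.5, woodland = 0, grassland = 0,
                                 water = 0, builtup = 0, unused = 0),
                     P_practice = c(cropland = 0.8, woodland = 1, grassland = 1,
                                    water = 1, builtup = 1, unused = 1))
  A <- soil_retention(lulc, f)
  expect_equal(A$values, matrix(100 * 0.3 * 2 * (1 - 0.4), 2, 2))  # = 36
  # C = 0 -> A = R K LS, and that is always an upper bound
  f0 <- rusle_factors(R = const_raster(100, 2, 2), K_soil = const_raster(0.3, 2, 2),
                      LS = const_raster(2, 2, 2),
                      C_cover = stats::setNames(rep(0, 6), names(lu_classes)))
  expect_equal(soil_retention(lulc, f0)$values, matrix(60, 2, 2))
  expect_true(all(A$values <= 100 * 0.3 * 2))
  # out-of-range lookups rejected
  expect_error(rusle_factors(R = const_raster(1, 2, 2), K_soil = const_raster(1, 2, 2),
                             LS = const_raster(1, 2, 2),
                             C_cover = c(cropland = 1.2, woodland = 0, grassland = 0,
                                         water = 0, builtup = 0, unused = 0)))
})

test_that("erosivity power law is exact and monotone", {
  p <- const_raster(matrix(c(0, 100, 400, 900), 2, 2))
  expect_equal(erosivity_from_precip(p, a = 1, b = 1)$values, p$values)
  expect_equal(erosivity_from_precip(p, a = 1, b = 1)$values[1, 1], 0)
  r <- erosivity_from_precip(p)$values
  expect_true(all(diff(r[order(p$values)]) > 0))
  expect_error(erosivity_from_precip(const_raster(-5, 2, 2)), ">= 0")
})

test_that("LS factor is zero on flat terrain and grows with slope", {
  flat <- ls_from_dem(raster_grid(matrix(100, 16, 16), cell_size = 30))
  expect_true(all(flat$values == flat$values[1, 1]))
  expect_equal(flat$values[1, 1], 0)
  ls_at_gradient <- function(g) {
    z <- matrix(rep(seq_len(16) * g, each = 16), 16, 16)
    ls_from_dem(raster_grid(z, cell_size = 30))$values[8, 8]
  }
  vals <- vapply(c(1, 5, 10, 20), ls_at_gradient, 0)
  expect_true(all(diff(vals) > 0))
  # deterministic (no RNG anywhere)
  expect_identical(ls_at_gradient(5), ls_at_gradient(5))
})

test_that("the four services respect their ranges on seeded landscapes", {
  for (seed in 1:3) {
    land <- generate_landscape(small_config(seed = seed, shape = c(48L, 48L)))
    es <- es_stack(land$lulc_t1, land$precip, land$aet, land$dem)
    expect_true(all(es$hq$values >= 0 & es$hq$values <= 1))
    expect_true(all(es$wy$values >= 0))
    expect_true(all(es$cs$values >= 0))
    expect_true(all(es$sr$values >= 0))
  }
})
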