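test_that("expansion sampling recovers known conversions and flags static classes", {
  nr <- 40; nc <- 40
  set.seed(7)
  t0v <- matrix(sample(c(1L, 3L), nr * nc, replace = TRUE), nr, nc)
  t1v <- t0v
  conv <- sample(which(t0v != 5L), 500)
  t1v[conv] <- 5L
  t0 <- cat_raster(t0v); t1 <- cat_raster(t1v)
  drv <- list(d1 = const_raster(matrix(rnorm(nr * nc), nr, nc), cell_size = 100))

  s <- extract_samples(t0, t1, drv, fraction = 1, seed = 2)
  expect_equal(sum(s$samples$builtup$label == 1), 500)
  expect_equal(sum(s$samples$builtup$label == 0), 500)
  expect_true(all(s$static[c("woodland", "water", "unused")]))
  expect_false(s$static["builtup"])

  # determinism of the draw
  s2 <- extract_samples(t0, t1, drv, fraction = 1, seed = 2)
  expect_identical(s$samples, s2$samples)

  # no change at all -> everything static
  s3 <- extract_samples(t0, t0, drv)
  expect_true(all(s3$static))
})

test_that("suitability fitting separates a threshold rule and ranks its driver first", {
  skip_if_not_installed("pROC")
  nr <- 60; nc <- 60
  set.seed(11)
  d1 <- matrix(runif(nr * nc), nr, nc)
  d2 <- matrix(runif(nr * nc), nr, nc)
  t0v <- matrix(1L, nr, nc)
  t1v <- t0v
  t1v[d1 > 0.8] <- 5L  # growth follows driver d1, noise-free
  t0 <- cat_raster(t0v); t1 <- cat_raster(t1v)
  drv <- list(d1 = const_raster(d1, cell_size = 100),
              d2 = const_raster(d2, cell_size = 100))
  # fit on the left half, hold out the right half
  left <- function(r) { v <- r$values; v[, (nc/2 + 1):nc] <- NA
                        raster_grid(v, r$cell_size, r$categorical) }
  s <- extract_samples(left(t0), left(t1), drv, seed = 4)
  suit <- fit_suitability(s, drv, seed = 4)
  expect_equal(unname(which.max(suit$importance["builtup", ])), 1L)
  held <- (col(t1v) > nc / 2)
  auc <- pROC::auc(pROC::roc(as.integer(t1v[held] == 5L),
                             suit$probs$builtup$values[held], quiet = TRUE))
  expect_gte(as.numeric(auc), 0.99)
})

test_that("an all-static landscape yields an all-zero suitability stack", {
  t0 <- cat_raster(matrix(c(1L, 2L), 10, 10))
  drv <- list(d1 = const_raster(matrix(rnorm(100), 10, 10), cell_size = 100))
  s <- extract_samples(t0, t0, drv)
  suit <- fit_suitability(s, drv)
  for (k in names(lu_classes))
    expect_true(all(suit$probs[[k]]$values == 0))
})

test_that("neighbourhood effect counts Moore neighbours with edge normalization", {
  uni <- cat_raster(matrix(2L, 10, 10))
  ne <- neighborhood_effect(uni, "woodland")
  expect_true(all(ne$values == 1))  # uniform map: every neighbour matches

  v <- matrix(1L, 5, 5); v[3, 3] <- 5L
  ne5 <- neighborhood_effect(cat_raster(v), "builtup")
  expect_equal(ne5$values[2, 2], 1 / 8)
  expect_equal(ne5$values[3, 3], 0)     # centre excluded
  expect_equal(ne5$values[1, 1], 0)     # out of reach
  # corner cell of a uniform map still normalizes to its 3 real neighbours
  expect_equal(neighborhood_effect(uni, "woodland")$values[1, 1], 1)

  empty <- neighborhood_effect(uni, "water")
  expect_true(all(empty$values == 0))

  expect_error(neighborhood_effect(uni, "woodland", window = 4), "odd")
})

test_that("allocation with demand equal to current counts returns the input", {
  v <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
  lulc <- cat_raster(v)
  dem <- tabulate(v, 6)
  st <- ca_state(lulc, dem, seed = 1)
  suit <- manual_suitability(list(), 20, 20)
  out <- allocate(st, suit)
  expect_identical(out$values, lulc$values)
  expect_true(out$converged)
  expect_equal(out$iterations, 0L)
})

test_that("allocation targets the high-suitability region", {
  nr <- 50; nc <- 50
  lulc <- cat_raster(matrix(1L, nr, nc))
  region <- matrix(0.05, nr, nc); region[1:15, ] <- 0.9
  suit <- manual_suitability(list(builtup = region), nr, nc)
  dem <- c(nr * nc - 100, 0, 0, 0, 100, 0)
  out <- allocate(ca_state(lulc, dem, seed = 3), suit)
  expect_true(out$converged)
  new5 <- which(out$values == 5L)
  expect_equal(length(new5), 100)
  expect_gte(sum(row(out$values)[new5] <= 15), 90)
})

test_that("allocation conserves cells, hits demand, and is seed-deterministic", {
  land <- generate_landscape(small_config(seed = 21L))
  drv <- list(dem = land$dem, slope = land$slope, precip = land$precip)
  s <- extract_samples(land$lulc_t0, land$lulc_t1, drv, seed = 5)
  suit <- fit_suitability(s, drv, seed = 5)
  cnt <- tabulate(land$lulc_t1$values, 6)
  dem <- cnt + c(-120, 60, -40, 0, 100, 0)
  st <- ca_state(land$lulc_t1, dem, seed = 9)
  out <- allocate(st, suit)
  expect_equal(sum(!is.na(out$values)), sum(!is.na(land$lulc_t1$values)))
  expect_true(out$converged)
  tol <- pmax(0, floor(0.001 * dem))
  expect_true(all(abs(tabulate(out$values, 6) - dem) <= tol))
  out2 <- allocate(ca_state(land$lulc_t1, dem, seed = 9), suit)
  expect_identical(out$values, out2$values)
  # demand not matching the cell count is rejected
  expect_error(allocate(ca_state(land$lulc_t1, dem + 1, seed = 9), suit),
               "must equal")
})

test_that("raising a class's demand never lowers its final count at fixed seed", {
  land <- generate_landscape(small_config(seed = 22L))
  drv <- list(dem = land$dem, slope = land$slope, precip = land$precip)
  s <- extract_samples(land$lulc_t0, land$lulc_t1, drv, seed = 5)
  suit <- fit_suitability(s, drv, seed = 5)
  cnt <- tabulate(land$lulc_t1$values, 6)
  counts5 <- vapply(c(50, 100, 200), function(extra) {
    dem <- cnt; dem[5] <- dem[5] + extra; dem[1] <- dem[1] - extra
    out <- allocate(ca_state(land$lulc_t1, dem, seed = 13), suit)
    tabulate(out$values, 6)[5]
  }, 0)
  expect_true(all(diff(counts5) >= 0))
})

test_that("allocation preferentially consumes top-decile suitability cells", {
  nr <- 60; nc <- 60
  set.seed(8)
  grad <- matrix(runif(nr * nc), nr, nc)
  lulc <- cat_raster(matrix(1L, nr, nc))
  suit <- manual_suitability(list(builtup = grad), nr, nc)
  n_new <- 200
  dem <- c(nr * nc - n_new, 0, 0, 0, n_new, 0)
  out <- allocate(ca_state(lulc, dem, seed = 4, tau = 0.5), suit)
  new5 <- which(out$values == 5L)
  top <- grad >= quantile(grad, 0.9)
  enrichment <- (sum(top[new5]) / length(new5)) / 0.1
  expect_gt(enrichment, 2)
})

test_that("agreement metrics match hand computations", {
  a <- cat_raster(matrix(1:4, 10, 10))
  expect_equal(agreement(a, a), list(overall_accuracy = 1, kappa = 1,
                                     confusion = agreement(a, a)$confusion))

  # confusion [[40,10],[10,40]] -> accuracy 0.8, kappa 0.6
  pred <- cat_raster(matrix(rep(c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L, 2L), 10), 10, 10))
  true <- cat_raster(matrix(rep(c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L), 10), 10, 10))
  ag <- agreement(pred, true)
  expect_equal(ag$overall_accuracy, 0.8)
  expect_equal(ag$kappa, 0.6)
  expect_equal(ag$confusion["cropland", "woodland"], 10)

  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  cm <- table(factor(pred$values, 1:6), factor(true$values, 1:6))
  ca <- e1071::classAgreement(cm)
  expect_equal(ag$overall_accuracy, ca$diag)
  expect_equal(ag$kappa, ca$kappa)
})

test_that("independent random maps have near-zero chance-corrected agreement", {
  set.seed(123)
  n <- 1e5
  a <- cat_raster(matrix(sample(1:6, n, replace = TRUE), 250, 400))
  b <- cat_raster(matrix(sample(1:6, n, replace = TRUE), 250, 400))
  expect_lt(abs(agreement(a, b)$kappa), 0.02)
})

test_that("agreement requires overlapping valid cells", {
  a <- cat_raster(matrix(c(1L, NA), 2, 2))
  b <- cat_raster(matrix(c(NA, 1L), 2, 2))
  expect_error(agreement(a, b), "overlap")
})
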