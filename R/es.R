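#' Annual water yield from the water balance
#'
#' Y = (1 - AET/P) * P = P - AET per cell, in mm, clamped at 0 where AET
#' exceeds P (negative annual yield is physically meaningless); cells with
#' P = 0 yield 0 without any division.
#'
#' @param precip,aet Aligned rasters of annual precipitation and actual
#'   evapotranspiration (mm), `precip >= 0`.
#' @return Continuous `raster_grid` (mm), >= 0.
#' @export
water_yield <- function(precip, aet) {
  stopifnot_aligned(precip, aet)
  if (any(precip$values < 0, na.rm = TRUE)) stop("precipitation must be >= 0")
  raster_grid(pmax(precip$values - aet$values, 0), cell_size = precip$cell_size)
}

#' Carbon density table
#'
#' Per-class densities of the four carbon pools (above-ground,
#' below-ground, soil, dead organic matter), t/hm^2, with an optional
#' per-class climate-correction multiplier (default 1). The default table
#' is SYNTHETIC: magnitudes plausible for subtropical south-west China,
#' for use with generated landscapes, not a calibrated regional dataset.
#'
#' @param above,below,soil,dead Named numeric vectors over the six classes.
#' @param mult Optional per-class multiplicative climate correction.
#' @return Data frame with one row per class.
#' @export
carbon_density_table <- function(
    above = c(cropland = 10.5, woodland = 35.0, grassland = 3.5,
              water = 0.5, builtup = 1.0, unused = 0.5),
    below = c(cropland = 2.5, woodland = 8.5, grassland = 8.0,
              water = 0.0, builtup = 0.5, unused = 0.1),
    soil  = c(cropland = 90, woodland = 120, grassland = 100,
              water = 60, builtup = 70, unused = 50),
    dead  = c(cropland = 1.5, woodland = 3.5, grassland = 1.0,
              water = 0.0, builtup = 0.0, unused = 0.0),
    mult = NULL) {
  cls <- names(lu_classes)
  if (is.null(mult)) mult <- stats::setNames(rep(1, 6), cls)
  tab <- data.frame(class = cls, above = above[cls], below = below[cls],
                    soil = soil[cls], dead = dead[cls], mult = mult[cls],
                    row.names = NULL)
  if (any(is.na(tab[-1L])) || any(tab[c("above", "below", "soil", "dead")] < 0))
    stop("carbon densities must be non-negative and cover all six classes")
  tab
}

#' Carbon stock per cell
#'
#' C_total = (C_above + C_below + C_soil + C_dead) x multiplier for the
#' cell's land-use class, t/hm^2.
#'
#' @param lulc Categorical `raster_grid`.
#' @param table A [carbon_density_table()].
#' @return Continuous `raster_grid` (t/hm^2).
#' @export
carbon_stock <- function(lulc, table = carbon_density_table()) {
  stopifnot(lulc$categorical)
  present <- unique(lulc$values[!is.na(lulc$values)])
  missing_cls <- setdiff(names(lu_classes)[present], table$class)
  if (length(missing_cls))
    stop("carbon table is missing class(es): ", paste(missing_cls, collapse = ", "))
  dens <- with(table, (above + below + soil + dead) * mult)
  names(dens) <- table$class
  out <- matrix(dens[names(lu_classes)[lulc$values]],
                nrow(lulc$values), ncol(lulc$values))
  raster_grid(out, cell_size = lulc$cell_size)
}

#' Habitat configuration
#'
#' Habitat suitability per class, the threat sources with their weights,
#' decay kernels and per-class sensitivities, plus the saturation
#' parameters of the quality response. Defaults treat cropland and
#' built-up land as the habitat stress factors, with woodland the most
#' suitable and most sensitive habitat.
#'
#' @param habitat Named suitability H_j per class, in `[0, 1]`.
#' @param threats List of threats, each a list with `source` (class
#'   name(s)), `weight` W_r in `[0, 1]`, `d_max` (m), `decay`
#'   (`"linear"` or `"exponential"`), and `sensitivity` S_jr (named per
#'   class, `[0, 1]`).
#' @param beta Accessibility multiplier, scalar or raster, in `[0, 1]`.
#' @param z Saturation exponent.
#' @param k Half-saturation constant; `NULL` = half the observed maximum
#'   degradation, recomputed per run.
#' @return Object of class `habitat_config`.
#' @export
habitat_config <- function(
    habitat = c(cropland = 0.3, woodland = 1.0, grassland = 0.7,
                water = 0.9, builtup = 0.0, unused = 0.1),
    threats = list(
      list(source = "cropland", weight = 0.6, d_max = 600, decay = "linear",
           sensitivity = c(cropland = 0.0, woodland = 0.6, grassland = 0.45,
                           water = 0.5, builtup = 0.0, unused = 0.2)),
      list(source = "builtup", weight = 1.0, d_max = 1200, decay = "exponential",
           sensitivity = c(cropland = 0.5, woodland = 0.85, grassland = 0.6,
                           water = 0.7, builtup = 0.0, unused = 0.3))
    ),
    beta = 1, z = 2.5, k = NULL) {
  stopifnot(all(habitat >= 0 & habitat <= 1), length(threats) >= 1L)
  for (th in threats) {
    stopifnot(th$weight >= 0, th$weight <= 1, th$d_max > 0,
              th$decay %in% c("linear", "exponential"),
              all(th$sensitivity >= 0 & th$sensitivity <= 1))
  }
  structure(list(habitat = habitat[names(lu_classes)], threats = threats,
                 beta = beta, z = z, k = k),
            class = "habitat_config")
}

# Linear convolution of a (nonnegative) field with a radially symmetric
# distance kernel, zero-padded FFT; exact for the centre-to-centre
# Euclidean kernel up to floating point.
kernel_convolve <- function(ind, cell_size, d_max, decay) {
  nr <- nrow(ind); nc <- ncol(ind)
  half <- ceiling(d_max / cell_size)
  off <- seq(-half, half)
  d <- sqrt(outer(off^2, off^2, `+`)) * cell_size
  kern <- if (decay == "linear") pmax(0, 1 - d / d_max)
          else ifelse(d <= d_max, exp(-2.99 * d / d_max), 0)
  P <- nr + 2L * half; Q <- nc + 2L * half
  A <- matrix(0, P, Q); A[seq_len(nr), seq_len(nc)] <- ind
  B <- matrix(0, P, Q); B[seq_len(2L * half + 1L), seq_len(2L * half + 1L)] <- kern
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P * Q)
  conv[half + seq_len(nr), half + seq_len(nc)]
}

#' Total threat degradation per cell
#'
#' D_xj = sum over threats r and threat cells y of
#' (W_r / sum W) r_y i_rxy beta_x S_jr, with the distance response
#' i_rxy = max(0, 1 - d/d_max) (linear) or exp(-2.99 d/d_max) truncated at
#' d_max (exponential), d the Euclidean centre-to-centre distance.
#'
#' @param lulc Categorical `raster_grid`.
#' @param config A [habitat_config()].
#' @return Continuous `raster_grid` of degradation scores, >= 0.
#' @export
threat_degradation <- function(lulc, config = habitat_config()) {
  stopifnot(lulc$categorical, inherits(config, "habitat_config"))
  v <- lulc$values
  wsum <- sum(vapply(config$threats, `[[`, 0, "weight"))
  beta <- if (inherits(config$beta, "raster_grid")) config$beta$values else config$beta
  D <- matrix(0, nrow(v), ncol(v))
  for (th in config$threats) {
    ind <- matrix(0, nrow(v), ncol(v))
    ind[v %in% lu_classes[th$source]] <- 1
    if (!any(ind > 0)) next
    expo <- kernel_convolve(ind, lulc$cell_size, th$d_max, th$decay)
    expo[expo < 0] <- 0  # FFT round-off
    sens <- matrix(th$sensitivity[names(lu_classes)[v]], nrow(v), ncol(v))
    D <- D + (th$weight / wsum) * expo * sens
  }
  D <- D * beta
  D[is.na(v)] <- NA
  raster_grid(D, cell_size = lulc$cell_size)
}

#' Habitat quality per cell
#'
#' Q_xj = H_j (1 - D^z / (D^z + k^z)): suitability of the cell's class
#' scaled down by half-saturated degradation, so Q = H_j where D = 0 and
#' Q = H_j/2 where D = k. Q is in `[0, 1]` and strictly decreasing in D.
#'
#' @param lulc Categorical `raster_grid`.
#' @param config A [habitat_config()]. If `config$k` is `NULL`, k is set
#'   to half the observed maximum degradation (0.5 if degradation is zero
#'   everywhere).
#' @param degradation Optional precomputed [threat_degradation()] raster.
#' @return Continuous `raster_grid` in `[0, 1]`.
#' @export
habitat_quality <- function(lulc, config = habitat_config(), degradation = NULL) {
  stopifnot(lulc$categorical)
  if (is.null(degradation)) degradation <- threat_degradation(lulc, config)
  stopifnot_aligned(lulc, degradation, check_mask = FALSE)
  D <- degradation$values
  k <- config$k
  if (is.null(k)) {
    dmax <- suppressWarnings(max(D, na.rm = TRUE))
    k <- if (is.finite(dmax) && dmax > 0) dmax / 2 else 0.5
  }
  if (k <= 0) stop("half-saturation constant k must be > 0")
  z <- config$z
  H <- matrix(config$habitat[names(lu_classes)[lulc$values]],
              nrow(lulc$values), ncol(lulc$values))
  Q <- H * (1 - D^z / (D^z + k^z))
  raster_grid(Q, cell_size = lulc$cell_size)
}

#' Rainfall erosivity from annual precipitation
#'
#' Power-law R = a P^b. The default coefficients (a = 0.0668, b = 1.6266)
#' are a widely used annual-precipitation erosivity fit for south-west
#' China; both are configurable.
#'
#' @param precip Annual precipitation raster (mm), >= 0.
#' @param a,b Power-law coefficients.
#' @return Erosivity raster (MJ mm / (hm^2 h a)).
#' @export
erosivity_from_precip <- function(precip, a = 0.0668, b = 1.6266) {
  if (any(precip$values < 0, na.rm = TRUE)) stop("precipitation must be >= 0")
  raster_grid(a * precip$values^b, cell_size = precip$cell_size)
}

# D8 receiver index (steepest descent among the 8 neighbours) and flow
# accumulation in cells; pits and flats accumulate but do not drain.
d8_accumulation <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  sh <- expand.grid(dr = -1:1, dc = -1:1)
  sh <- sh[!(sh$dr == 0 & sh$dc == 0), ]
  best_drop <- matrix(-Inf, nr, nc)
  rec <- matrix(0L, nr, nc)
  ri <- row(z); ci <- col(z)
  for (i in seq_len(nrow(sh))) {
    r2 <- ri + sh$dr[i]; c2 <- ci + sh$dc[i]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    idx2 <- (c2 - 1L) * nr + r2
    drop <- matrix(-Inf, nr, nc)
    drop[ok] <- (z[ok] - z[idx2[ok]]) / sqrt(sh$dr[i]^2 + sh$dc[i]^2)
    upd <- ok & drop > best_drop & drop > 0
    best_drop[upd] <- drop[upd]
    rec[upd] <- idx2[upd]
  }
  acc <- rep(1, n)
  for (i in order(z, decreasing = TRUE)) {
    r <- rec[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  matrix(acc, nr, nc)
}

#' Slope-length (LS) factor from a DEM
#'
#' Standard unit-stream-power formulation: LS = (A_s / 22.13)^m *
#' (sin(theta) / 0.0896)^n, with A_s the D8 flow-accumulation specific
#' area (upslope cells x cell size) and theta the slope. Flat terrain
#' yields the minimal constant 0.
#'
#' @param dem Elevation raster (m).
#' @param m,n Length and steepness exponents.
#' @return LS factor raster, >= 0.
#' @export
ls_from_dem <- function(dem, m = 0.4, n = 1.3) {
  slope <- slope_from_dem(dem)
  acc <- d8_accumulation(dem$values, dem$cell_size)
  As <- acc * dem$cell_size
  ls <- (As / 22.13)^m * (sin(slope$values * pi / 180) / 0.0896)^n
  raster_grid(ls, cell_size = dem$cell_size)
}

#' RUSLE factor bundle
#'
#' @param R,K_soil,LS Erosivity, soil-erodibility and slope-length factor
#'   rasters, all >= 0.
#' @param C_cover,P_practice Named per-class cover-management and
#'   support-practice lookups in `[0, 1]`. Defaults: dense woodland lowest
#'   C, cropland with terracing-style practice.
#' @return Object of class `rusle_factors`.
#' @export
rusle_factors <- function(R, K_soil, LS,
                          C_cover = c(cropland = 0.22, woodland = 0.006,
                                      grassland = 0.04, water = 0.0,
                                      builtup = 0.2, unused = 0.8),
                          P_practice = c(cropland = 0.35, woodland = 1.0,
                                         grassland = 1.0, water = 0.0,
                                         builtup = 1.0, unused = 1.0)) {
  for (r in list(R, K_soil, LS))
    if (any(r$values < 0, na.rm = TRUE)) stop("RUSLE factor rasters must be >= 0")
  stopifnot(all(C_cover >= 0 & C_cover <= 1), all(P_practice >= 0 & P_practice <= 1))
  structure(list(R = R, K_soil = K_soil, LS = LS,
                 C_cover = C_cover[names(lu_classes)],
                 P_practice = P_practice[names(lu_classes)]),
            class = "rusle_factors")
}

#' Soil retention per cell (RUSLE)
#'
#' A = R K LS (1 - C P), t/hm^2: the erosion avoided by the cell's cover
#' and practice factors relative to bare conditions.
#'
#' @param lulc Categorical `raster_grid`.
#' @param factors A [rusle_factors()] bundle aligned with `lulc`.
#' @return Continuous `raster_grid` (t/hm^2), >= 0.
#' @export
soil_retention <- function(lulc, factors) {
  stopifnot(lulc$categorical, inherits(factors, "rusle_factors"))
  stopifnot_aligned(lulc, factors$R, factors$K_soil, factors$LS,
                    check_mask = FALSE)
  cls <- names(lu_classes)[lulc$values]
  C <- matrix(factors$C_cover[cls], nrow(lulc$values), ncol(lulc$values))
  P <- matrix(factors$P_practice[cls], nrow(lulc$values), ncol(lulc$values))
  cp <- C * P
  if (any(cp > 1, na.rm = TRUE))
    stop("C x P exceeds 1 somewhere; retention would be negative")
  A <- factors$R$values * factors$K_soil$values * factors$LS$values * (1 - cp)
  raster_grid(A, cell_size = lulc$cell_size)
}

#' Compute the four ecosystem services for one landscape
#'
#' Convenience wrapper: water yield from P and AET, carbon stock from the
#' density table, habitat quality from the threat configuration, and
#' RUSLE soil retention with erosivity derived from precipitation, a
#' constant default erodibility and the DEM-derived LS factor.
#'
#' @param lulc Categorical land-use raster.
#' @param precip,aet Climate rasters (mm).
#' @param dem Elevation raster (m).
#' @param carbon_table A [carbon_density_table()].
#' @param habitat A [habitat_config()].
#' @param k_soil Soil-erodibility raster, or a scalar (default 0.03)
#'   expanded to the grid.
#' @return Named list of rasters: `wy`, `cs`, `hq`, `sr`.
#' @export
es_stack <- function(lulc, precip, aet, dem,
                     carbon_table = carbon_density_table(),
                     habitat = habitat_config(), k_soil = 0.03) {
  if (!inherits(k_soil, "raster_grid"))
    k_soil <- raster_grid(matrix(k_soil, nrow(lulc$values), ncol(lulc$values)),
                          cell_size = lulc$cell_size)
  rf <- rusle_factors(R = erosivity_from_precip(precip),
                      K_soil = k_soil, LS = ls_from_dem(dem))
  list(wy = water_yield(precip, aet),
       cs = carbon_stock(lulc, carbon_table),
       hq = habitat_quality(lulc, habitat),
       sr = soil_retention(lulc, rf))
}
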