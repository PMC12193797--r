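#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the seeded generator: grid shape, target class
#' fractions, spatial autocorrelation, climate field parameters and the
#' ground-truth land-use transition rules. One integer seed fully
#' determines all generated artifacts; each artifact draws from its own
#' deterministic sub-stream so that, e.g., regenerating the terrain does
#' not perturb the land-use noise.
#'
#' Default class fractions follow the 2030 composition of a forested
#' plateau urban agglomeration (woodland-dominated, ~20% cropland, little
#' water/built-up/unused). Default climate means are the two
#' emission-scenario means used by [rcp_climate_params()].
#'
#' @param shape Integer (rows, cols), each >= 16.
#' @param seed Integer master seed.
#' @param class_fractions Six non-negative fractions summing to 1, in
#'   `lu_classes` order.
#' @param autocorrelation_length Correlation length of all noise fields, in
#'   cells; maps to the spectral cutoff of the power-law noise.
#' @param cell_size Cell edge, metres.
#' @param elev_base,elev_amplitude Mean elevation and vertical relief (m).
#' @param climate List of climate-field parameters; see
#'   [rcp_climate_params()] for the scenario presets. Fields: `precip_mean`
#'   (mm), `precip_lapse` (mm per m of elevation), `precip_trend` (mm per
#'   km southward), `precip_noise_sd` (mm), `temp_mean` (deg C),
#'   `temp_lapse` (deg C per 100 m, negative), `temp_noise_sd`,
#'   `aet_fraction` (mean AET/P ratio), `aet_fraction_sd`.
#' @param change_rules Data frame (`from`, `to`, `rate`) of per-decade
#'   conversion propensities: `rate` is the fraction of `from`-class cells
#'   that convert to `to`, chosen where the destination class's generating
#'   suitability (plus neighbourhood contagion) is highest. This is the
#'   known ground truth the allocation stage is asked to recover.
#' @param spectral_exponent Power-law falloff exponent of the noise
#'   spectrum beyond the cutoff.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(shape = c(200L, 200L),
                             seed = 1L,
                             class_fractions = c(cropland = 0.2023,
                                                 woodland = 0.4908,
                                                 grassland = 0.2684,
                                                 water = 0.0131,
                                                 builtup = 0.0239,
                                                 unused = 0.0015),
                             autocorrelation_length = 8,
                             cell_size = 30,
                             elev_base = 1900,
                             elev_amplitude = 600,
                             climate = rcp_climate_params("RCP4.5"),
                             change_rules = default_change_rules(),
                             spectral_exponent = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop("'shape' must be two integers, each >= 16")
  if (length(class_fractions) != 6L || any(class_fractions < 0))
    stop("'class_fractions' must be six non-negative numbers")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("'class_fractions' must sum to 1")
  names(class_fractions) <- names(lu_classes)
  structure(list(shape = shape, seed = as.integer(seed),
                 class_fractions = class_fractions,
                 autocorrelation_length = autocorrelation_length,
                 cell_size = cell_size,
                 elev_base = elev_base, elev_amplitude = elev_amplitude,
                 climate = climate, change_rules = change_rules,
                 spectral_exponent = spectral_exponent),
            class = "synthetic_config")
}

#' Climate parameters for the two emission scenarios
#'
#' Presets whose regional means match the study area's downscaled 2030
#' climate under moderate (RCP4.5: 851.55 mm, 16.55 deg C) and high
#' (RCP8.5: 1080.60 mm, 16.47 deg C) greenhouse-gas forcing.
#'
#' @param scenario `"RCP4.5"` or `"RCP8.5"`.
#' @return A list of climate-field parameters for [synthetic_config()].
#' @export
rcp_climate_params <- function(scenario = c("RCP4.5", "RCP8.5")) {
  scenario <- match.arg(scenario)
  base <- list(precip_lapse = 0.05, precip_trend = 8, precip_noise_sd = 60,
               temp_lapse = -0.6, temp_noise_sd = 0.3,
               aet_fraction = 0.6, aet_fraction_sd = 0.08)
  if (scenario == "RCP4.5")
    c(list(precip_mean = 851.55, temp_mean = 16.55), base)
  else
    c(list(precip_mean = 1080.60, temp_mean = 16.47), base)
}

#' Default ground-truth transition rules
#'
#' Emulates the historical trend of the study system: built-up expansion
#' into cropland and woodland around existing settlements, cropland
#' reclamation of grassland, lake-margin water spread, plus the smaller
#' counter-flows real decade-scale change always shows (afforestation of
#' grassland, farmland-to-forest return, reclamation and degradation of
#' marginal land), so every class has some expansion over the period.
#'
#' @return Data frame with columns `from`, `to`, `rate`.
#' @export
default_change_rules <- function() {
  data.frame(
    from = c("cropland", "woodland", "grassland", "grassland", "cropland",
             "unused",    "grassland", "cropland", "cropland",  "grassland"),
    to   = c("builtup",  "builtup",  "cropland",  "builtup",   "water",
             "grassland", "woodland",  "woodland", "grassland", "unused"),
    rate = c(0.040,      0.008,      0.020,       0.010,       0.005,
             0.010,       0.015,       0.005,      0.010,       0.001),
    stringsAsFactors = FALSE
  )
}

# Zero-mean, unit-variance random field with power-law spectral falloff.
# Amplitude filter A(k) = (1 + (k * L)^2)^(-beta/2): flat below the cutoff
# 1/L (k in cycles per cell), power-law k^-beta above it, so L is the
# autocorrelation length in cells.
spectral_noise <- function(nr, nc, acl, beta = 3, seed = 1L) {
  fx <- (seq_len(nc) - 1) / nc
  fx <- ifelse(fx > 0.5, fx - 1, fx)
  fy <- (seq_len(nr) - 1) / nr
  fy <- ifelse(fy > 0.5, fy - 1, fy)
  k <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- (1 + (k * acl)^2)^(-beta / 2)
  amp[1, 1] <- 0  # zero the DC component
  z <- with_seed(seed, {
    matrix(stats::rnorm(nr * nc), nr, nc) +
      1i * matrix(stats::rnorm(nr * nc), nr, nc)
  })
  f <- Re(stats::fft(z * amp, inverse = TRUE)) / sqrt(nr * nc)
  s <- stats::sd(f)
  if (s == 0) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}

#' Generate synthetic terrain
#'
#' DEM as a smooth spectral-noise surface (mean `elev_base`, relief set by
#' `elev_amplitude`) plus its slope map in degrees.
#'
#' @param config A [synthetic_config()].
#' @return List with `dem` and `slope` rasters.
#' @export
generate_terrain <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$shape[1]; nc <- config$shape[2]
  n <- spectral_noise(nr, nc, config$autocorrelation_length,
                      config$spectral_exponent,
                      substream(config$seed, "terrain"))
  dem <- raster_grid(config$elev_base + config$elev_amplitude * n,
                     cell_size = config$cell_size)
  list(dem = dem, slope = slope_from_dem(dem))
}

#' Generate synthetic climate fields
#'
#' Precipitation and temperature as configured spatial trend + elevation
#' lapse + seeded autocorrelated noise; actual evapotranspiration as a
#' clamped fraction field of precipitation, so `0 <= aet <= precip`
#' cellwise by construction. Negative precipitation after noise is clipped
#' to 0 (a message reports how many cells).
#'
#' @param dem DEM raster from [generate_terrain()].
#' @param config A [synthetic_config()].
#' @return List with `precip`, `temp`, `aet` rasters (mm, deg C, mm).
#' @export
generate_climate <- function(dem, config) {
  stopifnot(inherits(dem, "raster_grid"), inherits(config, "synthetic_config"))
  cl <- config$climate
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  dz <- dem$values - mean(dem$values)
  # north-south trend, km from the grid's central row (southward positive)
  south_km <- (row(dem$values) - (nr + 1) / 2) * dem$cell_size / 1000
  noise <- function(label) {
    spectral_noise(nr, nc, config$autocorrelation_length,
                   config$spectral_exponent, substream(config$seed, label))
  }
  p <- cl$precip_mean + cl$precip_lapse * dz + cl$precip_trend * south_km +
    cl$precip_noise_sd * noise("precip")
  n_clip <- sum(p < 0)
  if (n_clip > 0) {
    message(sprintf("generate_climate: %d negative precipitation cells clipped to 0", n_clip))
    p[p < 0] <- 0
  }
  tmp <- cl$temp_mean + cl$temp_lapse * dz / 100 +
    cl$temp_noise_sd * noise("temp")
  frac <- cl$aet_fraction + cl$aet_fraction_sd * noise("aet")
  frac <- pmin(pmax(frac, 0), 1)
  list(precip = raster_grid(p, cell_size = dem$cell_size),
       temp   = raster_grid(tmp, cell_size = dem$cell_size),
       aet    = raster_grid(frac * p, cell_size = dem$cell_size))
}

# Per-class latent suitability fields: driver-weighted + autocorrelated
# noise. Rows of the weight matrix are (dem, slope, precip) z-score
# weights; chosen so woodland/unused sit high and steep, cropland/built-up
# low and flat, water in valley bottoms.
class_latent_fields <- function(dem, slope, precip, config, noise_weight = 0.6) {
  z <- function(m) {
    s <- stats::sd(m)
    if (s == 0) m * 0 else (m - mean(m)) / s
  }
  zd <- z(dem$values); zs <- z(slope$values); zp <- z(precip$values)
  w <- rbind(
    cropland  = c(-0.6, -0.8,  0.2),
    woodland  = c( 0.6,  0.4,  0.4),
    grassland = c( 0.3,  0.1, -0.2),
    water     = c(-1.0, -0.6,  0.2),
    builtup   = c(-0.7, -0.9, -0.1),
    unused    = c( 1.2,  0.8, -0.3)
  )
  nr <- nrow(zd); nc <- ncol(zd)
  out <- vector("list", 6L)
  names(out) <- names(lu_classes)
  for (k in names(lu_classes)) {
    n <- spectral_noise(nr, nc, config$autocorrelation_length,
                        config$spectral_exponent,
                        substream(config$seed, paste0("latent_", k)))
    out[[k]] <- w[k, 1] * zd + w[k, 2] * zs + w[k, 3] * zp + noise_weight * n
  }
  out
}

#' Generate a pair of land-use maps with known transition truth
#'
#' The date-1 map is built by rank-thresholding driver-weighted latent
#' suitability fields, which realizes the configured class fractions
#' exactly up to integer rounding. The date-2 map applies the configured
#' `change_rules`: for each rule, the `rate` fraction of source-class cells
#' with the highest destination suitability (latent field plus a
#' neighbourhood-contagion bonus) convert. The generating latent fields are
#' returned as ground truth for testing suitability recovery.
#'
#' @param dem,climate Outputs of [generate_terrain()] / [generate_climate()]
#'   (`dem` the DEM raster, `climate` the list with `precip`).
#' @param config A [synthetic_config()].
#' @return List with categorical rasters `lulc_t0`, `lulc_t1` and `truth`
#'   (the applied `change_rules` plus the per-class latent fields).
#' @export
generate_lulc_pair <- function(dem, climate, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (abs(sum(config$class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  slope <- slope_from_dem(dem)
  stopifnot_aligned(dem, climate$precip)
  latent <- class_latent_fields(dem, slope, climate$precip, config)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  ncell <- nr * nc
  counts <- round(config$class_fractions * ncell)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + (ncell - sum(counts))
  lulc <- integer(ncell)
  # allocate scarce classes first so their best cells are still free
  for (k in names(sort(counts))) {
    if (counts[k] == 0) next
    free <- which(lulc == 0L)
    pick <- free[order(latent[[k]][free], decreasing = TRUE)[seq_len(counts[k])]]
    lulc[pick] <- lu_classes[[k]]
  }
  t0 <- matrix(lulc, nr, nc)

  t1 <- t0
  rules <- config$change_rules
  if (!is.null(rules) && nrow(rules) > 0) {
    for (i in seq_len(nrow(rules))) {
      from <- lu_classes[[rules$from[i]]]
      to <- lu_classes[[rules$to[i]]]
      rate <- rules$rate[i]
      if (rate <= 0) next
      src <- which(t1 == from & t0 == from)  # untouched source cells
      n_conv <- round(rate * sum(t0 == from))
      if (n_conv == 0 || length(src) == 0) next
      nb <- class_neighbor_fraction(t1, to, window = 3L)
      score <- latent[[rules$to[i]]][src] + 1.5 * nb[src]
      conv <- src[order(score, decreasing = TRUE)[seq_len(min(n_conv, length(src)))]]
      t1[conv] <- to
    }
  }
  list(lulc_t0 = raster_grid(t0, cell_size = config$cell_size, categorical = TRUE),
       lulc_t1 = raster_grid(t1, cell_size = config$cell_size, categorical = TRUE),
       truth = list(change_rules = rules, latent = latent))
}

#' Generate a full synthetic landscape
#'
#' Convenience wrapper running terrain, climate and the land-use pair in
#' sequence from one config.
#'
#' @param config A [synthetic_config()].
#' @return List with `dem`, `slope`, `precip`, `temp`, `aet`, `lulc_t0`,
#'   `lulc_t1`, `truth`.
#' @export
generate_landscape <- function(config = synthetic_config()) {
  terr <- generate_terrain(config)
  clim <- generate_climate(terr$dem, config)
  pair <- generate_lulc_pair(terr$dem, clim, config)
  c(terr, clim, pair)
}
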