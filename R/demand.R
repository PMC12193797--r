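#' Per-class land-use areas
#'
#' The decision vector of the demand stage: areas x1..x6 in hectares
#' (cropland, woodland, grassland, water, built-up, unused) plus the
#' population scalar P in 10^4 persons.
#'
#' @param areas Named (or ordered) numeric vector of six areas, ha, >= 0.
#' @param population Population in 10^4 persons (optional).
#' @return Object of class `land_use_areas`.
#' @export
land_use_areas <- function(areas, population = NA_real_) {
  stopifnot(length(areas) == 6L, all(areas >= 0 | is.na(areas)))
  areas <- stats::setNames(as.numeric(areas), names(lu_classes))
  structure(list(areas = areas, population = as.numeric(population)),
            class = "land_use_areas")
}

#' @export
print.land_use_areas <- function(x, ...) {
  cat("<land_use_areas> (ha)\n")
  print(round(x$areas, 2))
  if (!is.na(x$population))
    cat(sprintf("population: %.2f x 10^4 persons\n", x$population))
  cat(sprintf("total: %.2f ha\n", sum(x$areas)))
  invisible(x)
}

#' Cross-tabulate two land-use maps into a transition matrix
#'
#' Entry (i, j) is the area (ha) of cells that were class i at the first
#' date and class j at the second; the diagonal is persistence.
#'
#' @param lulc_t0,lulc_t1 Aligned categorical rasters.
#' @return 6 x 6 transition area matrix (ha), class `transition_matrix`.
#' @export
cross_tabulate <- function(lulc_t0, lulc_t1) {
  stopifnot(lulc_t0$categorical, lulc_t1$categorical)
  stopifnot_aligned(lulc_t0, lulc_t1)
  a <- factor(lulc_t0$values, levels = lu_classes)
  b <- factor(lulc_t1$values, levels = lu_classes)
  m <- table(a, b) * cell_area_ha(lulc_t0)
  m <- matrix(as.numeric(m), 6L, 6L,
              dimnames = list(names(lu_classes), names(lu_classes)))
  structure(m, class = c("transition_matrix", "matrix"))
}

#' Markov projection of land-use areas
#'
#' Converts the transition area matrix to its row-stochastic form P and
#' applies areas_{t+1} = areas_t P for `steps` periods. A class absent at
#' the first date keeps an identity row; if such a class nonetheless holds
#' area in the input vector, the projection is undefined and errors.
#'
#' @param areas A [land_use_areas()] (or named 6-vector, ha).
#' @param trans A `transition_matrix` from [cross_tabulate()] (areas, ha).
#' @param steps Number of transition periods (>= 1).
#' @return A [land_use_areas()]; total area is conserved.
#' @export
markov_project <- function(areas, trans, steps = 1L) {
  if (inherits(areas, "land_use_areas")) {
    pop <- areas$population
    a <- areas$areas
  } else {
    pop <- NA_real_
    a <- stats::setNames(as.numeric(areas), names(lu_classes))
  }
  stopifnot(length(a) == 6L, steps >= 1L)
  m <- unclass(trans)
  rs <- rowSums(m)
  p <- diag(6L)
  dimnames(p) <- dimnames(m)
  for (i in which(rs > 0)) p[i, ] <- m[i, ] / rs[i]
  if (any(rs == 0 & a > 0))
    stop("transition matrix has a zero source row for a class with nonzero area: ",
         paste(names(lu_classes)[rs == 0 & a > 0], collapse = ", "))
  for (s in seq_len(steps)) a <- as.numeric(a %*% p)
  land_use_areas(a, pop)
}

#' Default multi-objective programming parameters
#'
#' The constraint and objective coefficients of the 2030 land-use demand
#' model for the study region: per-hectare ecological benefit (million CNY)
#' for the ecological-protection objective, per-hectare economic benefit
#' for the economic-development objective, the fixed total area, population
#' carrying-capacity bounds (10^4 persons), food-security parameters,
#' per-class area bounds (policy baselines +/- 1%), per-capita built-up
#' land, and the minimum ecological-land share. Bound pairs are stored
#' sorted as `[lower, upper]`.
#'
#' @param nis_grassland Grassland area (ha) from the natural-increase
#'   projection, used as the grassland bound baseline (+/- 1%).
#' @return Named list of parameters consumed by [build_lp()].
#' @export
mop_params <- function(nis_grassland = 2950164.63) {
  list(
    s_total = 11141039.34,
    esv = c(cropland = 0.5, woodland = 2.72, grassland = 1.55,
            water = 16.12, builtup = -1.58, unused = 0.08),
    ec  = c(cropland = 12.88, woodland = 0.79, grassland = 7.74,
            water = 7.10, builtup = 785.85, unused = 0.001),
    pop_bounds = c(2127, 3050),
    food = list(per_capita_kg = 141.2, self_sufficiency = 1.1411,
                yield_kg_ha = 4316.24, multiple_cropping = 1.11,
                crop_share = 0.67),
    bounds = list(
      cropland  = c(0, Inf),
      woodland  = c(5413076.08, 5522431.16),           # 2020 area -/+ 1%
      grassland = sort(nis_grassland * c(0.99, 1.01)), # NIS projection -/+ 1%
      water     = c(146419.93, 164919.00),
      builtup   = c(332112.95, 367072.21),
      unused    = c(15849.30, 16049.16)
    ),
    per_capita_builtup_ha = 0.0109,
    eco_share = 0.75
  )
}

#' Build the land-use demand linear program
#'
#' Assembles the LP over (x1..x6, P): maximize the ecological (`"eps"`) or
#' economic (`"eds"`) benefit objective subject to the fixed total area,
#' population bounds, food security (crop production must cover per-capita
#' demand times the self-sufficiency factor), per-class area bounds,
#' per-capita built-up land, and ecological land (woodland + grassland +
#' water) of at least `eco_share` of the total area. P enters the food and
#' built-up constraints in persons (x 10^4).
#'
#' @param scenario `"eps"` (ecological protection) or `"eds"` (economic
#'   development).
#' @param params Parameter list from [mop_params()].
#' @return Object of class `lp_spec`: objective, variable bounds, and
#'   labelled constraint rows with senses.
#' @export
build_lp <- function(scenario = c("eps", "eds"), params = mop_params()) {
  scenario <- match.arg(scenario)
  vars <- c(names(lu_classes), "population")
  obj <- c(if (scenario == "eps") params$esv else params$ec, population = 0)
  lower <- c(vapply(params$bounds, `[`, 0, 1L), population = params$pop_bounds[1])
  upper <- c(vapply(params$bounds, `[`, 0, 2L), population = params$pop_bounds[2])
  names(lower) <- names(upper) <- vars
  bad <- names(lower)[lower > upper]
  if (length(bad))
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))

  f <- params$food
  rows <- list(
    total_area = list(
      a = c(rep(1, 6), 0), sense = "=", rhs = params$s_total),
    food_security = list(  # P*1e4*demand*ss <= x1*yield*mci*share
      a = c(-f$yield_kg_ha * f$multiple_cropping * f$crop_share, rep(0, 5),
            1e4 * f$per_capita_kg * f$self_sufficiency),
      sense = "<=", rhs = 0),
    builtup_per_capita = list(  # P*1e4*0.0109 <= x5
      a = c(0, 0, 0, 0, -1, 0, 1e4 * params$per_capita_builtup_ha),
      sense = "<=", rhs = 0),
    ecological_land = list(
      a = c(0, 1, 1, 1, 0, 0, 0), sense = ">=",
      rhs = params$eco_share * params$s_total)
  )
  A <- do.call(rbind, lapply(rows, `[[`, "a"))
  colnames(A) <- vars
  structure(list(scenario = scenario, objective = obj, sense = "max",
                 lower = lower, upper = upper,
                 A = A, con_sense = vapply(rows, `[[`, "", "sense"),
                 rhs = vapply(rows, `[[`, 0, "rhs"),
                 labels = names(rows)),
            class = "lp_spec")
}

#' @export
print.lp_spec <- function(x, ...) {
  cat(sprintf("<lp_spec> %s: maximize over %d variables, %d constraints + bounds\n",
              toupper(x$scenario), length(x$objective), nrow(x$A)))
  invisible(x)
}

# Express the lp_spec as the (A1, b1, A2, b2, A3, b3) blocks of
# boot::simplex, with finite bounds folded in as rows and the whole system
# uniformly rescaled so coefficients are O(1)-O(1e3) (the simplex pivot
# tolerance is absolute).
lp_blocks <- function(spec) {
  nv <- length(spec$objective)
  rows_a <- list(); rows_s <- character(); rows_b <- numeric(); labs <- character()
  add <- function(a, s, b, lab) {
    rows_a[[length(rows_a) + 1L]] <<- a
    rows_s <<- c(rows_s, s); rows_b <<- c(rows_b, b); labs <<- c(labs, lab)
  }
  for (i in seq_len(nrow(spec$A)))
    add(spec$A[i, ], spec$con_sense[i], spec$rhs[i], spec$labels[i])
  for (j in seq_len(nv)) {
    e <- numeric(nv); e[j] <- 1
    v <- names(spec$objective)[j]
    if (is.finite(spec$upper[j])) add(e, "<=", spec$upper[j], paste0(v, "_upper"))
    if (spec$lower[j] > 0) add(e, ">=", spec$lower[j], paste0(v, "_lower"))
  }
  A <- do.call(rbind, rows_a)
  scale <- max(abs(rows_b), 1) / 1e3
  list(A = A, sense = rows_s, b = rows_b, labels = labs, scale = scale)
}

# Minimal total-violation diagnosis: relax every constraint with a
# violation variable and minimize their sum; constraints still violated at
# the optimum form the reported infeasible set.
diagnose_infeasible <- function(blocks) {
  A <- blocks$A; b <- blocks$b / blocks$scale
  nv <- ncol(A); m <- nrow(A)
  V <- diag(m)
  obj <- c(numeric(nv), rep(1, m))
  i1 <- blocks$sense == "<="; i2 <- blocks$sense == ">="; i3 <- blocks$sense == "="
  mk <- function(idx, sgn) if (any(idx)) cbind(A[idx, , drop = FALSE], sgn * V[idx, , drop = FALSE])
  s <- boot::simplex(a = obj,
                     A1 = mk(i1, -1), b1 = b[i1],
                     A2 = mk(i2, +1), b2 = b[i2],
                     A3 = mk(i3, +1), b3 = b[i3],
                     maxi = FALSE)
  v <- s$soln[(nv + 1):(nv + m)]
  blocks$labels[v > 1e-7]
}

#' Solve a demand LP exactly
#'
#' Simplex solution of the continuous LP (no integer variables), with the
#' system rescaled internally for numerical stability. The returned vertex
#' is verified against every constraint to 1e-6 relative tolerance;
#' binding constraints are labelled. Infeasible problems error with the
#' set of constraints that cannot be met jointly (from a minimal
#' total-violation relaxation).
#'
#' @param spec An `lp_spec` from [build_lp()].
#' @return Object of class `lp_result`: `areas` ([land_use_areas()]),
#'   `objective` (million CNY), `binding` labels, `status`.
#' @export
solve_lp <- function(spec) {
  stopifnot(inherits(spec, "lp_spec"))
  blk <- lp_blocks(spec)
  b <- blk$b / blk$scale
  i1 <- blk$sense == "<="; i2 <- blk$sense == ">="; i3 <- blk$sense == "="
  pick <- function(idx) if (any(idx)) blk$A[idx, , drop = FALSE]
  s <- boot::simplex(a = spec$objective,
                     A1 = pick(i1), b1 = b[i1],
                     A2 = pick(i2), b2 = b[i2],
                     A3 = pick(i3), b3 = b[i3],
                     maxi = identical(spec$sense, "max"),
                     n.iter = 200L)
  if (s$solved == -1) {
    bad <- diagnose_infeasible(blk)
    stop("LP infeasible; irreducibly conflicting constraints: ",
         paste(bad, collapse = ", "))
  }
  if (s$solved != 1) stop("LP did not converge (unbounded or iteration limit)")
  x <- s$soln * blk$scale
  names(x) <- names(spec$objective)
  # post-hoc verification and binding-constraint detection
  ax <- as.numeric(blk$A %*% x)
  tol <- 1e-6 * pmax(1, abs(blk$b))
  viol <- (blk$sense == "<=" & ax > blk$b + tol) |
          (blk$sense == ">=" & ax < blk$b - tol) |
          (blk$sense == "="  & abs(ax - blk$b) > tol)
  if (any(viol))
    stop("solver returned an infeasible point (violated: ",
         paste(blk$labels[viol], collapse = ", "), ")")
  binding <- blk$labels[abs(ax - blk$b) <= tol]
  standard <- identical(names(spec$objective),
                        c(names(lu_classes), "population"))
  structure(list(
    scenario = spec$scenario,
    solution = x,
    areas = if (standard) land_use_areas(x[1:6], x[["population"]]),
    objective = sum(spec$objective * x),
    binding = binding,
    status = "optimal"
  ), class = "lp_result")
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("<lp_result> %s, %s; objective %.2f million CNY\n",
              toupper(x$scenario), x$status, x$objective))
  if (is.null(x$areas)) print(round(x$solution, 4)) else print(x$areas)
  cat("binding:", paste(x$binding, collapse = ", "), "\n")
  invisible(x)
}

#' 2030 demand under the three land-use scenarios
#'
#' Natural increase (`nis`) is the one-decade Markov projection of the
#' base-year areas through the observed decade transition matrix;
#' ecological protection (`eps`) and economic development (`eds`) are the
#' LP optima of [build_lp()]/[solve_lp()].
#'
#' @param scenario `"nis"`, `"eps"` or `"eds"`.
#' @param areas_t Base-year [land_use_areas()] (needed for `nis`).
#' @param trans Decade `transition_matrix` (needed for `nis`).
#' @param params [mop_params()] list (for `eps`/`eds`).
#' @return A [land_use_areas()] of 2030 demand.
#' @export
demand_2030 <- function(scenario = c("nis", "eps", "eds"),
                        areas_t = NULL, trans = NULL, params = mop_params()) {
  scenario <- match.arg(scenario)
  if (scenario == "nis") {
    if (is.null(areas_t) || is.null(trans))
      stop("'nis' needs base-year areas and a transition matrix")
    markov_project(areas_t, trans, steps = 1L)
  } else {
    solve_lp(build_lp(scenario, params))$areas
  }
}
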