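scenario_grid <- data.frame(
  id = paste0("S", 1:6),
  lulc = c("nis", "nis", "eps", "eps", "eds", "eds"),
  climate = rep(c("RCP4.5", "RCP8.5"), 3L),
  stringsAsFactors = FALSE
)

#' Scenario specification
#'
#' The six coupled land-use x climate scenarios: S1/S2 = natural increase
#' under RCP4.5/RCP8.5, S3/S4 = ecological protection, S5/S6 = economic
#' development. Any id outside S1..S6, or a (land-use, climate) pair not
#' on the grid, is rejected.
#'
#' @param id `"S1"` .. `"S6"`.
#' @param seed Integer seed for the whole run.
#' @return Object of class `scenario_spec` with fields `id`, `lulc`
#'   (`"nis"|"eps"|"eds"`), `climate` (`"RCP4.5"|"RCP8.5"`), `seed`.
#' @export
scenario_spec <- function(id, seed = 1L) {
  i <- match(id, scenario_grid$id)
  if (is.na(i)) stop("unknown scenario id '", id, "'; use S1..S6")
  structure(list(id = id, lulc = scenario_grid$lulc[i],
                 climate = scenario_grid$climate[i], seed = as.integer(seed)),
            class = "scenario_spec")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)  # deterministic serialization
  unname(tools::md5sum(f))
}

raster_summary <- function(r) {
  v <- r$values[!is.na(r$values)]
  c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
}

#' Run one coupled scenario end to end
#'
#' Pipeline: (1) generate the synthetic landscape (terrain, historical
#' climate, dated land-use pair) from `config` reseeded with the
#' scenario's seed; (2) derive the 2030 demand — Markov projection for the
#' natural-increase scenario, LP optimum otherwise — and convert the area
#' shares to cell counts; (3) mine expansion samples, fit suitability
#' surfaces and allocate the demand with the cellular automaton; (4)
#' compute the four ecosystem services under the scenario's emission
#' climate (climate enters only this stage, so allocation is identical
#' across climate scenarios); (5) aggregate to sampling units and compute
#' the Spearman trade-off matrix.
#'
#' @param spec A [scenario_spec()].
#' @param config A [synthetic_config()]; its `climate` entry is the
#'   historical climate driving map generation and allocation.
#' @param params [mop_params()] for the LP scenarios.
#' @param unit_size Trade-off sampling-unit edge (m); default `NULL` =
#'   1 km rounded to the nearest multiple of the cell size.
#' @param out_dir Optional directory; when given, all rasters are written
#'   there as ESRI ASCII grids and the report as JSON.
#' @return Object of class `run_report`.
#' @export
run_scenario <- function(spec, config = synthetic_config(),
                         params = mop_params(), unit_size = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  config$seed <- spec$seed
  if (is.null(unit_size))
    unit_size <- max(1, round(1000 / config$cell_size)) * config$cell_size
  stage <- "synthetic_landscape"
  report <- list(id = spec$id, lulc_scenario = spec$lulc,
                 climate_scenario = spec$climate, seed = spec$seed,
                 config_hash = config_hash(config))
  result <- try({
    land <- generate_landscape(config)

    stage <- "demand"
    area_ha <- cell_area_ha(land$lulc_t1)
    n_valid <- sum(!is.na(land$lulc_t1$values))
    demand_areas <- if (spec$lulc == "nis") {
      trans <- cross_tabulate(land$lulc_t0, land$lulc_t1)
      t1_areas <- land_use_areas(colSums(unclass(trans)))
      markov_project(t1_areas, trans, steps = 1L)
    } else {
      solve_lp(build_lp(spec$lulc, params))$areas
    }
    shares <- demand_areas$areas / sum(demand_areas$areas)
    demand_cells <- round(shares * n_valid)
    demand_cells[which.max(demand_cells)] <- demand_cells[which.max(demand_cells)] +
      (n_valid - sum(demand_cells))

    stage <- "allocation"
    drivers <- list(dem = land$dem, slope = land$slope,
                    precip = land$precip, temp = land$temp)
    samples <- extract_samples(land$lulc_t0, land$lulc_t1, drivers,
                               seed = substream(spec$seed, "leas"))
    suit <- fit_suitability(samples, drivers,
                            seed = substream(spec$seed, "forest"))
    state <- ca_state(land$lulc_t1, demand_cells,
                      seed = substream(spec$seed, "cars"))
    alloc <- allocate(state, suit)

    stage <- "ecosystem_services"
    scen_cfg <- config
    scen_cfg$climate <- rcp_climate_params(spec$climate)
    clim <- generate_climate(land$dem, scen_cfg)
    es <- es_stack(alloc, clim$precip, clim$aet, land$dem)

    stage <- "tradeoffs"
    tab <- aggregate_grid(lapply(es, identity), unit_size)
    corr <- spearman_matrix(tab, vars = c("wy", "cs", "hq", "sr"))

    report$grid_shape <- dim(land$lulc_t1$values)
    report$demand_ha <- round(unname(demand_areas$areas), 2)
    report$demand_cells <- unname(demand_cells)
    report$allocated_counts <- unname(alloc$counts)
    report$allocation_converged <- alloc$converged
    report$allocation_iterations <- alloc$iterations
    report$es_summary <- lapply(es, function(r) round(raster_summary(r), 6))
    report$spearman_rho <- round(corr$rho, 6)
    report$spearman_p <- signif(corr$p, 6)
    report$n_sample_units <- corr$n
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_ascii_grid(alloc, file.path(out_dir, paste0(spec$id, "_lulc2030.asc")))
      for (nm in names(es))
        write_ascii_grid(es[[nm]], file.path(out_dir, paste0(spec$id, "_", nm, ".asc")))
    }
    list(alloc = alloc, es = es, table = tab, corr = corr)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    report$failed_stage <- stage
    report$error <- conditionMessage(attr(result, "condition"))
  }
  rep <- structure(report, class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(rep, file.path(out_dir, paste0(spec$id, "_report.json")))
  }
  attr(rep, "artifacts") <- if (!inherits(result, "try-error")) result
  rep
}

#' Serialize a run report to canonical JSON
#'
#' @param report A `run_report`.
#' @param path Optional output path; omitted = return the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
write_report <- function(report, path = NULL) {
  payload <- unclass(report)
  attr(payload, "artifacts") <- NULL
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (%s x %s), seed %d\n", x$id,
              toupper(x$lulc_scenario), x$climate_scenario, x$seed))
  if (!is.null(x$failed_stage)) {
    cat("FAILED at stage:", x$failed_stage, "-", x$error, "\n")
    return(invisible(x))
  }
  cat("demand (ha):", paste(names(lu_classes), x$demand_ha, collapse = ", "), "\n")
  cat("ES means:", paste(names(x$es_summary),
                         vapply(x$es_summary, function(s) sprintf("%.3f", s[["mean"]]), ""),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Compare scenario run reports
#'
#' Per-ES means by scenario plus the pairwise Spearman rho by scenario,
#' formatted as two long tables.
#'
#' @param reports List of >= 2 successful `run_report`s on the same grid.
#' @return List with data frames `es_means` (ES x scenario) and
#'   `correlations` (pair x scenario).
#' @export
compare_scenarios <- function(reports) {
  stopifnot(length(reports) >= 2L)
  shapes <- lapply(reports, `[[`, "grid_shape")
  if (!all(vapply(shapes, identical, TRUE, shapes[[1L]])))
    stop("reports come from mismatched grids")
  ids <- make.unique(vapply(reports, `[[`, "", "id"))
  es_means <- data.frame(es = names(reports[[1L]]$es_summary))
  for (i in seq_along(reports))
    es_means[[ids[i]]] <- vapply(reports[[i]]$es_summary, function(s) s[["mean"]], 0)
  vars <- rownames(reports[[1L]]$spearman_rho)
  pairs <- utils::combn(vars, 2L)
  correlations <- data.frame(pair = paste(toupper(pairs[1L, ]),
                                          toupper(pairs[2L, ]), sep = "-"))
  for (i in seq_along(reports))
    correlations[[ids[i]]] <- reports[[i]]$spearman_rho[cbind(pairs[1L, ], pairs[2L, ])]
  list(es_means = es_means, correlations = correlations)
}
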