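#' Land-use class codes
#'
#' Integer codes for the six land-use classes used throughout the package,
#' in the order of the demand decision variables x1..x6.
#'
#' @format Named integer vector: cropland = 1, woodland = 2, grassland = 3,
#'   water = 4, builtup = 5, unused = 6.
#' @export
lu_classes <- c(
  cropland = 1L, woodland = 2L, grassland = 3L,
  water    = 4L, builtup  = 5L, unused   = 6L
)

#' Single-band raster grid
#'
#' A lightweight in-memory raster: a numeric (or integer-coded categorical)
#' matrix with a cell size in metres. Row 1 is the top of the map; cell
#' centres are at ((col - 0.5) * cell_size, (nrow - row + 0.5) * cell_size).
#' Missing cells are `NA`.
#'
#' @param values Numeric or integer matrix.
#' @param cell_size Cell edge length in metres (> 0).
#' @param categorical Logical; `TRUE` for integer-coded land-use maps, whose
#'   non-`NA` values must lie in `lu_classes`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 30, categorical = FALSE) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  if (categorical) {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% lu_classes))
      stop("categorical raster has values outside the class codes 1..6")
    storage.mode(values) <- "integer"
  }
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 categorical = isTRUE(categorical)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %.6g m, %s\n",
              nrow(v), ncol(v), x$cell_size,
              if (x$categorical) "categorical" else "continuous"))
  ok <- !is.na(v)
  if (x$categorical) {
    tab <- table(factor(v[ok], levels = lu_classes, labels = names(lu_classes)))
    print(tab)
  } else if (any(ok)) {
    cat(sprintf("  range [%.6g, %.6g], %d NA cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Test that rasters share shape, resolution and missingness
#'
#' @param ... Two or more `raster_grid` objects.
#' @param check_mask Also require identical `NA` masks.
#' @return `TRUE` invisibly, or an error describing the mismatch.
#' @export
stopifnot_aligned <- function(..., check_mask = TRUE) {
  rs <- list(...)
  stopifnot(length(rs) >= 2L)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!identical(dim(ref$values), dim(r$values)))
      stop("rasters are not aligned: shapes differ")
    if (!isTRUE(all.equal(ref$cell_size, r$cell_size)))
      stop("rasters are not aligned: cell sizes differ")
    if (check_mask && !identical(is.na(ref$values), is.na(r$values)))
      stop("rasters are not aligned: NA masks differ")
  }
  invisible(TRUE)
}

#' Hectares covered by one cell
#' @param r A `raster_grid`.
#' @return Cell area in ha.
#' @export
cell_area_ha <- function(r) r$cell_size^2 / 1e4

#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text interchange format readable by every GIS. Categorical rasters
#' use nodata 0, continuous rasters -9999.
#'
#' @param r A `raster_grid`.
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  nodata <- if (r$categorical) 0 else -9999
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path File written by [write_ascii_grid()] or any GIS.
#' @param categorical Interpret values as land-use class codes.
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, categorical = FALSE) {
  lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(lines), "\\s+")
  key <- tolower(vapply(hdr, `[[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == val[["nrows"]], ncol(v) == val[["ncols"]])
  v[v == val[["nodata_value"]]] <- NA
  raster_grid(v, cell_size = val[["cellsize"]], categorical = categorical)
}

#' Slope in degrees from a DEM
#'
#' Central finite differences in the interior, one-sided at the edges.
#'
#' @param dem Elevation `raster_grid` (m).
#' @return Continuous `raster_grid` of slope in degrees, >= 0.
#' @export
slope_from_dem <- function(dem) {
  z <- dem$values
  h <- dem$cell_size
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2L || nc < 2L) stop("DEM must be at least 2 x 2")
  # column-direction (x) gradient
  gx <- z
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * h)
  gx[, 1] <- (z[, 2] - z[, 1]) / h
  gx[, nc] <- (z[, nc] - z[, nc - 1]) / h
  # row-direction (y) gradient
  gy <- z
  gy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * h)
  gy[1, ] <- (z[2, ] - z[1, ]) / h
  gy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / h
  raster_grid(atan(sqrt(gx^2 + gy^2)) * 180 / pi, cell_size = h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is untouched. All package randomness goes through
# this so that a single integer seed determines every artifact.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Deterministic sub-stream seed for a named artifact.
substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
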