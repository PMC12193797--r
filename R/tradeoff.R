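#' Aggregate aligned rasters to a grid sample table
#'
#' Partitions the map into square units of `unit_size` metres, records the
#' mean of valid cells per unit for every raster in the stack, and drops
#' units with fewer than 50% valid cells. Unit centroids (metres, map
#' coordinates) feed the spatial regression.
#'
#' @param stack Named list of aligned continuous rasters.
#' @param unit_size Sampling-unit edge (m), a multiple of the cell size.
#' @return Data frame with columns `u`, `v` (centroid coordinates) and one
#'   column per raster; attributes `block_dim` and `block_index` allow
#'   mapping rows back to units.
#' @export
aggregate_grid <- function(stack, unit_size) {
  stopifnot(length(stack) >= 1L)
  if (length(stack) >= 2L)
    do.call(stopifnot_aligned, c(unname(stack), list(check_mask = FALSE)))
  ref <- stack[[1L]]
  cs <- ref$cell_size
  uc <- unit_size / cs
  if (abs(uc - round(uc)) > 1e-8 || uc < 1)
    stop("'unit_size' must be a positive multiple of the cell size")
  uc <- as.integer(round(uc))
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  bi <- as.vector(row(ref$values) - 1L) %/% uc
  bj <- as.vector(col(ref$values) - 1L) %/% uc
  block <- bi * (max(bj) + 1L) + bj
  cell_valid <- Reduce(`&`, lapply(stack, function(r) !is.na(r$values)))
  n_tot <- as.vector(rowsum(rep(1, length(block)), block))
  n_ok <- as.vector(rowsum(as.numeric(cell_valid), block))
  keep <- n_ok / n_tot >= 0.5 & n_ok > 0
  xs <- (col(ref$values) - 0.5) * cs
  ys <- (nr - row(ref$values) + 0.5) * cs
  agg <- function(m) {
    m2 <- m; m2[!cell_valid] <- 0
    as.vector(rowsum(as.numeric(m2), block)) / pmax(n_ok, 1)
  }
  # centroids over the same valid cells the means use
  out <- data.frame(u = agg(xs), v = agg(ys))
  for (nm in names(stack)) out[[nm]] <- agg(stack[[nm]]$values)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("no sampling units with >= 50% valid cells")
  attr(out, "block_dim") <- c(max(bi) + 1L, max(bj) + 1L)
  attr(out, "block_index") <- which(keep) - 1L
  attr(out, "unit_size") <- unit_size
  out
}

#' Pairwise Spearman correlations with synergy/trade-off signs
#'
#' rho is the Pearson correlation of average-ranked values (ties get the
#' mean rank); two-sided p-values use the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)). A positive rho is read as synergy, a
#' negative one as trade-off. Zero-variance columns give `NA` for their
#' pairs and are flagged.
#'
#' @param table Sample data frame (e.g. from [aggregate_grid()]).
#' @param vars Columns to correlate; default every column except `u`, `v`.
#' @return Object of class `correlation_matrix`: `rho`, `p`,
#'   `classification` (character matrix), `n`, `degenerate` (flagged
#'   columns).
#' @export
spearman_matrix <- function(table, vars = setdiff(names(table), c("u", "v"))) {
  X <- as.matrix(table[vars])
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows")
  degenerate <- vars[apply(X, 2L, function(x) stats::sd(x) == 0)]
  R <- apply(X, 2L, rank)  # average ranks for ties
  rho <- suppressWarnings(stats::cor(R))
  rho[vars %in% degenerate, ] <- NA
  rho[, vars %in% degenerate] <- NA
  diag(rho) <- ifelse(vars %in% degenerate, NA, 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  cls <- ifelse(rho > 0, "synergy", ifelse(rho < 0, "trade-off", "none"))
  diag(cls) <- NA
  structure(list(rho = rho, p = p, classification = cls, n = n,
                 degenerate = degenerate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> Spearman rho, n = %d\n", x$n))
  print(round(x$rho, digits))
  if (length(x$degenerate))
    cat("zero-variance (flagged):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

gwr_kernel <- function(d, h, kernel) {
  switch(kernel,
         bisquare = ifelse(d < h, (1 - (d / h)^2)^2, 0),
         gaussian = exp(-0.5 * (d / h)^2),
         uniform  = as.numeric(d <= h))
}

gwr_engine <- function(y, X, D, h, kernel, adaptive) {
  n <- length(y); p <- ncol(X)
  beta <- matrix(NA_real_, n, p)
  fit <- rep(NA_real_, n)
  lev <- rep(NA_real_, n)
  singular <- logical(n)
  for (i in seq_len(n)) {
    hi <- if (adaptive) sort(D[i, ])[min(max(round(h), p + 2), n)] else h
    w <- gwr_kernel(D[i, ], hi, kernel)
    if (kernel == "bisquare" && adaptive) w[w == 0 & D[i, ] <= hi] <- 1e-9
    sw <- sum(w)
    if (sw <= 0) { singular[i] <- TRUE; next }
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    if (rcond(XtWX) < 1e-10) { singular[i] <- TRUE; next }
    M <- solve(XtWX, t(Xw))       # p x n
    b <- M %*% y
    beta[i, ] <- b
    fit[i] <- sum(X[i, ] * b)
    lev[i] <- sum(X[i, ] * M[, i])
  }
  list(beta = beta, fitted = fit, leverage = lev, singular = singular)
}

gwr_aicc <- function(y, X, D, h, kernel, adaptive) {
  e <- gwr_engine(y, X, D, h, kernel, adaptive)
  ok <- !e$singular
  n <- sum(ok)
  if (n < ncol(X) + 2L) return(Inf)
  rss <- sum((y[ok] - e$fitted[ok])^2)
  trS <- sum(e$leverage[ok])
  if (n - 2 - trS <= 0) return(Inf)
  n * log(rss / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' Geographically weighted regression
#'
#' Local weighted least squares at every sample location with a spatial
#' kernel: y_i = beta_0(u_i, v_i) + sum_k beta_k(u_i, v_i) x_ik + e_i.
#' The default adaptive bisquare kernel sets each local bandwidth to the
#' distance of the `bandwidth`-th nearest neighbour; with `bandwidth =
#' NULL` the bandwidth minimizing the corrected AIC is found by
#' golden-section search. Local fits with a singular weighted design are
#' flagged and their coefficients set missing.
#'
#' @param y Response vector.
#' @param x Predictor vector or matrix (columns named).
#' @param coords Two-column matrix/data frame of sample coordinates (m).
#' @param kernel `"bisquare"` (default), `"gaussian"` or `"uniform"`.
#' @param adaptive Logical; `TRUE` interprets the bandwidth as a
#'   neighbour count, `FALSE` as a fixed distance (m).
#' @param bandwidth Bandwidth, or `NULL` for AICc selection.
#' @return Object of class `gwr`: local `coefficients` (one row per
#'   sample), `fitted`, `residuals`, `bandwidth`, `aicc`, `trace_S`,
#'   `local_R2`, `global_R2`, `singular` flags.
#' @export
gwr_fit <- function(y, x, coords, kernel = c("bisquare", "gaussian", "uniform"),
                    adaptive = TRUE, bandwidth = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  stopifnot(nrow(x) == n, nrow(coords) == n)
  X <- cbind(`(Intercept)` = 1, x)
  D <- as.matrix(stats::dist(as.matrix(coords)))
  p <- ncol(X)
  if (is.null(bandwidth)) {
    lo <- if (adaptive) p + 2 else min(D[D > 0])
    hi <- if (adaptive) n else max(D) * 2
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- gwr_aicc(y, X, D, c1, kernel, adaptive)
    f2 <- gwr_aicc(y, X, D, c2, kernel, adaptive)
    for (it in seq_len(40L)) {
      if (abs(b - a) < ifelse(adaptive, 1, (hi - lo) * 1e-4)) break
      if (f1 < f2) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a)
        f1 <- gwr_aicc(y, X, D, c1, kernel, adaptive)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a)
        f2 <- gwr_aicc(y, X, D, c2, kernel, adaptive)
      }
    }
    bandwidth <- if (f1 < f2) c1 else c2
    if (adaptive) bandwidth <- round(bandwidth)
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  e <- gwr_engine(y, X, D, bandwidth, kernel, adaptive)
  ok <- !e$singular
  res <- y - e$fitted
  rss <- sum(res[ok]^2)
  tss <- sum((y[ok] - mean(y[ok]))^2)
  colnames(e$beta) <- colnames(X)
  structure(list(coefficients = e$beta, fitted = e$fitted, residuals = res,
                 y = y, x = x, coords = as.matrix(coords),
                 kernel = kernel, adaptive = adaptive, bandwidth = bandwidth,
                 aicc = gwr_aicc(y, X, D, bandwidth, kernel, adaptive),
                 trace_S = sum(e$leverage[ok]),
                 global_R2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 singular = e$singular),
            class = "gwr")
}

#' @export
print.gwr <- function(x, ...) {
  cat(sprintf("<gwr> n = %d, kernel = %s (%s bandwidth %.6g), global R2 = %.3f\n",
              length(x$y), x$kernel,
              if (x$adaptive) "adaptive" else "fixed", x$bandwidth,
              x$global_R2))
  if (any(x$singular))
    cat(sum(x$singular), "singular local fits flagged\n")
  invisible(x)
}

#' @export
summary.gwr <- function(object, ...) {
  q <- apply(object$coefficients, 2L, stats::quantile,
             probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  structure(list(coef_quartiles = t(q), bandwidth = object$bandwidth,
                 kernel = object$kernel, aicc = object$aicc,
                 global_R2 = object$global_R2,
                 n_singular = sum(object$singular)),
            class = "summary.gwr")
}

#' @export
print.summary.gwr <- function(x, ...) {
  cat("Local coefficient quartiles:\n")
  print(round(x$coef_quartiles, 4))
  cat(sprintf("bandwidth %.6g (%s), AICc %.2f, global R2 %.3f, %d singular\n",
              x$bandwidth, x$kernel, x$aicc, x$global_R2, x$n_singular))
  invisible(x)
}

#' @export
coef.gwr <- function(object, ...) object$coefficients

#' @export
residuals.gwr <- function(object, ...) object$residuals

#' @export
fitted.gwr <- function(object, ...) object$fitted

#' Classify local slopes into trade-off/synergy categories
#'
#' Positive local slopes are synergies, negative ones trade-offs; the
#' strong/weak split falls at the median absolute slope (or user
#' thresholds). With the sample table from [aggregate_grid()], the
#' categories are also mapped back to a coarse raster (integer codes
#' 1 = strong trade-off .. 4 = strong synergy).
#'
#' @param gwr A fitted [gwr_fit()] object.
#' @param table Optional sample table carrying the `block_*` attributes.
#' @param slope Name or index of the slope column (default the first
#'   non-intercept coefficient).
#' @param threshold Absolute-slope cutoff for "strong"; default the median
#'   absolute slope.
#' @return List with `category` (ordered factor per sample), `threshold`,
#'   and, when `table` is supplied, `raster` (integer-coded
#'   `raster_grid` at the sampling-unit resolution).
#' @export
classify_relationship <- function(gwr, table = NULL, slope = 2L,
                                  threshold = NULL) {
  s <- gwr$coefficients[, slope]
  if (all(is.na(s))) stop("all local slopes are missing")
  if (is.null(threshold)) threshold <- stats::median(abs(s), na.rm = TRUE)
  lev <- c("strong trade-off", "weak trade-off", "weak synergy", "strong synergy")
  code <- ifelse(is.na(s), NA_integer_,
                 ifelse(s < 0, ifelse(abs(s) >= threshold, 1L, 2L),
                        ifelse(abs(s) >= threshold, 4L, 3L)))
  category <- factor(lev[code], levels = lev, ordered = TRUE)
  out <- list(category = category, threshold = threshold)
  if (!is.null(table) && !is.null(attr(table, "block_dim"))) {
    bd <- attr(table, "block_dim")
    m <- matrix(NA_real_, bd[1], bd[2])
    b <- attr(table, "block_index")        # row-major block ids
    m[cbind(b %/% bd[2] + 1L, b %% bd[2] + 1L)] <- code
    out$raster <- raster_grid(m, cell_size = attr(table, "unit_size"))
  }
  out
}
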