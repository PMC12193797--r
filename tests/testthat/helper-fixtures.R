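# Shared fixtures, all built in code.

# Categorical raster from a vector/matrix of class codes.
cat_raster <- function(codes, nr = NULL, nc = NULL, cell_size = 100) {
  if (!is.matrix(codes)) codes <- matrix(codes, nr, nc)
  raster_grid(codes, cell_size = cell_size, categorical = TRUE)
}

# Continuous raster filled with a constant or matrix.
const_raster <- function(x, nr = 4, nc = 4, cell_size = 30) {
  if (!is.matrix(x)) x <- matrix(x, nr, nc)
  raster_grid(x, cell_size = cell_size)
}

# A hand-built suitability stack: `probs` is a named list of matrices for
# some classes; missing classes get zero surfaces.
manual_suitability <- function(probs, nr, nc, cell_size = 30) {
  out <- stats::setNames(vector("list", 6L), names(lu_classes))
  for (k in names(lu_classes)) {
    m <- if (k %in% names(probs)) probs[[k]] else matrix(0, nr, nc)
    out[[k]] <- raster_grid(m, cell_size = cell_size)
  }
  structure(list(probs = out,
                 importance = matrix(NA_real_, 6, 0),
                 static = stats::setNames(!(names(lu_classes) %in% names(probs)),
                                          names(lu_classes))),
            class = "suitability_stack")
}

# Small landscape for pipeline-level tests.
small_config <- function(seed = 1L, shape = c(64L, 64L), ...) {
  synthetic_config(shape = shape, seed = seed, ...)
}

# Exhaustive-rank Spearman oracle: Pearson's product-moment formula applied
# to average ranks, computed from first principles.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# All n! permutations of 1..n, as a list of vectors.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1))
    for (i in 0:(n - 1))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

# Brute-force threat degradation oracle: O(N^2) double loop over all
# (habitat cell, threat cell) pairs.
degradation_oracle <- function(lulc, config) {
  v <- lulc$values
  nr <- nrow(v); nc <- ncol(v)
  wsum <- sum(vapply(config$threats, `[[`, 0, "weight"))
  D <- matrix(0, nr, nc)
  for (th in config$threats) {
    ys <- which(matrix(v %in% lu_classes[th$source], nr, nc), arr.ind = TRUE)
    if (nrow(ys) == 0) next
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      d <- sqrt((ys[, 1] - i)^2 + (ys[, 2] - j)^2) * lulc$cell_size
      irxy <- if (th$decay == "linear") pmax(0, 1 - d / th$d_max)
              else ifelse(d <= th$d_max, exp(-2.99 * d / th$d_max), 0)
      sens <- th$sensitivity[[names(lu_classes)[v[i, j]]]]
      D[i, j] <- D[i, j] + (th$weight / wsum) * sum(irxy) * sens
    }
  }
  D[is.na(v)] <- NA
  D
}

# Brute-force LP oracle: enumerate every basic feasible solution (vertex)
# of {A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0} and return the best
# objective value. Only for tiny problems.
lp_vertex_oracle <- function(obj, A, sense, b, maximize = TRUE) {
  n <- ncol(A)
  # add nonnegativity rows
  A_all <- rbind(A, diag(n))
  b_all <- c(b, numeric(n))
  m <- nrow(A_all)
  best <- if (maximize) -Inf else Inf
  best_x <- NULL
  for (rows in utils::combn(m, n, simplify = FALSE)) {
    M <- A_all[rows, , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    x <- solve(M, b_all[rows])
    lhs <- as.numeric(A_all %*% x)
    tol <- 1e-8 * pmax(1, abs(b_all))
    feas <- all(
      lhs[seq_along(sense)][sense == "<="] <= b[sense == "<="] + tol[seq_along(sense)][sense == "<="],
      lhs[seq_along(sense)][sense == ">="] >= b[sense == ">="] - tol[seq_along(sense)][sense == ">="],
      abs(lhs[seq_along(sense)][sense == "="] - b[sense == "="]) <= tol[seq_along(sense)][sense == "="],
      x >= -1e-8
    )
    if (!feas) next
    val <- sum(obj * x)
    if ((maximize && val > best) || (!maximize && val < best)) {
      best <- val
      best_x <- x
    }
  }
  list(objective = best, x = best_x)
}
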