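# Clipped-window 2-D box sum via an integral image. `half` is the window
# half-width; windows are truncated at the borders.
boxsum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- s
  ri <- as.vector(row(m)); ci <- as.vector(col(m))
  r1 <- pmax(ri - half, 1L); r2 <- pmin(ri + half, nr)
  c1 <- pmax(ci - half, 1L); c2 <- pmin(ci + half, nc)
  out <- S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
  matrix(out, nr, nc)
}

# Fraction of class-k cells in the Moore neighbourhood, excluding the
# centre, with the denominator the realized (border-clipped) window size.
class_neighbor_fraction <- function(values, k, window = 3L) {
  half <- (window - 1L) %/% 2L
  ind <- (values == k) & !is.na(values)
  storage.mode(ind) <- "double"
  valid <- !is.na(values)
  storage.mode(valid) <- "double"
  num <- boxsum(ind, half) - ind
  den <- boxsum(valid, half) - valid
  out <- ifelse(den > 0, num / den, 0)
  out[!valid] <- NA
  out
}

#' Neighbourhood effect of a land-use class
#'
#' Per cell, the fraction of class-`k` cells among its Moore
#' (window x window) neighbours, excluding the centre cell, with border
#' windows normalized by their realized size. This is the local
#' land-use-competition term of the cellular automaton.
#'
#' @param lulc Categorical `raster_grid`.
#' @param k Class code (1..6) or name.
#' @param window Odd window width >= 3.
#' @return Continuous `raster_grid` in `[0, 1]`.
#' @export
neighborhood_effect <- function(lulc, k, window = 3L) {
  stopifnot(lulc$categorical)
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")
  if (is.character(k)) k <- lu_classes[[k]]
  raster_grid(class_neighbor_fraction(lulc$values, k, window),
              cell_size = lulc$cell_size)
}

#' Mine land-expansion samples from two dated maps
#'
#' The land-expansion analysis step: for each class k, positive cells are
#' those that newly became k between the two dates; negatives are an
#' equal-sized seeded random draw from cells that did not. Driver values
#' are attached to every sampled cell. Classes with no expansion cells are
#' flagged static and skipped downstream.
#'
#' @param lulc_t0,lulc_t1 Aligned categorical rasters.
#' @param drivers Named list of aligned continuous rasters.
#' @param fraction Fraction of the positive cells to sample, in (0, 1].
#' @param seed Integer sampling seed.
#' @return Object of class `expansion_samples`: per-class data frames with
#'   a binary `label` column plus one column per driver, and a `static`
#'   logical vector.
#' @export
extract_samples <- function(lulc_t0, lulc_t1, drivers, fraction = 1, seed = 1L) {
  stopifnot(lulc_t0$categorical, lulc_t1$categorical)
  do.call(stopifnot_aligned,
          c(list(lulc_t0, lulc_t1), drivers, list(check_mask = FALSE)))
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  v0 <- lulc_t0$values; v1 <- lulc_t1$values
  X <- vapply(drivers, function(d) as.numeric(d$values), numeric(length(v0)))
  colnames(X) <- names(drivers)
  valid <- which(!is.na(v0) & !is.na(v1) & rowSums(is.na(X)) == 0)
  samples <- stats::setNames(vector("list", 6L), names(lu_classes))
  static <- stats::setNames(logical(6L), names(lu_classes))
  with_seed(seed, {
    for (k in names(lu_classes)) {
      code <- lu_classes[[k]]
      pos <- valid[v0[valid] != code & v1[valid] == code]
      if (length(pos) == 0L) {
        static[k] <- TRUE
        next
      }
      if (fraction < 1)
        pos <- sort(sample(pos, max(1L, round(fraction * length(pos)))))
      pool <- setdiff(valid, pos)
      neg <- sample(pool, min(length(pos), length(pool)))
      idx <- c(pos, neg)
      samples[[k]] <- data.frame(label = rep(c(1L, 0L), c(length(pos), length(neg))),
                                 X[idx, , drop = FALSE])
    }
  })
  structure(list(samples = samples, static = static,
                 fraction = fraction, seed = as.integer(seed)),
            class = "expansion_samples")
}

#' Fit per-class growth-suitability surfaces
#'
#' Random-forest probability classifiers (one per non-static class) relate
#' class growth to the drivers; predicting on every cell yields the
#' suitability stack used by the cellular automaton. Driver importances
#' (impurity decrease) are reported per class. Static classes get a zero
#' surface; a degenerate single-label sample gets a constant surface with
#' a warning.
#'
#' @param samples An `expansion_samples` object.
#' @param drivers The same named driver raster list used for sampling.
#' @param num_trees,max_depth Forest size and depth (0 = unlimited).
#' @param seed Integer seed for tree randomization.
#' @return Object of class `suitability_stack`: per-class probability
#'   rasters in `[0, 1]` and an importance matrix (classes x drivers).
#' @export
fit_suitability <- function(samples, drivers, num_trees = 100L,
                            max_depth = 0L, seed = 1L) {
  stopifnot(inherits(samples, "expansion_samples"))
  ref <- drivers[[1L]]
  X <- data.frame(vapply(drivers, function(d) as.numeric(d$values),
                         numeric(length(ref$values))))
  colnames(X) <- names(drivers)
  mask <- is.na(ref$values)
  probs <- stats::setNames(vector("list", 6L), names(lu_classes))
  imp <- matrix(NA_real_, 6L, length(drivers),
                dimnames = list(names(lu_classes), names(drivers)))
  for (k in names(lu_classes)) {
    df <- samples$samples[[k]]
    if (samples$static[k] || is.null(df)) {
      p <- matrix(0, nrow(ref$values), ncol(ref$values))
    } else if (length(unique(df$label)) < 2L) {
      warning("class '", k, "' has a single-label sample; constant surface")
      p <- matrix(mean(df$label), nrow(ref$values), ncol(ref$values))
    } else {
      df$label <- factor(df$label, levels = c(0L, 1L))
      fit <- ranger::ranger(label ~ ., data = df, probability = TRUE,
                            num.trees = num_trees, max.depth = max_depth,
                            importance = "impurity", seed = seed,
                            num.threads = 1L)
      imp[k, ] <- fit$variable.importance[colnames(imp)]
      p <- matrix(stats::predict(fit, X, num.threads = 1L)$predictions[, "1"],
                  nrow(ref$values), ncol(ref$values))
    }
    p[mask] <- NA
    probs[[k]] <- raster_grid(p, cell_size = ref$cell_size)
  }
  structure(list(probs = probs, importance = imp, static = samples$static),
            class = "suitability_stack")
}

#' Cellular-automaton state
#'
#' Bundles everything the allocation CA needs besides the suitability
#' stack: the current map, per-class demand in cells, adaptive inertia
#' coefficients, the patch-seeding threshold and its decay, the
#' neighbourhood window, the allowed-transition matrix and the RNG seed.
#'
#' @param lulc Categorical `raster_grid` starting map.
#' @param demand Named (or ordered) vector of six target cell counts; must
#'   sum to the number of valid cells.
#' @param inertia Initial per-class inertia coefficients.
#' @param tau Initial patch-seeding suitability threshold, in (0, 1].
#' @param delta Per-iteration decay multiplier of `tau`.
#' @param window Odd Moore-window width.
#' @param allowed 6 x 6 logical allowed-transition matrix (rows = from);
#'   default permits everything except water to unused. Diagonal must be
#'   `TRUE`.
#' @param max_iter Iteration cap.
#' @param tol Relative demand tolerance per class (fraction of demand).
#' @param seed Integer seed for the CA randomness.
#' @return Object of class `ca_state`.
#' @export
ca_state <- function(lulc, demand, inertia = rep(1, 6), tau = 0.5,
                     delta = 0.9, window = 3L, allowed = NULL,
                     max_iter = 200L, tol = 0.001, seed = 1L) {
  stopifnot(lulc$categorical, length(demand) == 6L, all(demand >= 0))
  if (tau <= 0 || tau > 1) stop("'tau' must be in (0, 1]")
  if (is.null(allowed)) {
    allowed <- matrix(TRUE, 6L, 6L,
                      dimnames = list(names(lu_classes), names(lu_classes)))
    allowed["water", "unused"] <- FALSE
  }
  if (!all(diag(allowed))) stop("allowed-transition diagonal must be TRUE")
  structure(list(lulc = lulc, demand = stats::setNames(round(as.numeric(demand)),
                                                       names(lu_classes)),
                 inertia = stats::setNames(as.numeric(inertia), names(lu_classes)),
                 tau = tau, delta = delta, window = as.integer(window),
                 allowed = allowed, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "ca_state")
}

#' Allocate land-use demand spatially
#'
#' Patch-seeding cellular automaton. Each iteration, cells of
#' surplus classes propose a conversion to a deficit class drawn by
#' roulette over combined probabilities (suitability x neighbourhood
#' effect x adaptive inertia, masked by the allowed-transition matrix);
#' cells with no neighbours of the candidate class may convert only as
#' random patch seeds where suitability exceeds the threshold `tau`, which
#' decays by `delta` each round. Proposals are accepted in weight-biased
#' random order subject to both the destination deficit and the source
#' surplus, so class counts can only move toward demand. Inertia grows for
#' classes whose deficit fails to shrink. Stops when every class count is
#' within tolerance of demand, or at `max_iter` with a warning.
#'
#' @param state A [ca_state()].
#' @param suitability A `suitability_stack` from [fit_suitability()].
#' @param seed_intensity Relative weight of a patch seed vs a same-class
#'   neighbour (default 0.05).
#' @return The allocated categorical `raster_grid`, with fields
#'   `converged`, `iterations` and `counts` added.
#' @export
allocate <- function(state, suitability, seed_intensity = 0.05) {
  stopifnot(inherits(state, "ca_state"), inherits(suitability, "suitability_stack"))
  v <- state$lulc$values
  valid <- !is.na(v)
  n_valid <- sum(valid)
  if (sum(state$demand) != n_valid)
    stop("demand (", sum(state$demand), " cells) must equal the number of valid cells (",
         n_valid, ")")
  suit <- vapply(suitability$probs, function(r) as.numeric(r$values),
                 numeric(length(v)))  # ncell x 6
  suit[is.na(suit)] <- 0
  inertia <- state$inertia
  tau <- state$tau
  half_tol <- pmax(0, floor(state$tol * state$demand))
  counts <- function(m) {
    tabulate(factor(m[valid], levels = lu_classes), nbins = 6L)
  }
  cnt <- stats::setNames(counts(v), names(lu_classes))
  gap <- state$demand - cnt
  prev_gap <- gap
  iter <- 0L
  converged <- all(abs(gap) <= half_tol)
  with_seed(state$seed, {
    while (!converged && iter < state$max_iter) {
      iter <- iter + 1L
      # adaptive inertia: boost classes whose deficit failed to shrink
      if (iter > 1L) {
        stuck <- abs(gap) >= abs(prev_gap) & abs(prev_gap) > 0
        ratio <- ifelse(prev_gap != 0, abs(gap) / abs(prev_gap), 1)
        inertia[stuck & gap > 0] <- inertia[stuck & gap > 0] * ratio[stuck & gap > 0]
        inertia <- pmin(pmax(inertia, 1e-3), 1e3)
      }
      prev_gap <- gap
      deficit <- which(gap > half_tol)
      surplus <- which(gap < -half_tol)
      if (length(deficit) == 0L || length(surplus) == 0L) { converged <- TRUE; break }
      cand <- which(valid & (v %in% surplus))
      if (length(cand) == 0L) break
      # combined probability per candidate cell and deficit class
      W <- matrix(0, length(cand), length(deficit))
      for (j in seq_along(deficit)) {
        k <- deficit[j]
        nb <- class_neighbor_fraction(v, k, state$window)[cand]
        w <- suit[cand, k] * inertia[k] * nb
        seedable <- nb == 0 & suit[cand, k] > tau
        w[seedable] <- suit[cand[seedable], k] * inertia[k] * seed_intensity
        w[!state$allowed[cbind(v[cand], k)]] <- 0
        W[, j] <- w
      }
      tw <- rowSums(W)
      ok <- tw > 0
      if (!any(ok)) break
      cand <- cand[ok]; W <- W[ok, , drop = FALSE]; tw <- tw[ok]
      # roulette: draw one destination class per candidate cell
      u <- stats::runif(length(cand)) * tw
      cum <- W
      if (ncol(W) > 1L) cum <- t(apply(W, 1L, cumsum))
      dest <- deficit[max.col(u <= cum, ties.method = "first")]
      wsel <- W[cbind(seq_along(cand), match(dest, deficit))]
      # accept in weight-biased random order, capped by deficit and surplus
      ord <- order(stats::runif(length(cand))^(1 / pmax(wsel, 1e-12)),
                   decreasing = TRUE)
      cand <- cand[ord]; dest <- dest[ord]
      src <- v[cand]
      pos_dest <- stats::ave(seq_along(cand), dest, FUN = seq_along)
      pos_src <- stats::ave(seq_along(cand), src, FUN = seq_along)
      accept <- pos_dest <= gap[dest] & pos_src <= -gap[src]
      if (!any(accept)) break
      v[cand[accept]] <- dest[accept]
      cnt <- stats::setNames(counts(v), names(lu_classes))
      gap <- state$demand - cnt
      tau <- tau * state$delta
      converged <- all(abs(gap) <= half_tol)
    }
  })
  if (!converged)
    warning("allocation did not converge within ", state$max_iter,
            " iterations; returning best map")
  out <- raster_grid(v, cell_size = state$lulc$cell_size, categorical = TRUE)
  out$converged <- converged
  out$iterations <- iter
  out$counts <- cnt
  out
}

#' Map agreement: overall accuracy and Cohen's kappa
#'
#' @param map_pred,map_true Aligned categorical rasters.
#' @return List with `overall_accuracy`, `kappa` and the 6 x 6 `confusion`
#'   matrix (cells).
#' @export
agreement <- function(map_pred, map_true) {
  stopifnot_aligned(map_pred, map_true, check_mask = FALSE)
  ok <- !is.na(map_pred$values) & !is.na(map_true$values)
  if (!any(ok)) stop("maps have no overlapping valid cells")
  cm <- table(factor(map_pred$values[ok], levels = lu_classes),
              factor(map_true$values[ok], levels = lu_classes))
  cm <- matrix(as.numeric(cm), 6L, 6L,
               dimnames = list(names(lu_classes), names(lu_classes)))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(overall_accuracy = po, kappa = kappa, confusion = cm)
}
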