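# Latent-space grid with per-cell averaged propensity scores and
# IPTW-derived weights; weighted rejection sampling of the prior.

#' Build a latent grid with per-cell propensity and weights
#'
#' Tiles the bounding box of the embedded training points with half-open
#' square cells of side `d` (default: the larger side of the box divided by
#' `resolution`), averages the per-point propensity scores within each cell,
#' converts the averages to weights by [overlap_weights()] or
#' [group_weights()], and normalises the weights to sum to one. When
#' `latent_dim > 2` the grid is built on the first two principal components
#' of the embedding and the rotation is stored for sampling.
#'
#' @param z Matrix of embedded training points (posterior means).
#' @param ps Per-point propensity scores in \eqn{(0,1)}.
#' @param d Cell side length; overrides `resolution`.
#' @param resolution Number of cells along the longer axis (default 20).
#' @param delta Acceptable deviation from \eqn{\bar p = 0.5}.
#' @param mode `"overlap"` keeps cells common to both sub-groups;
#'   `"group"` keeps cells typical for group \eqn{g = 0}.
#' @return Object of class `latent_grid` with `d`, `origin`, `N1`, `N2`,
#'   `counts`, `pbar` (NA when empty), `w`, `wbar`, `delta`, `mode`,
#'   `rotation` (`NULL` in 2-D).
#' @export
build_latent_grid <- function(z, ps, d = NULL, resolution = 20L,
                              delta = 0.1, mode = c("overlap", "group")) {
  mode <- match.arg(mode)
  z <- as.matrix(z)
  stopifnot(nrow(z) == length(ps), all(ps > 0), all(ps < 1))
  rotation <- NULL
  if (ncol(z) > 2L) {
    pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    rotation <- list(rot = pca$rotation[, 1:2, drop = FALSE],
                     center = pca$center)
    z <- pca$x[, 1:2, drop = FALSE]
  }
  spans <- c(diff(range(z[, 1L])), diff(range(z[, 2L])))
  if (is.null(d)) d <- max(spans) / resolution
  origin <- c(min(z[, 1L]), min(z[, 2L]))
  N1 <- max(1L, ceiling(spans[1L] / d))
  N2 <- max(1L, ceiling(spans[2L] / d))
  grid <- list(d = d, origin = origin, N1 = N1, N2 = N2,
               maxima = origin + d * c(N1, N2), rotation = rotation)
  cells <- assign_cells(z, grid)
  agg <- average_ps_per_cell(cells, ps, N1, N2)
  w <- if (mode == "overlap") overlap_weights(agg$pbar, delta)
       else group_weights(agg$pbar, delta)
  grid$counts <- agg$counts
  grid$pbar <- agg$pbar
  grid$w <- w
  grid$wbar <- normalize_weights(w)
  grid$delta <- delta
  grid$mode <- mode
  class(grid) <- "latent_grid"
  grid
}

#' @export
print.latent_grid <- function(x, ...) {
  cat("Latent grid:", x$N1, "x", x$N2, "cells of side",
      format(x$d, digits = 4), "| mode", x$mode, "| delta", x$delta, "\n")
  cat("  ", sum(x$w > 0), "admissible cells,",
      sum(x$counts > 0), "occupied cells\n")
  invisible(x)
}

#' Assign 2-D latent points to grid cells
#'
#' Half-open bins of width `d` starting at the per-dimension minimum of the
#' training embedding; the maximum maps into the last cell. Points outside
#' the training bounding box get `NA` ("outside") indices.
#'
#' @param z Matrix with 2 columns.
#' @param grid A `latent_grid` (or list with `origin`, `d`, `N1`, `N2`,
#'   `maxima`).
#' @return Integer matrix with columns `i`, `j` (`NA` = outside).
#' @export
assign_cells <- function(z, grid) {
  z <- as.matrix(z)
  i <- floor((z[, 1L] - grid$origin[1L]) / grid$d) + 1L
  j <- floor((z[, 2L] - grid$origin[2L]) / grid$d) + 1L
  # upper boundary belongs to the last cell
  i[z[, 1L] == grid$maxima[1L]] <- grid$N1
  j[z[, 2L] == grid$maxima[2L]] <- grid$N2
  out <- i < 1L | i > grid$N1 | j < 1L | j > grid$N2
  i[out] <- NA_integer_; j[out] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Average propensity score per grid cell
#'
#' Mean of the member points' propensity scores, dividing by the cell's own
#' member count; empty cells are `NA` (undefined), not zero.
#'
#' @param cells Integer matrix from [assign_cells()].
#' @param ps Per-point propensity scores.
#' @param N1,N2 Grid dimensions.
#' @return List with matrices `pbar` and `counts` (N1 x N2).
#' @export
average_ps_per_cell <- function(cells, ps, N1, N2) {
  counts <- matrix(0L, N1, N2)
  sums <- matrix(0, N1, N2)
  ok <- which(!is.na(cells[, 1L]))
  for (k in ok) {
    i <- cells[k, 1L]; j <- cells[k, 2L]
    counts[i, j] <- counts[i, j] + 1L
    sums[i, j] <- sums[i, j] + ps[k]
  }
  pbar <- sums / counts
  pbar[counts == 0L] <- NA_real_
  list(pbar = pbar, counts = counts)
}

#' IPTW overlap weights on the propensity grid
#'
#' Keeps only cells common to both sub-groups:
#' \eqn{w = 0} when \eqn{|\bar p - 0.5| > \delta}, \eqn{1/\bar p} when
#' \eqn{\bar p > 0.5}, \eqn{1/(1-\bar p)} when \eqn{\bar p < 0.5}, and 2 at
#' \eqn{\bar p = 0.5} (the continuity limit). Undefined (empty) cells get 0.
#'
#' @param pbar Matrix of per-cell averaged propensity scores (`NA` = empty).
#' @param delta Band half-width in \eqn{(0, 0.5)}.
#' @return Nonnegative weight matrix.
#' @export
overlap_weights <- function(pbar, delta) {
  stopifnot(delta > 0, delta < 0.5)
  w <- matrix(0, nrow(pbar), ncol(pbar))
  def <- !is.na(pbar)
  inb <- def & abs(pbar - 0.5) <= delta
  hi <- inb & pbar > 0.5
  lo <- inb & pbar < 0.5
  eq <- inb & pbar == 0.5
  w[hi] <- 1 / pbar[hi]
  w[lo] <- 1 / (1 - pbar[lo])
  w[eq] <- 2
  w
}

#' IPTW one-group weights on the propensity grid
#'
#' Keeps cells typical for group \eqn{g = 0}: \eqn{w = 0} when
#' \eqn{\bar p > 0.5 + \delta}, else \eqn{1/\bar p} (capped at `cap` to bound
#' the influence of near-empty extreme cells). Undefined cells get 0.
#'
#' @inheritParams overlap_weights
#' @param cap Upper bound on a single cell's unnormalised weight.
#' @export
group_weights <- function(pbar, delta, cap = 100) {
  stopifnot(delta > 0, delta < 0.5)
  w <- matrix(0, nrow(pbar), ncol(pbar))
  keep <- !is.na(pbar) & pbar <= 0.5 + delta
  w[keep] <- pmin(1 / pbar[keep], cap)
  w
}

#' Normalise grid weights to sum to one
#'
#' @param w Nonnegative weight matrix with at least one positive entry.
#' @export
normalize_weights <- function(w) {
  s <- sum(w)
  if (s <= 0)
    stop("normalize_weights: no admissible region; increase delta")
  w / s
}

#' Propensity-weighted rejection sampling from the latent prior
#'
#' Repeatedly draws latent points from the standard-normal prior, locates
#' each in the grid, and accepts it with probability proportional to its
#' cell's weight (scaled so the largest weight accepts with probability one,
#' which targets the same distribution as Bernoulli(\eqn{\bar w}) acceptance
#' at a far higher rate). Draws outside the grid or in zero-weight cells are
#' rejected. Accepted points are decoded and the pipeline inverted.
#'
#' @param object A `synthvae` fit.
#' @param grid A `latent_grid` built on the fit's embedding.
#' @param n_target Number of synthetic rows to accept.
#' @param seed RNG seed.
#' @param min_acceptance Abort if the acceptance rate of the first probe
#'   batch falls below this floor.
#' @return Data frame of synthetic rows on the original scale, with the
#'   realised acceptance rate as attribute `"acceptance_rate"` and the
#'   accepted latent points as attribute `"z"`.
#' @export
sample_weighted <- function(object, grid, n_target, seed = 1L,
                            min_acceptance = 1e-4) {
  stopifnot(inherits(object, "synthvae"), inherits(grid, "latent_grid"),
            n_target >= 1L)
  Ld <- object$config$latent_dim
  wmax <- max(grid$w)
  if (wmax <= 0) stop("sample_weighted: all cell weights are zero")
  set.seed(seed)
  acc <- matrix(numeric(0), 0L, Ld)
  drawn <- 0L
  batch <- max(1000L, 4L * n_target)
  first <- TRUE
  while (nrow(acc) < n_target) {
    z <- matrix(stats::rnorm(batch * Ld), batch, Ld)
    z2 <- if (!is.null(grid$rotation))
      sweep(z, 2L, grid$rotation$center) %*% grid$rotation$rot else z
    cells <- assign_cells(z2, grid)
    idx <- cells[, 1L] + (cells[, 2L] - 1L) * grid$N1
    p_acc <- rep(0, batch)
    ok <- !is.na(idx)
    p_acc[ok] <- grid$w[idx[ok]] / wmax
    keep <- stats::runif(batch) < p_acc
    drawn <- drawn + batch
    acc <- rbind(acc, z[keep, , drop = FALSE])
    if (first && nrow(acc) / drawn < min_acceptance)
      stop("sample_weighted: admissible region too small (acceptance rate ",
           format(nrow(acc) / drawn, digits = 3), ")")
    first <- FALSE
  }
  rate <- nrow(acc) / drawn
  z_acc <- acc[seq_len(n_target), , drop = FALSE]
  t01 <- decode_and_sample(object$vae, z_acc, seed = seed + 1L)
  out <- pipeline_inverse(object$pipeline, t01)
  attr(out, "acceptance_rate") <- rate
  attr(out, "z") <- z_acc
  out
}

#' Latent-space overlay figure: embedding, sub-groups and the weighted grid
#'
#' Draws the per-cell averaged propensity score (or the normalised sampling
#' weight) as a heat map with the embedded training points on top, coloured
#' by sub-group; zero-weight cells are shaded grey in the weight variant.
#'
#' @param object A `synthvae` fit.
#' @param grid A `latent_grid`.
#' @param group Binary sub-group labels for the embedded rows.
#' @param what `"pbar"` or `"weight"`.
#' @param file Output file (`.png` or `.svg`); `NULL` draws to the active
#'   device.
#' @param newdata Rows to embed; default the training table (required when
#'   `object` was restored from an archive, which stores no training rows).
#' @return The file path (or `NULL`), invisibly.
#' @export
latent_heatmap <- function(object, grid, group, what = c("pbar", "weight"),
                           file = NULL, newdata = NULL) {
  what <- match.arg(what)
  z <- if (is.null(newdata)) predict(object) else predict(object, newdata)
  if (!is.null(grid$rotation))
    z <- sweep(z, 2L, grid$rotation$center) %*% grid$rotation$rot
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 6)
    else grDevices::png(file, width = 700, height = 600)
    on.exit(grDevices::dev.off())
  }
  xb <- grid$origin[1L] + grid$d * (0:grid$N1)
  yb <- grid$origin[2L] + grid$d * (0:grid$N2)
  val <- if (what == "pbar") grid$pbar else grid$wbar
  pal <- grDevices::hcl.colors(21, if (what == "pbar") "Blue-Red" else "Greens",
                               rev = what == "weight")
  graphics::image(xb, yb, val, col = pal, xlab = "z1", ylab = "z2",
                  main = if (what == "pbar") "cell-averaged propensity score"
                         else "normalised sampling weight",
                  useRaster = FALSE)
  if (what == "weight") {
    zero <- which(grid$w == 0, arr.ind = TRUE)
    for (k in seq_len(nrow(zero)))
      graphics::rect(xb[zero[k, 1L]], yb[zero[k, 2L]],
                     xb[zero[k, 1L] + 1L], yb[zero[k, 2L] + 1L],
                     col = "grey85", border = NA)
  }
  graphics::points(z[, 1L], z[, 2L], pch = ifelse(group == 1, 17, 16),
                   col = grDevices::adjustcolor(
                     ifelse(group == 1, "red3", "blue3"), 0.5), cex = 0.6)
  invisible(file)
}
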