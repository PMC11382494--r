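# Empirical-CDF / inverse-normal ("quantile") pre-transformation, the
# non-parametric baseline. Fitted on the training split only; out-of-range
# values are clipped to the training range on inversion and application.

#' Fit the empirical-quantile normal transform
#'
#' Stores the sorted training sample as the reference for the empirical CDF.
#' [apply_quantile_normal()] maps new values through the empirical CDF with
#' rank-based interior offsets (so probabilities stay in \eqn{(0,1)} and the
#' normal inverse CDF stays finite); [invert_quantile_normal()] maps standard
#' normal values back through interpolated empirical quantiles. Values outside
#' the training range are clipped to it and counted.
#'
#' @param x Numeric training vector with at least 2 distinct values.
#' @return Object of class `quantile_params`: list with
#'   `sorted_training_values` and `n`.
#' @export
fit_quantile_normal <- function(x) {
  x <- sort(as.numeric(x))
  if (length(unique(x)) < 2L) stop("fit_quantile_normal: input is constant")
  structure(list(sorted_training_values = x, n = length(x)),
            class = "quantile_params")
}

#' @rdname fit_quantile_normal
#' @param params A `quantile_params` object.
#' @export
apply_quantile_normal <- function(x, params) {
  sv <- params$sorted_training_values
  n <- params$n
  n_clip <- sum(x < sv[1L] | x > sv[n])
  xc <- pmin(pmax(x, sv[1L]), sv[n])
  # empirical CDF with (r - 0.5)/n interior offsets via interpolation on the
  # training order statistics
  # duplicated order statistics are collapsed to their mean plotting position
  p <- stats::approx(sv, (seq_len(n) - 0.5) / n, xout = xc, ties = mean,
                     rule = 2)$y
  out <- stats::qnorm(p)
  if (n_clip > 0L) attr(out, "n_clipped") <- n_clip
  out
}

#' @rdname fit_quantile_normal
#' @param y Numeric vector on the standard-normal scale.
#' @export
invert_quantile_normal <- function(y, params) {
  sv <- params$sorted_training_values
  n <- params$n
  p <- stats::pnorm(y)
  grid <- (seq_len(n) - 0.5) / n
  # clip to the training probability range, then interpolate the empirical
  # quantile function
  p <- pmin(pmax(p, grid[1L]), grid[n])
  stats::approx(grid, sv, xout = p, ties = "ordered", rule = 2)$y
}
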