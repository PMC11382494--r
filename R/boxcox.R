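# Box-Cox power transformation: forward, inverse, and profile-likelihood fit.
# Values of |lambda1| below .bc_log_tol are treated as the log branch so the
# two branches join continuously.

.bc_log_tol <- 1e-4

#' Box-Cox transformation of a numeric vector
#'
#' Applies the shifted Box-Cox power transform
#' \deqn{f(x) = ((x + \lambda_2)^{\lambda_1} - 1)/\lambda_1} for
#' \eqn{\lambda_1 \neq 0} and \eqn{f(x) = \log(x + \lambda_2)} for
#' \eqn{\lambda_1 = 0}. \eqn{\lambda_2} is a shift that makes the data
#' positive; \eqn{\lambda_1} is the power parameter. \eqn{|\lambda_1|}
#' below `1e-4` uses the log branch.
#'
#' @param x Numeric vector.
#' @param params A `boxcox_params` object from [fit_boxcox()], or a list with
#'   elements `lambda1` and `lambda2`.
#' @param clip If `TRUE`, values whose shift `x + lambda2` is nonpositive
#'   (new data below the training support) are clipped to a small positive
#'   shift instead of raising an error; the clip count is attached as
#'   attribute `"n_clipped"`.
#' @return Numeric vector of transformed values.
#' @seealso [invert_boxcox()], [fit_boxcox()]
#' @export
#' @examples
#' apply_boxcox(c(2, 5), list(lambda1 = 1, lambda2 = 0))  # x - 1
apply_boxcox <- function(x, params, clip = FALSE) {
  l1 <- params$lambda1
  l2 <- params$lambda2
  s <- x + l2
  bad <- which(s <= 0)
  if (length(bad) > 0L) {
    if (!clip)
      stop("apply_boxcox: shifted value (x + lambda2) is nonpositive at index ",
           bad[1L], " (value ", format(s[bad[1L]]), ")")
    s[bad] <- min(s[s > 0], 1e-12)
  }
  out <- if (abs(l1) < .bc_log_tol) log(s) else (s^l1 - 1) / l1
  if (clip && length(bad) > 0L) attr(out, "n_clipped") <- length(bad)
  out
}

#' Invert the Box-Cox transformation
#'
#' Back-transforms values produced by [apply_boxcox()]:
#' \eqn{(\lambda_1 y + 1)^{1/\lambda_1} - \lambda_2} for
#' \eqn{\lambda_1 \neq 0}, \eqn{\exp(y) - \lambda_2} for \eqn{\lambda_1 = 0}.
#'
#' @param y Numeric vector on the transformed scale.
#' @param params As in [apply_boxcox()].
#' @param clip If `TRUE`, out-of-support values (\eqn{\lambda_1 y + 1 \le 0},
#'   which a Gaussian decoder can emit) are clipped to the support boundary
#'   instead of raising an error; the clip count is attached as attribute
#'   `"n_clipped"`.
#' @return Numeric vector on the original scale.
#' @export
invert_boxcox <- function(y, params, clip = FALSE) {
  l1 <- params$lambda1
  l2 <- params$lambda2
  if (abs(l1) < .bc_log_tol) return(exp(y) - l2)
  arg <- l1 * y + 1
  n_clip <- sum(arg <= 0)
  if (n_clip > 0L) {
    if (!clip)
      stop("invert_boxcox: lambda1*y + 1 <= 0 at index ", which(arg <= 0)[1L],
           "; decoder output outside the transform support")
    arg <- pmax(arg, 1e-12)
  }
  out <- arg^(1 / l1) - l2
  if (n_clip > 0L) attr(out, "n_clipped") <- n_clip
  out
}

# Profile log-likelihood of lambda1 given the shift lambda2 (Jacobian-corrected
# Gaussian likelihood of the transformed values).
.boxcox_loglik <- function(lambda1, x, lambda2, eps = 1e-8) {
  y <- apply_boxcox(x, list(lambda1 = lambda1, lambda2 = lambda2))
  s2 <- stats::var(y)
  -(length(x) / 2) * log(s2 + eps) + (lambda1 - 1) * sum(log(x + lambda2 + eps))
}

#' Fit a Box-Cox transformation by maximum likelihood
#'
#' The shift is fixed deterministically as
#' \eqn{\lambda_2 = \max(0, -\min(x)) + 10^{-6}\,\mathrm{range}(x)} so that all
#' shifted values are strictly positive, then \eqn{\lambda_1} is fitted by
#' gradient-based maximisation of the profile log-likelihood
#' \deqn{L(\lambda_1) = -\tfrac{N}{2}\log(\sigma^2 + \epsilon)
#'   + (\lambda_1 - 1)\sum_i \log(x_i + \lambda_2 + \epsilon),}
#' where \eqn{\sigma^2} is the variance of the transformed values and
#' \eqn{\epsilon = 10^{-8}} a stability constant.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param lambda1_init Starting value for the power parameter.
#' @param eps Stability constant added inside both logarithms.
#' @return An object of class `boxcox_params`: list with `lambda1`, `lambda2`,
#'   `epsilon`, `loglik`, `converged`, `fit_loss_trace`.
#' @export
fit_boxcox <- function(x, lambda1_init = 1, eps = 1e-8) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) stop("fit_boxcox: input is constant")
  rng <- diff(range(x))
  lambda2 <- max(0, -min(x)) + 1e-6 * rng
  trace <- numeric(0)
  nll <- function(l1) {
    v <- -.boxcox_loglik(l1, x, lambda2, eps)
    if (!is.finite(v)) v <- 1e12
    trace[length(trace) + 1L] <<- v
    v
  }
  opt <- stats::optim(lambda1_init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  structure(list(lambda1 = opt$par, lambda2 = lambda2, epsilon = eps,
                 loglik = -opt$value, converged = opt$convergence == 0L,
                 fit_loss_trace = trace),
            class = "boxcox_params")
}
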