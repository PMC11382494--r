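# Propensity-score model for known sub-groups: two-stage logistic regression
# on the original (untransformed) covariates with p-value variable selection.

#' Fit a propensity-score model for sub-group membership
#'
#' Stage one fits a full logistic regression of the binary group label on all
#' candidate covariates and retains those with Wald p-value below `alpha`
#' (default 0.05); stage two refits on the retained covariates. Predictions
#' are the estimated \eqn{p(g = 1 \mid x)}.
#'
#' @param data Data frame on the original scale.
#' @param group Binary vector (or name of a column in `data`) with both
#'   classes present.
#' @param covariates Character vector of candidate covariate names.
#' @param alpha Selection threshold on the stage-one p-values.
#' @return Object of class `propensity_model`: list with `fit` (the stage-two
#'   `glm`), `selected`, `p_values` (stage one), `alpha`, `separation` flag.
#' @export
fit_propensity <- function(data, group, covariates, alpha = 0.05) {
  if (is.character(group) && length(group) == 1L) group <- data[[group]]
  g <- as.numeric(group)
  if (!all(g %in% c(0, 1)) || length(unique(g)) < 2L)
    stop("fit_propensity: group must be binary with both classes present")
  X <- data[, covariates, drop = FALSE]
  df <- cbind(.g = g, X)
  full <- suppressWarnings(
    stats::glm(.g ~ ., data = df, family = stats::binomial()))
  separation <- !full$converged || any(abs(stats::coef(full)[-1L]) > 15,
                                       na.rm = TRUE)
  pv <- summary(full)$coefficients
  pv <- pv[rownames(pv) != "(Intercept)", 4L, drop = FALSE]
  pv <- stats::setNames(pv[, 1L], rownames(pv))
  # coefficient names of factor expansions map back to their column
  sel <- covariates[vapply(covariates, function(cv)
    any(pv[startsWith(names(pv), cv)] < alpha, na.rm = TRUE), logical(1))]
  if (length(sel) == 0L) {
    warning("fit_propensity: no covariate passed selection; intercept-only model")
    refit <- suppressWarnings(
      stats::glm(.g ~ 1, data = df, family = stats::binomial()))
  } else {
    refit <- suppressWarnings(
      stats::glm(stats::reformulate(sel, ".g"), data = df,
                 family = stats::binomial()))
  }
  if (separation)
    warning("fit_propensity: possible separation; coefficients may be unstable")
  structure(list(fit = refit, selected = sel, p_values = pv, alpha = alpha,
                 separation = separation),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic, p-value selection at alpha =", x$alpha, ")\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Predicted sub-group membership probabilities
#'
#' @param object A `propensity_model`.
#' @param newdata Data frame of covariates; default the training frame.
#' @param ... Unused.
#' @return Vector of probabilities strictly inside \eqn{(0,1)}.
#' @export
predict.propensity_model <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) stats::fitted(object$fit) else
    stats::predict(object$fit, newdata = newdata, type = "response")
  pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
}
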