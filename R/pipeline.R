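# Per-variable invertible transform chain: {none | boxcox | bimodal |
# quantile} per continuous column, then min-max scaling of the transformed
# continuous columns to [0,1]. Binary columns pass through untouched.

.sample_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Suggest a transform per continuous column
#'
#' Flags a column `"bimodal"` when the kernel-density bandwidth ladder finds
#' two or more peaks whose intervening valley is at least 10% deeper than the
#' lower peak, `"boxcox"` when the absolute sample skewness exceeds 0.5, and
#' `"none"` otherwise. The user-supplied assignment always takes precedence;
#' this is a convenience for exploratory use.
#'
#' @param data A data frame.
#' @param continuous Character vector of continuous column names.
#' @return Named character vector of suggested transform kinds.
#' @export
suggest_transforms <- function(data, continuous) {
  vapply(continuous, function(nm) {
    x <- data[[nm]]
    if (kde_valley_init(x)$found) return("bimodal")
    if (abs(.sample_skewness(x)) > 0.5) return("boxcox")
    "none"
  }, character(1))
}

#' Fit the pre-transformation pipeline of a cohort table
#'
#' Fits the assigned transform for every continuous column, then a shared
#' min-max scaling stage mapping each transformed continuous column to
#' \eqn{[0, 1]}. Binary columns are validated as \{0,1\} and passed through.
#'
#' @param data Data frame holding the cohort.
#' @param continuous,binary Character vectors naming the columns of each type.
#' @param assignment Named character vector mapping each continuous column to
#'   one of `"none"`, `"boxcox"`, `"bimodal"`, `"quantile"`. `NULL` uses
#'   [suggest_transforms()].
#' @return Object of class `transform_pipeline`.
#' @seealso [pipeline_forward()], [pipeline_inverse()]
#' @export
fit_pipeline <- function(data, continuous, binary = character(0),
                         assignment = NULL) {
  stopifnot(is.data.frame(data))
  unknown <- setdiff(c(continuous, binary), names(data))
  if (length(unknown) > 0L)
    stop("fit_pipeline: unknown column(s): ", paste(unknown, collapse = ", "))
  for (nm in binary) {
    v <- data[[nm]]
    if (!all(v %in% c(0, 1)))
      stop("fit_pipeline: binary column ", nm, " has values outside {0,1}")
  }
  if (is.null(assignment)) {
    assignment <- suggest_transforms(data, continuous)
  } else {
    miss <- setdiff(continuous, names(assignment))
    if (length(miss) > 0L)
      stop("fit_pipeline: no transform assigned for: ",
           paste(miss, collapse = ", "))
    bad <- setdiff(names(assignment), c(continuous, binary))
    if (length(bad) > 0L)
      stop("fit_pipeline: assignment references unknown column(s): ",
           paste(bad, collapse = ", "))
    ok <- c("none", "boxcox", "bimodal", "quantile")
    if (!all(assignment %in% ok))
      stop("fit_pipeline: transform kind must be one of ",
           paste(ok, collapse = ", "))
  }
  stages <- lapply(continuous, function(nm) {
    kind <- assignment[[nm]]
    x <- data[[nm]]
    params <- switch(kind,
      none = NULL,
      boxcox = fit_boxcox(x),
      bimodal = fit_bimodal(x),
      quantile = fit_quantile_normal(x))
    y <- .stage_forward(x, kind, params)
    list(kind = kind, params = params,
         minimum = min(y), maximum = max(y))
  })
  names(stages) <- continuous
  for (nm in continuous) {
    st <- stages[[nm]]
    if (st$maximum <= st$minimum)
      stop("fit_pipeline: column ", nm, " is constant after transformation")
  }
  structure(list(stages = stages, continuous = continuous, binary = binary),
            class = "transform_pipeline")
}

.stage_forward <- function(x, kind, params, clip = FALSE) {
  switch(kind,
    none = x,
    boxcox = apply_boxcox(x, params, clip = clip),
    bimodal = apply_bimodal(x, params),
    quantile = apply_quantile_normal(x, params))
}

.stage_inverse <- function(y, kind, params) {
  switch(kind,
    none = y,
    boxcox = invert_boxcox(y, params, clip = TRUE),
    bimodal = invert_bimodal(y, params),
    quantile = invert_quantile_normal(y, params))
}

#' Apply a fitted pipeline to a cohort table
#'
#' @param pipeline A `transform_pipeline` from [fit_pipeline()].
#' @param data Data frame with the pipeline's columns.
#' @return Data frame with continuous columns transformed and scaled to
#'   \eqn{[0,1]} (on the training sample) and binary columns unchanged.
#' @export
pipeline_forward <- function(pipeline, data) {
  out <- data[, c(pipeline$continuous, pipeline$binary), drop = FALSE]
  for (nm in pipeline$continuous) {
    st <- pipeline$stages[[nm]]
    # new data below a fitted Box-Cox support is clipped to the support edge,
    # as with the quantile stage's training-range clipping
    y <- .stage_forward(data[[nm]], st$kind, st$params, clip = TRUE)
    out[[nm]] <- (as.numeric(y) - st$minimum) / (st$maximum - st$minimum)
  }
  out
}

#' Invert a fitted pipeline
#'
#' Un-scales each continuous column and applies the per-variable inverse
#' transforms. Decoder outputs outside \eqn{[0,1]} (the Gaussian decoder has
#' unbounded support) are clipped to \eqn{[0,1]} first; the overall clip rate
#' is attached as attribute `"clip_rate"`.
#'
#' @inheritParams pipeline_forward
#' @param data01 Data frame on the transformed \eqn{[0,1]} scale.
#' @export
pipeline_inverse <- function(pipeline, data01) {
  out <- data01[, c(pipeline$continuous, pipeline$binary), drop = FALSE]
  n_clip <- 0L
  n_tot <- 0L
  for (nm in pipeline$continuous) {
    st <- pipeline$stages[[nm]]
    v <- data01[[nm]]
    n_clip <- n_clip + sum(v < 0 | v > 1)
    n_tot <- n_tot + length(v)
    v <- pmin(pmax(v, 0), 1)
    y <- v * (st$maximum - st$minimum) + st$minimum
    out[[nm]] <- as.numeric(.stage_inverse(y, st$kind, st$params))
  }
  if (n_tot > 0L) attr(out, "clip_rate") <- n_clip / n_tot
  out
}
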