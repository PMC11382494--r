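# User-level fitting interface: pre-transformation pipeline + mixed-type VAE
# in one classed model object, in the style of classic R modelling functions.

#' Fit a synthetic-cohort generator to a cohort table
#'
#' Fits the full generative model: per-variable invertible pre-transformations
#' that remove skewness (Box-Cox) and bimodality (signed-power transform)
#' from the continuous margins, min-max scaling to \eqn{[0,1]}, and a
#' variational autoencoder with a joint Gaussian (continuous) + Bernoulli
#' (binary) decoder. Synthetic rows are then obtained with
#' [simulate.synthvae()] by sampling the standard-normal latent prior,
#' decoding, and inverting the pipeline.
#'
#' @param data Data frame holding the cohort. Rows with missing values in the
#'   modelled columns are dropped (with a message).
#' @param continuous,binary Column names of each type. Group-label and
#'   outcome columns should simply be left out of these.
#' @param transforms Named character vector assigning `"none"`, `"boxcox"`,
#'   `"bimodal"` or `"quantile"` to each continuous column; `NULL` asks
#'   [suggest_transforms()].
#' @param config A [vae_config()].
#' @return Object of class `synthvae` with components `pipeline`
#'   (`transform_pipeline`), `vae` (`trained_vae`), `config`, `data01`
#'   (the transformed training table) and `call`.
#' @seealso [simulate.synthvae()], [sample_weighted()], [crossval_utility()]
#' @export
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 1)
#' roles <- attr(cohort, "roles")
#' fit <- synthvae(cohort, continuous = roles$continuous,
#'                 binary = roles$binary, config = vae_config(epochs = 5))
#' syn <- simulate(fit, nsim = 100, seed = 2)
synthvae <- function(data, continuous, binary = character(0),
                     transforms = NULL, config = vae_config()) {
  cl <- match.call()
  cols <- c(continuous, binary)
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!keep))
    message("synthvae: dropping ", sum(!keep), " row(s) with missing values")
  data <- data[keep, , drop = FALSE]
  pipeline <- fit_pipeline(data, continuous, binary, transforms)
  data01 <- pipeline_forward(pipeline, data)
  vae <- train_vae(data01, continuous, binary, config)
  structure(list(pipeline = pipeline, vae = vae, config = config,
                 continuous = continuous, binary = binary,
                 data01 = data01, n = nrow(data01), call = cl),
            class = "synthvae")
}

#' @export
print.synthvae <- function(x, ...) {
  cat("Synthetic-cohort VAE generator\n")
  cat("  n =", x$n, "rows;", length(x$continuous), "continuous,",
      length(x$binary), "binary columns\n")
  kinds <- vapply(x$pipeline$stages, `[[`, "", "kind")
  cat("  transforms:", paste(sprintf("%s=%s", names(kinds), kinds),
                             collapse = ", "), "\n")
  cat("  latent dim", x$config$latent_dim, "| fusion", x$config$fusion,
      "|", x$config$epochs, "epochs\n")
  tr <- x$vae$loss_trace
  cat("  final loss", format(tr$total[nrow(tr)], digits = 5),
      "(recon", format(tr$recon[nrow(tr)], digits = 5),
      "+ KL", format(tr$kl[nrow(tr)], digits = 5), ")\n")
  invisible(x)
}

#' @export
summary.synthvae <- function(object, ...) {
  tr <- object$vae$loss_trace
  stages <- lapply(object$pipeline$stages, function(st) {
    c(kind = st$kind,
      params = switch(st$kind,
        boxcox = sprintf("lambda1=%.3f lambda2=%.3g", st$params$lambda1,
                         st$params$lambda2),
        bimodal = sprintf("alpha=%.3f beta_sq=%.3f rho=%.3f",
                          st$params$alpha, st$params$beta_sq, st$params$rho),
        quantile = sprintf("n_ref=%d", st$params$n),
        none = ""))
  })
  out <- list(n = object$n, config = object$config, stages = stages,
              loss_first = tr$total[1L], loss_final = tr$total[nrow(tr)])
  class(out) <- "summary.synthvae"
  out
}

#' @export
print.summary.synthvae <- function(x, ...) {
  cat("Synthetic-cohort VAE generator (n =", x$n, ")\n\nPre-transformations:\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-14s %-8s %s\n", nm, x$stages[[nm]]["kind"],
                x$stages[[nm]]["params"]))
  cat("\nTraining loss:", format(x$loss_first, digits = 5), "->",
      format(x$loss_final, digits = 5), "over", x$config$epochs, "epochs\n")
  invisible(x)
}

#' Generate synthetic cohort rows from a fitted generator
#'
#' Samples latent points from the standard-normal prior (default; original
#' rows influence output only through the decoder parameters) or from the
#' posterior of the training rows, decodes them through the Gaussian /
#' Bernoulli heads, and inverts the pre-transformation pipeline back to the
#' original scale.
#'
#' @param object A `synthvae` fit.
#' @param nsim Number of synthetic rows.
#' @param seed RNG seed.
#' @param mode `"prior"` or `"posterior"` latent sampling.
#' @param ... Unused.
#' @return Data frame of `nsim` synthetic rows on the original scale.
#' @export
simulate.synthvae <- function(object, nsim = object$n, seed = 1L,
                              mode = c("prior", "posterior"), ...) {
  mode <- match.arg(mode)
  z <- if (mode == "prior") {
    sample_prior(nsim, object$config$latent_dim, seed = seed)
  } else {
    idx_seed <- seed + 1L
    set.seed(idx_seed)
    rows <- sample.int(object$n, nsim, replace = nsim > object$n)
    sample_posterior(object$vae, object$data01[rows, , drop = FALSE],
                     seed = seed)
  }
  t01 <- decode_and_sample(object$vae, z, seed = seed + 2L)
  pipeline_inverse(object$pipeline, t01)
}

#' Posterior-mean latent embedding of rows
#'
#' @param object A `synthvae` fit.
#' @param newdata Data frame on the original scale; default the training data
#'   is not stored on that scale, so the transformed training table is used.
#' @param ... Unused.
#' @return Matrix of posterior means (rows x latent_dim).
#' @export
predict.synthvae <- function(object, newdata = NULL, ...) {
  t01 <- if (is.null(newdata)) object$data01 else
    pipeline_forward(object$pipeline, newdata)
  encode(object$vae, t01)$mu
}

#' Reconstruction residuals on the transformed scale
#'
#' Observed minus decoded-at-posterior-mean values for the continuous
#' columns; observed minus Bernoulli-head probability for binary columns.
#'
#' @param object A `synthvae` fit.
#' @param ... Unused.
#' @export
residuals.synthvae <- function(object, ...) {
  mu <- encode(object$vae, object$data01)$mu
  rec <- decode_and_sample(object$vae, mu, noiseless = TRUE)
  as.data.frame(object$data01[, names(rec), drop = FALSE] - rec)
}

#' Diagnostic plots for a fitted generator
#'
#' `which = "loss"` draws the training-loss trace; `which = "latent"` the
#' 2-D latent embedding of the training rows (first two dimensions).
#'
#' @param x A `synthvae` fit.
#' @param which `"loss"` or `"latent"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.synthvae <- function(x, which = c("loss", "latent"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    tr <- x$vae$loss_trace
    graphics::plot(seq_len(nrow(tr)), tr$total, type = "l", xlab = "epoch",
                   ylab = "mean loss", main = "VAE training loss", ...)
    graphics::lines(seq_len(nrow(tr)), tr$recon, lty = 2)
    graphics::legend("topright", c("total", "reconstruction"), lty = 1:2,
                     bty = "n")
  } else {
    z <- predict.synthvae(x)
    graphics::plot(z[, 1L], z[, 2L], xlab = "z1", ylab = "z2",
                   main = "latent embedding", pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.5), ...)
  }
  invisible(x)
}
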