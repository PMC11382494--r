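# pMSE utility metric: CART classifier distinguishing original from
# synthetic rows, its permutation null, and a k-fold CV evaluation harness.

#' Utility-metric configuration
#'
#' @param min_leaf Minimum leaf size of the CART classifier (default 20).
#' @param max_depth Maximum tree depth (default 25).
#' @param n_permutations Label permutations for the null (default 100).
#' @param seed RNG seed for the permutation stream.
#' @export
utility_config <- function(min_leaf = 20L, max_depth = 25L,
                           n_permutations = 100L, seed = 1L) {
  stopifnot(min_leaf >= 1L, max_depth >= 1L, n_permutations >= 1L)
  structure(list(min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "utility_config")
}

# CART probability of the synthetic label for each stacked row
.cart_prob <- function(features, y, config) {
  df <- cbind(.y = factor(y, levels = c(0, 1)), features)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minbucket = config$min_leaf,
                        maxdepth = min(config$max_depth, 30L),
                        cp = 0, xval = 0, minsplit = 2L * config$min_leaf))
  stats::predict(fit, type = "prob")[, "1"]
}

#' pMSE utility statistic
#'
#' Stacks the original and synthetic tables with an indicator
#' \eqn{y_i = 1} for synthetic rows, fits a CART classifier on the stacked
#' features, and returns
#' \deqn{\psi = \frac1N \sum_{i=1}^N (\hat y_i - c)^2, \qquad
#'       c = n_{syn}/N.}
#' \eqn{\psi = 0} when the classifier cannot beat the constant \eqn{c}
#' (indistinguishable tables); \eqn{\psi = c(1-c)\,\max(c,1-c)}-scale values
#' indicate separable tables.
#'
#' @param original,synthetic Data frames with identical columns.
#' @param config A [utility_config()].
#' @return List of class `pmse_result`: `psi`, `c`, `yhat`, `n_orig`,
#'   `n_syn`.
#' @export
pmse <- function(original, synthetic, config = utility_config()) {
  if (!identical(sort(names(original)), sort(names(synthetic))))
    stop("pmse: original and synthetic tables must have the same columns")
  synthetic <- synthetic[, names(original), drop = FALSE]
  feats <- rbind(original, synthetic)
  y <- rep(c(0, 1), c(nrow(original), nrow(synthetic)))
  cc <- nrow(synthetic) / length(y)
  yhat <- .cart_prob(feats, y, config)
  structure(list(psi = mean((yhat - cc)^2), c = cc, yhat = yhat,
                 n_orig = nrow(original), n_syn = nrow(synthetic)),
            class = "pmse_result")
}

#' Permutation null of the pMSE statistic
#'
#' Recomputes \eqn{\psi} after permuting the original/synthetic labels on the
#' stacked table (rows fixed, labels resampled per permutation from a seeded
#' stream), giving the distribution of \eqn{\psi} under the null that the two
#' tables are indistinguishable, and its mean \eqn{\bar\psi}.
#'
#' @inheritParams pmse
#' @return List of class `pmse_null`: `psi_bar`, `psi_perm`,
#'   `n_permutations`.
#' @export
permutation_null <- function(original, synthetic, config = utility_config()) {
  if (!identical(sort(names(original)), sort(names(synthetic))))
    stop("permutation_null: tables must have the same columns")
  synthetic <- synthetic[, names(original), drop = FALSE]
  feats <- rbind(original, synthetic)
  y <- rep(c(0, 1), c(nrow(original), nrow(synthetic)))
  cc <- mean(y)
  set.seed(config$seed)
  psi_perm <- vapply(seq_len(config$n_permutations), function(j) {
    yp <- sample(y)
    mean((.cart_prob(feats, yp, config) - cc)^2)
  }, numeric(1))
  structure(list(psi_bar = mean(psi_perm), psi_perm = psi_perm,
                 n_permutations = config$n_permutations),
            class = "pmse_null")
}

#' pMSE ratio
#'
#' \eqn{\psi_{ratio} = \psi / \bar\psi}; values near 1 mean the classifier
#' does no better on the true labels than on permuted ones, i.e. the
#' synthetic data is original-like.
#'
#' @param psi Observed pMSE (or a `pmse_result`).
#' @param psi_bar Permutation-null mean (or a `pmse_null`).
#' @return Scalar ratio; `NA` with a warning when `psi_bar` is zero.
#' @export
psi_ratio <- function(psi, psi_bar) {
  if (inherits(psi, "pmse_result")) psi <- psi$psi
  if (inherits(psi_bar, "pmse_null")) psi_bar <- psi_bar$psi_bar
  if (psi_bar <= 0) {
    warning("psi_ratio: psi_bar is zero; ratio undefined")
    return(NA_real_)
  }
  psi / psi_bar
}

#' Cross-validated utility evaluation of a generator
#'
#' Splits the cohort into `k` folds; per fold, calls
#' `generator(train, m, seed)` to obtain `m =` heldout-size synthetic rows
#' from a model fitted on the training part only, and computes \eqn{\psi},
#' \eqn{\bar\psi} and \eqn{\psi_{ratio}} against the heldout originals.
#' The default generator fits the full [synthvae()] model per fold and
#' samples the prior; any function with the same signature (for instance a
#' resampler of the training rows) can be evaluated.
#'
#' @param data Cohort data frame.
#' @param continuous,binary Feature columns given to the classifier (group
#'   label and outcome columns should be left out).
#' @param generator `function(train, m, seed) -> data.frame`, or `NULL` for
#'   the default synthvae generator.
#' @param k Number of folds (default 10).
#' @param config A [utility_config()].
#' @param vae_cfg A [vae_config()] for the default generator.
#' @param transforms Transform assignment for the default generator.
#' @param seed Seed for the fold partition and per-fold generator seeds.
#' @return List of class `utility_cv`: per-fold data frame `folds`
#'   (`psi`, `psi_bar`, `psi_ratio`, `failed`), summary rows `mean` and `sd`,
#'   and `loss_traces` (per-fold training/heldout traces when the default
#'   generator is used).
#' @export
crossval_utility <- function(data, continuous, binary = character(0),
                             generator = NULL, k = 10L,
                             config = utility_config(),
                             vae_cfg = vae_config(), transforms = NULL,
                             seed = 1L) {
  stopifnot(k >= 2L)
  cols <- c(continuous, binary)
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
               drop = FALSE]
  n <- nrow(data)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(k), n))
  loss_traces <- vector("list", k)
  default_gen <- is.null(generator)
  res <- lapply(seq_len(k), function(f) {
    train <- data[fold_id != f, , drop = FALSE]
    held <- data[fold_id == f, , drop = FALSE]
    fold_seed <- seed + f
    syn <- tryCatch({
      if (default_gen) {
        cfg <- vae_cfg
        cfg$seed <- fold_seed
        fit <- synthvae(train, continuous, binary, transforms = transforms,
                        config = cfg)
        held01 <- pipeline_forward(fit$pipeline, held)
        loss_traces[[f]] <<- cbind(fit$vae$loss_trace,
          heldout_final = .eval_loss(fit$vae, as.matrix(held01))[["recon"]])
        simulate(fit, nsim = nrow(held), seed = fold_seed)
      } else {
        generator(train, nrow(held), fold_seed)
      }
    }, error = function(e) e)
    if (inherits(syn, "error")) {
      warning("crossval_utility: fold ", f, " failed: ", conditionMessage(syn))
      return(data.frame(psi = NA, psi_bar = NA, psi_ratio = NA, failed = TRUE))
    }
    cfg_f <- config; cfg_f$seed <- fold_seed
    ps <- pmse(held, syn, cfg_f)
    nl <- permutation_null(held, syn, cfg_f)
    data.frame(psi = ps$psi, psi_bar = nl$psi_bar,
               psi_ratio = psi_ratio(ps, nl), failed = FALSE)
  })
  folds <- do.call(rbind, res)
  ok <- !folds$failed
  structure(list(folds = folds,
                 mean = colMeans(folds[ok, 1:3, drop = FALSE]),
                 sd = apply(folds[ok, 1:3, drop = FALSE], 2L, stats::sd),
                 k = k, fold_id = fold_id, loss_traces = loss_traces),
            class = "utility_cv")
}

#' @export
print.utility_cv <- function(x, ...) {
  cat("Cross-validated utility (", x$k, "folds,",
      sum(!x$folds$failed), "completed )\n")
  for (nm in c("psi", "psi_bar", "psi_ratio"))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}
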