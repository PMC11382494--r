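# Mixed-type variational autoencoder: Gaussian likelihood for continuous
# columns (already pipeline-transformed into [0,1]), Bernoulli likelihood for
# binary columns, diagonal-Gaussian posterior, standard-normal prior.

#' VAE configuration
#'
#' @param latent_dim Latent dimensionality (default 2; small by design — a
#'   richer model invites overfitting and with it data disclosure).
#' @param enc_hidden,dec_hidden Hidden layer widths (tanh activations).
#' @param fusion `"early"` concatenates continuous and binary inputs into one
#'   encoder; `"late"` trains separate encoders per type and averages their
#'   posterior means and log-variances.
#' @param epochs,batch_size,lr Training schedule (Adam).
#' @param sigma_floor Additive floor on the decoder's Gaussian scale head.
#' @param seed Seed controlling initialisation, shuffling and the
#'   reparameterisation noise.
#' @return List of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 2L, enc_hidden = c(32L, 16L),
                       dec_hidden = c(16L, 32L), fusion = c("early", "late"),
                       epochs = 200L, batch_size = 64L, lr = 1e-3,
                       sigma_floor = 1e-4, seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(latent_dim >= 1L, all(enc_hidden > 0L), all(dec_hidden > 0L),
            epochs >= 1L, batch_size >= 1L, lr > 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 enc_hidden = as.integer(enc_hidden),
                 dec_hidden = as.integer(dec_hidden), fusion = fusion,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 sigma_floor = sigma_floor, seed = as.integer(seed)),
            class = "vae_config")
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' \deqn{D_{KL}\big(N(\mu, \mathrm{diag}(e^{\mathrm{logvar}}))\,\|\,N(0,I)\big)
#'   = \tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - \log \sigma_d^2 - 1).}
#'
#' @param mu,logvar Numeric vectors (one posterior) or matrices (rows =
#'   posteriors).
#' @return Nonnegative scalar, or vector of per-row values for matrix input.
#' @export
kl_diag_gaussian <- function(mu, logvar) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)))
  if (is.matrix(mu)) {
    0.5 * rowSums(mu^2 + exp(logvar) - logvar - 1)
  } else {
    0.5 * sum(mu^2 + exp(logvar) - logvar - 1)
  }
}

#' Mixed-type reconstruction loss for one row
#'
#' Negative log-density of the observed row under the decoder heads: a
#' Bernoulli term per binary column and a Gaussian term per continuous
#' column,
#' \deqn{-\sum_k \log \mathrm{Bern}(x_k; \pi_k)
#'       -\sum_j \log N(x_j; \mu_j, \sigma_j).}
#' Probabilities exactly 0 or 1 are clamped to \eqn{[10^{-7}, 1-10^{-7}]}.
#'
#' @param x_continuous,x_binary Observed values (either may be empty).
#' @param mu,sigma Gaussian head outputs for the continuous columns.
#' @param pi Bernoulli head probabilities for the binary columns.
#' @return Scalar negative log-likelihood.
#' @export
reconstruction_loss <- function(x_continuous = numeric(0), mu = numeric(0),
                                sigma = numeric(0), x_binary = numeric(0),
                                pi = numeric(0)) {
  stopifnot(length(x_continuous) == length(mu),
            length(mu) == length(sigma),
            length(x_binary) == length(pi))
  loss <- 0
  if (length(x_binary) > 0L) {
    stopifnot(all(x_binary %in% c(0, 1)))
    p <- pmin(pmax(pi, 1e-7), 1 - 1e-7)
    loss <- loss - sum(x_binary * log(p) + (1 - x_binary) * log(1 - p))
  }
  if (length(x_continuous) > 0L) {
    stopifnot(all(sigma > 0))
    loss <- loss - sum(stats::dnorm(x_continuous, mu, sigma, log = TRUE))
  }
  loss
}

# split a decoder output matrix into its heads
.dec_heads <- function(out, pc, pb, sigma_floor) {
  mu <- if (pc > 0L) out[, seq_len(pc), drop = FALSE] else NULL
  sigma <- if (pc > 0L)
    .softplus(out[, pc + seq_len(pc), drop = FALSE]) + sigma_floor else NULL
  logits <- if (pb > 0L) out[, 2L * pc + seq_len(pb), drop = FALSE] else NULL
  pi <- if (pb > 0L) stats::plogis(logits) else NULL
  list(mu = mu, sigma = sigma, logits = logits, pi = pi)
}

# encoder forward for one or two (late-fusion) encoders
.encode_raw <- function(vae, X) {
  Ld <- vae$config$latent_dim
  if (vae$config$fusion == "late" && vae$pc > 0L && vae$pb > 0L) {
    cc <- .mlp_forward(vae$enc_c, X[, seq_len(vae$pc), drop = FALSE])
    cb <- .mlp_forward(vae$enc_b, X[, vae$pc + seq_len(vae$pb), drop = FALSE])
    mu <- (cc$out[, seq_len(Ld), drop = FALSE] +
           cb$out[, seq_len(Ld), drop = FALSE]) / 2
    lv <- (cc$out[, Ld + seq_len(Ld), drop = FALSE] +
           cb$out[, Ld + seq_len(Ld), drop = FALSE]) / 2
    list(mu = mu, logvar = lv, cache_c = cc, cache_b = cb)
  } else {
    cc <- .mlp_forward(vae$enc, X)
    list(mu = cc$out[, seq_len(Ld), drop = FALSE],
         logvar = cc$out[, Ld + seq_len(Ld), drop = FALSE], cache = cc)
  }
}

# mean per-row loss (recon + KL) of a data matrix at the posterior mean
.eval_loss <- function(vae, X) {
  enc <- .encode_raw(vae, X)
  dec <- .mlp_forward(vae$dec, enc$mu)
  heads <- .dec_heads(dec$out, vae$pc, vae$pb, vae$config$sigma_floor)
  recon <- 0
  if (vae$pc > 0L) {
    Xc <- X[, seq_len(vae$pc), drop = FALSE]
    recon <- recon - rowSums(stats::dnorm(Xc, heads$mu, heads$sigma, log = TRUE))
  }
  if (vae$pb > 0L) {
    Xb <- X[, vae$pc + seq_len(vae$pb), drop = FALSE]
    recon <- recon + rowSums(.softplus(heads$logits) - Xb * heads$logits)
  }
  kl <- kl_diag_gaussian(enc$mu, enc$logvar)
  c(recon = mean(recon), kl = mean(kl), total = mean(recon + kl))
}

#' Train the mixed-type VAE
#'
#' Minimises, by Adam with one reparameterisation sample per row per step,
#' the per-row loss: Bernoulli negative log-likelihood over binary columns
#' plus Gaussian negative log-likelihood over continuous columns plus the KL
#' divergence of the diagonal-Gaussian posterior from the standard-normal
#' prior. Continuous columns must already be pipeline-transformed into
#' \eqn{[0,1]}; binary columns are modelled on \{0,1\} unscaled.
#'
#' @param table01 Data frame of transformed continuous and binary columns,
#'   no missing values.
#' @param continuous,binary Column names of each type.
#' @param config A [vae_config()].
#' @param heldout Optional data frame on the same scale; its reconstruction
#'   loss (at the posterior mean) is recorded per epoch.
#' @return Object of class `trained_vae` with the network parameters, the
#'   per-epoch loss trace (`loss_trace`: columns `recon`, `kl`, `total`, and
#'   `heldout_recon` when `heldout` is given), and the configuration.
#' @export
train_vae <- function(table01, continuous, binary = character(0),
                      config = vae_config(), heldout = NULL) {
  X <- as.matrix(table01[, c(continuous, binary), drop = FALSE])
  if (anyNA(X)) stop("train_vae: missing values in input")
  pc <- length(continuous); pb <- length(binary)
  if (pc > 0L) {
    rng_c <- range(X[, seq_len(pc)])
    if (rng_c[1L] < -1e-8 || rng_c[2L] > 1 + 1e-8)
      stop("train_vae: continuous columns must be scaled into [0,1]")
  }
  n <- nrow(X)
  Ld <- config$latent_dim
  set.seed(config$seed)
  vae <- list(config = config, pc = pc, pb = pb,
              continuous = continuous, binary = binary)
  late <- config$fusion == "late" && pc > 0L && pb > 0L
  if (late) {
    vae$enc_c <- .mlp_init(c(pc, config$enc_hidden, 2L * Ld))
    vae$enc_b <- .mlp_init(c(pb, config$enc_hidden, 2L * Ld))
  } else {
    vae$enc <- .mlp_init(c(pc + pb, config$enc_hidden, 2L * Ld))
  }
  vae$dec <- .mlp_init(c(Ld, config$dec_hidden, 2L * pc + pb))
  states <- lapply(vae[intersect(c("enc", "enc_c", "enc_b", "dec"),
                                 names(vae))], .adam_init)
  trace <- matrix(NA_real_, config$epochs, 4L,
                  dimnames = list(NULL, c("recon", "kl", "total",
                                          "heldout_recon")))
  Xh <- if (!is.null(heldout))
    as.matrix(heldout[, c(continuous, binary), drop = FALSE]) else NULL

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_recon <- 0; ep_kl <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      B <- X[idx, , drop = FALSE]
      m <- nrow(B)
      enc <- .encode_raw(vae, B)
      eps <- matrix(stats::rnorm(m * Ld), m, Ld)
      sd_post <- exp(0.5 * enc$logvar)
      z <- enc$mu + eps * sd_post
      dec <- .mlp_forward(vae$dec, z)
      heads <- .dec_heads(dec$out, pc, pb, config$sigma_floor)

      # loss pieces and gradients w.r.t. the decoder's linear outputs
      dOut <- matrix(0, m, 2L * pc + pb)
      recon_row <- numeric(m)
      if (pc > 0L) {
        Bc <- B[, seq_len(pc), drop = FALSE]
        dmu <- (heads$mu - Bc) / heads$sigma^2
        dsig <- 1 / heads$sigma - (Bc - heads$mu)^2 / heads$sigma^3
        sraw <- dec$out[, pc + seq_len(pc), drop = FALSE]
        dOut[, seq_len(pc)] <- dmu / m
        dOut[, pc + seq_len(pc)] <- dsig * stats::plogis(sraw) / m
        recon_row <- recon_row -
          rowSums(stats::dnorm(Bc, heads$mu, heads$sigma, log = TRUE))
      }
      if (pb > 0L) {
        Bb <- B[, pc + seq_len(pb), drop = FALSE]
        dOut[, 2L * pc + seq_len(pb)] <- (heads$pi - Bb) / m
        recon_row <- recon_row +
          rowSums(.softplus(heads$logits) - Bb * heads$logits)
      }
      gdec <- .mlp_backward(vae$dec, dec, dOut)
      dz <- gdec$dX
      dmu_post <- dz + enc$mu / m
      dlv <- dz * eps * 0.5 * sd_post + 0.5 * (exp(enc$logvar) - 1) / m
      dEnc <- cbind(dmu_post, dlv)

      if (!is.finite(sum(recon_row)))
        stop("train_vae: non-finite loss at epoch ", epoch)

      up <- .adam_step(vae$dec, gdec, states$dec, config$lr)
      vae$dec <- up$net; states$dec <- up$state
      if (late) {
        g <- .mlp_backward(vae$enc_c, enc$cache_c, dEnc / 2)
        up <- .adam_step(vae$enc_c, g, states$enc_c, config$lr)
        vae$enc_c <- up$net; states$enc_c <- up$state
        g <- .mlp_backward(vae$enc_b, enc$cache_b, dEnc / 2)
        up <- .adam_step(vae$enc_b, g, states$enc_b, config$lr)
        vae$enc_b <- up$net; states$enc_b <- up$state
      } else {
        g <- .mlp_backward(vae$enc, enc$cache, dEnc)
        up <- .adam_step(vae$enc, g, states$enc, config$lr)
        vae$enc <- up$net; states$enc <- up$state
      }
      ep_recon <- ep_recon + sum(recon_row)
      ep_kl <- ep_kl + sum(kl_diag_gaussian(enc$mu, enc$logvar))
    }
    trace[epoch, "recon"] <- ep_recon / n
    trace[epoch, "kl"] <- ep_kl / n
    trace[epoch, "total"] <- (ep_recon + ep_kl) / n
    if (!is.null(Xh)) trace[epoch, "heldout_recon"] <- .eval_loss(vae, Xh)["recon"]
  }
  vae$loss_trace <- as.data.frame(trace)
  class(vae) <- "trained_vae"
  vae
}

#' Posterior parameters of rows under a trained VAE
#'
#' @param vae A `trained_vae`.
#' @param table01 Data frame on the model's transformed scale.
#' @return List with matrices `mu` and `logvar` (rows = input rows).
#' @export
encode <- function(vae, table01) {
  X <- as.matrix(table01[, c(vae$continuous, vae$binary), drop = FALSE])
  enc <- .encode_raw(vae, X)
  list(mu = enc$mu, logvar = enc$logvar)
}

#' Sample latent points from the posterior of observed rows
#'
#' @inheritParams encode
#' @param seed Seed for the reparameterisation noise.
#' @param noise_scale Multiplier on the posterior standard deviation; 0
#'   returns the posterior means.
#' @return Matrix of latent points (rows = input rows).
#' @export
sample_posterior <- function(vae, table01, seed = 1L, noise_scale = 1) {
  enc <- encode(vae, table01)
  set.seed(seed)
  eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
  enc$mu + noise_scale * eps * exp(0.5 * enc$logvar)
}

#' Sample latent points from the standard-normal prior
#'
#' @param n Number of points (0 gives a 0-row matrix).
#' @param latent_dim Latent dimensionality.
#' @param seed RNG seed.
#' @export
sample_prior <- function(n, latent_dim = 2L, seed = 1L) {
  set.seed(seed)
  matrix(stats::rnorm(n * latent_dim), n, latent_dim)
}

#' Decode latent points into rows on the transformed scale
#'
#' Continuous columns are drawn from the decoder's per-row Gaussian heads and
#' binary columns from its Bernoulli heads; with `noiseless = TRUE` the head
#' parameters \eqn{(\mu_D, \pi_D)} are returned directly.
#'
#' @param vae A `trained_vae`.
#' @param z Matrix of latent points with `latent_dim` columns.
#' @param seed RNG seed for the output sampling.
#' @param noiseless Return head parameters instead of samples.
#' @return Data frame on the \eqn{[0,1]}/\{0,1\} transformed scale.
#' @export
decode_and_sample <- function(vae, z, seed = 1L, noiseless = FALSE) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == vae$config$latent_dim)
  dec <- .mlp_forward(vae$dec, z)
  heads <- .dec_heads(dec$out, vae$pc, vae$pb, vae$config$sigma_floor)
  n <- nrow(z)
  out <- matrix(NA_real_, n, vae$pc + vae$pb,
                dimnames = list(NULL, c(vae$continuous, vae$binary)))
  if (!noiseless) set.seed(seed)
  if (vae$pc > 0L) {
    out[, seq_len(vae$pc)] <- if (noiseless) heads$mu else
      matrix(stats::rnorm(n * vae$pc, heads$mu, heads$sigma), n, vae$pc)
  }
  if (vae$pb > 0L) {
    out[, vae$pc + seq_len(vae$pb)] <- if (noiseless) heads$pi else
      matrix(as.numeric(stats::runif(n * vae$pb) < heads$pi), n, vae$pb)
  }
  as.data.frame(out)
}
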