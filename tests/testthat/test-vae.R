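test_that("closed-form KL matches the trivial cases and a Monte-Carlo oracle", {
  expect_equal(kl_diag_gaussian(0, 0), 0)
  expect_equal(kl_diag_gaussian(1, 0), 0.5)
  set.seed(51)
  mu <- c(0.7, -1.2, 0.3)
  lv <- c(0.4, -0.8, 0.1)
  z <- matrix(rnorm(3e5 * 3, rep(mu, each = 3e5), rep(exp(lv / 2), each = 3e5)),
              ncol = 3)
  lq <- rowSums(dnorm(z, rep(mu, each = 3e5), rep(exp(lv / 2), each = 3e5),
                      log = TRUE))
  lp <- rowSums(dnorm(z, log = TRUE))
  diffs <- lq - lp
  mc <- mean(diffs)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(kl_diag_gaussian(mu, lv) - mc), 3 * se)
  expect_true(all(kl_diag_gaussian(matrix(rnorm(20), 5), matrix(rnorm(20), 5)) >= 0))
})

test_that("reconstruction loss reproduces the independent-term log-densities", {
  expect_equal(reconstruction_loss(x_binary = 1, pi = 0.5), -log(0.5))
  expect_equal(reconstruction_loss(x_continuous = 0.3, mu = 0.3, sigma = 1),
               0.5 * log(2 * base::pi))
  # mixed row: sum of the two independent terms
  expect_equal(
    reconstruction_loss(x_continuous = 0.2, mu = 0.5, sigma = 0.3,
                        x_binary = 0, pi = 0.8),
    -dnorm(0.2, 0.5, 0.3, log = TRUE) - log(0.2))
  # clamped probability keeps the loss finite
  expect_true(is.finite(reconstruction_loss(x_binary = 1, pi = 0)))
})

test_that("training reduces the loss, is seed-deterministic, and decomposes exactly", {
  sc <- small_cohort(n = 300, seed = 52)
  asg <- setNames(rep("none", 9), sc$roles$continuous)
  pl <- fit_pipeline(sc$data, sc$roles$continuous, sc$roles$binary, asg)
  t01 <- pipeline_forward(pl, sc$data)
  cfg <- fast_cfg(epochs = 20)
  v1 <- train_vae(t01, sc$roles$continuous, sc$roles$binary, cfg)
  expect_lt(v1$loss_trace$total[20], v1$loss_trace$total[1])
  expect_equal(v1$loss_trace$total, v1$loss_trace$recon + v1$loss_trace$kl)
  v2 <- train_vae(t01, sc$roles$continuous, sc$roles$binary, cfg)
  expect_identical(v1$loss_trace, v2$loss_trace)
  # late fusion trains too, with separate encoders
  v3 <- train_vae(t01, sc$roles$continuous, sc$roles$binary,
                  fast_cfg(epochs = 10, fusion = "late"))
  expect_true(!is.null(v3$enc_c) && !is.null(v3$enc_b))
  expect_lt(v3$loss_trace$total[10], v3$loss_trace$total[1])
})

test_that("encoding is deterministic and posterior sampling concentrates on the mean", {
  sc <- small_cohort(n = 200, seed = 53)
  asg <- setNames(rep("none", 9), sc$roles$continuous)
  pl <- fit_pipeline(sc$data, sc$roles$continuous, sc$roles$binary, asg)
  t01 <- pipeline_forward(pl, sc$data)
  v <- train_vae(t01, sc$roles$continuous, sc$roles$binary, fast_cfg(epochs = 5))
  e1 <- encode(v, t01)
  e2 <- encode(v, t01)
  expect_identical(e1, e2)
  expect_equal(sample_posterior(v, t01, seed = 3, noise_scale = 0), e1$mu,
               ignore_attr = TRUE)
  # empirical mean of many posterior samples of one row ~ its posterior mean
  row1 <- t01[rep(1, 10000), , drop = FALSE]
  zs <- sample_posterior(v, row1, seed = 4)
  se <- apply(zs, 2, sd) / sqrt(nrow(zs))
  expect_true(all(abs(colMeans(zs) - e1$mu[1, ]) < 3 * se))
})

test_that("prior sampling is standard normal and reproducible", {
  expect_equal(nrow(sample_prior(0, 2)), 0)
  z <- sample_prior(10000, 2, seed = 6)
  expect_true(all(abs(colMeans(z)) < 3 / sqrt(10000)))
  expect_identical(z, sample_prior(10000, 2, seed = 6))
})

test_that("decoding respects its heads: noiseless determinism and Bernoulli rates", {
  sc <- small_cohort(n = 200, seed = 54)
  asg <- setNames(rep("none", 9), sc$roles$continuous)
  pl <- fit_pipeline(sc$data, sc$roles$continuous, sc$roles$binary, asg)
  t01 <- pipeline_forward(pl, sc$data)
  v <- train_vae(t01, sc$roles$continuous, sc$roles$binary, fast_cfg(epochs = 5))
  z0 <- matrix(c(0.3, -0.5), 1)
  d1 <- decode_and_sample(v, z0, noiseless = TRUE)
  d2 <- decode_and_sample(v, z0, noiseless = TRUE)
  expect_identical(d1, d2)
  # empirical Bernoulli rate over many decodes of one z matches pi_D(z)
  many <- decode_and_sample(v, z0[rep(1, 10000), , drop = FALSE], seed = 7)
  b1 <- sc$roles$binary[1]
  p <- d1[[b1]]
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(many[[b1]]) - p), 3 * se + 1e-12)
  expect_error(decode_and_sample(v, matrix(0, 1, 3)), "latent_dim")
})
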