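# Shared fixture builders; everything is generated in code at test time.

# the exposure-linked 0/4 mixture the bimodal transform targets
mixture_fixture <- function(n = 2500L, prev = 0.25, seed = 100L) {
  set.seed(seed)
  E <- stats::rbinom(n, 1L, prev)
  list(x = stats::rnorm(n, 4 * E, 1), E = E)
}

small_cohort <- function(n = 400L, seed = 21L) {
  co <- simulate_cohort(n = n, seed = seed)
  list(data = co, roles = attr(co, "roles"))
}

# quick VAE config for training sanity tests
fast_cfg <- function(epochs = 20L, seed = 5L, ...) {
  vae_config(epochs = epochs, seed = seed, ...)
}

# type-7 quantile written out independently of stats::quantile, as the
# oracle for the 1-sigma criterion hand evaluation
quantile_type7_manual <- function(x, tau) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * tau + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}
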