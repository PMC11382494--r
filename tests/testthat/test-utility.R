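test_that("pMSE hits its closed-form values in degenerate designs", {
  # uninformative features: the tree predicts the constant c, so psi = 0
  orig <- data.frame(x = rep(1, 40))
  syn <- data.frame(x = rep(1, 40))
  r0 <- pmse(orig, syn, utility_config(min_leaf = 5))
  expect_equal(r0$psi, 0)
  expect_equal(r0$c, 0.5)
  # perfectly separable tables with n_syn = n_orig: psi = mean((y-0.5)^2) = 0.25
  orig2 <- data.frame(x = rnorm(40, 0, 0.1))
  syn2 <- data.frame(x = rnorm(40, 10, 0.1))
  r1 <- pmse(orig2, syn2, utility_config(min_leaf = 5))
  expect_equal(r1$psi, 0.25)
  expect_error(pmse(orig, data.frame(zzz = 1:3)), "same columns")
})

test_that("a depth-1 tree on a fixed 8-row table gives the hand-computed pMSE", {
  # split on x: left leaf 3 original + 1 synthetic (yhat 0.25),
  #             right leaf 1 original + 3 synthetic (yhat 0.75)
  orig <- data.frame(x = c(0, 0, 0, 1))
  syn <- data.frame(x = c(0, 1, 1, 1))
  r <- pmse(orig, syn, utility_config(min_leaf = 2, max_depth = 1))
  expect_equal(r$psi, mean(c(rep((0.25 - 0.5)^2, 4), rep((0.75 - 0.5)^2, 4))))
  expect_equal(sort(unique(r$yhat)), c(0.25, 0.75))
})

test_that("psi is invariant to row order and bounded as expected", {
  sc <- small_cohort(n = 200, seed = 91)
  feats <- sc$data[, c(sc$roles$continuous, sc$roles$binary)]
  a <- feats[1:100, ]; b <- feats[101:200, ]
  cfg <- utility_config(seed = 1)
  p1 <- pmse(a, b, cfg)$psi
  set.seed(2)
  p2 <- pmse(a[sample(100), ], b[sample(100), ], cfg)$psi
  expect_equal(p1, p2)
  cc <- 0.5
  expect_lte(p1, max(cc, 1 - cc)^2)
  expect_gte(p1, 0)
})

test_that("permutation null is seeded, and an independent same-law sample sits inside it", {
  co <- simulate_cohort(n = 600, seed = 92)
  roles <- attr(co, "roles")
  feats <- co[, c(roles$continuous, roles$binary)]
  a <- feats[1:300, ]; b <- feats[301:600, ]
  cfg <- utility_config(n_permutations = 40, seed = 93)
  nl <- permutation_null(a, b, cfg)
  nl2 <- permutation_null(a, b, cfg)
  expect_identical(nl$psi_perm, nl2$psi_perm)   # fixed seed, fixed sequence
  expect_equal(nl$psi_bar, mean(nl$psi_perm))
  p <- pmse(a, b, cfg)$psi
  band <- quantile(nl$psi_perm, c(0.005, 0.995))
  expect_gte(p, band[[1]])
  expect_lte(p, band[[2]])
  # doubling the permutations moves the mean by < 5%
  nl_big <- permutation_null(a, b, utility_config(n_permutations = 80, seed = 93))
  expect_lt(abs(nl_big$psi_bar - nl$psi_bar) / nl$psi_bar, 0.05)
})

test_that("psi_ratio is the plain quotient with a guarded denominator", {
  expect_equal(psi_ratio(0.05, 0.05), 1)
  expect_equal(psi_ratio(0, 0.05), 0)
  expect_warning(r <- psi_ratio(0.1, 0), "undefined")
  expect_true(is.na(r))
})

test_that("cross-validated harness: partition integrity and self-resampling near 1", {
  co <- simulate_cohort(n = 500, seed = 94)
  roles <- attr(co, "roles")
  resampler <- function(train, m, seed) {
    set.seed(seed)
    train[sample(nrow(train), m), ]
  }
  cv <- crossval_utility(co, roles$continuous, roles$binary,
                         generator = resampler, k = 5,
                         config = utility_config(n_permutations = 20, seed = 95),
                         seed = 95)
  expect_equal(length(cv$fold_id), 500L)
  expect_true(all(table(cv$fold_id) == 100L))  # each row heldout exactly once
  expect_false(any(cv$folds$failed))
  # resampling the training part is a same-distribution generator
  expect_gt(cv$mean[["psi_ratio"]], 0.6)
  expect_lt(cv$mean[["psi_ratio"]], 1.4)
  expect_output(print(cv), "psi_ratio")
  # reproducible partition
  cv2 <- crossval_utility(co, roles$continuous, roles$binary,
                          generator = resampler, k = 5,
                          config = utility_config(n_permutations = 20, seed = 95),
                          seed = 95)
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_equal(cv$folds$psi, cv2$folds$psi)
})

test_that("a 2-fold run on a tiny table works end to end with the default generator", {
  co <- simulate_cohort(n = 60, seed = 96)
  roles <- attr(co, "roles")
  asg <- setNames(rep("none", 9), roles$continuous)
  cv <- crossval_utility(co, roles$continuous, roles$binary, k = 2,
                         config = utility_config(n_permutations = 5, seed = 97),
                         vae_cfg = fast_cfg(epochs = 3), transforms = asg,
                         seed = 97)
  expect_equal(nrow(cv$folds), 2L)
  expect_true(all(is.finite(cv$folds$psi)))
  expect_length(cv$loss_traces, 2L)
  expect_false(is.null(cv$loss_traces[[1]]))
})
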