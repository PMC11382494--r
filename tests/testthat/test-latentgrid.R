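toy_grid <- function(w, d = 1, origin = c(-3, -3), N1 = nrow(w), N2 = ncol(w)) {
  g <- list(d = d, origin = origin, N1 = N1, N2 = N2,
            maxima = origin + d * c(N1, N2), rotation = NULL,
            w = w, wbar = w / sum(w), delta = 0.1, mode = "overlap")
  class(g) <- "latent_grid"
  g
}

test_that("cell assignment uses half-open bins with a ceiling cell count", {
  g <- list(d = 0.5, origin = c(0, 0), N1 = 2L, N2 = 2L, maxima = c(1, 1))
  cells <- assign_cells(rbind(c(0, 0), c(0.9, 0.9)), g)
  expect_equal(cells[1, ], c(i = 1L, j = 1L))
  expect_equal(cells[2, ], c(i = 2L, j = 2L))
  # maximum maps into the last cell; outside points get the NA sentinel
  expect_equal(unname(assign_cells(rbind(c(1, 1)), g)[1, ]), c(2L, 2L))
  expect_true(all(is.na(assign_cells(rbind(c(2, 0.5)), g)[1, ])))
  # N = ceil(range/d): range 1, d = 0.3 -> 4 cells per axis
  set.seed(81)
  z <- matrix(runif(40), ncol = 2)
  z[1, ] <- 0; z[2, ] <- 1
  gr <- build_latent_grid(z, rep(0.5, 20), d = 0.3, delta = 0.2)
  expect_equal(c(gr$N1, gr$N2), c(4L, 4L))
  # brute-force double-loop binning oracle on random points
  set.seed(82)
  zr <- matrix(runif(2000), ncol = 2)
  g2 <- list(d = 0.23, origin = c(0, 0), N1 = 5L, N2 = 5L,
             maxima = c(0 + 0.23 * 5, 0 + 0.23 * 5))
  got <- assign_cells(zr, g2)
  for (k in sample(1000, 50)) {
    i_exp <- NA_integer_; j_exp <- NA_integer_
    for (i in 1:5) for (j in 1:5) {
      in_i <- zr[k, 1] >= (i - 1) * 0.23 & zr[k, 1] < i * 0.23
      in_j <- zr[k, 2] >= (j - 1) * 0.23 & zr[k, 2] < j * 0.23
      if (in_i && in_j) { i_exp <- i; j_exp <- j }
    }
    expect_identical(unname(got[k, ]), c(i_exp, j_exp))
  }
})

test_that("per-cell propensity averages divide by the cell member count", {
  cells <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(NA, NA))
  agg <- average_ps_per_cell(cells, c(0.2, 0.4, 0.9, 0.5), 2L, 2L)
  expect_equal(agg$pbar[1, 1], 0.3)
  expect_equal(agg$pbar[2, 2], 0.9)
  expect_true(is.na(agg$pbar[1, 2]))  # empty cell is undefined, not 0
  expect_equal(agg$counts[1, 1], 2L)
  # random configuration vs brute force
  set.seed(83)
  cl <- cbind(sample(1:4, 300, TRUE), sample(1:3, 300, TRUE))
  ps <- runif(300, 0.01, 0.99)
  agg2 <- average_ps_per_cell(cl, ps, 4L, 3L)
  for (i in 1:4) for (j in 1:3) {
    sel <- cl[, 1] == i & cl[, 2] == j
    if (any(sel)) expect_equal(agg2$pbar[i, j], mean(ps[sel]))
  }
})

test_that("overlap and one-group weights follow their branch definitions exactly", {
  pb <- matrix(c(0.7, 0.55, 0.45, 0.5, NA, 0.2), 2, 3)
  w <- overlap_weights(pb, delta = 0.1)
  expect_equal(w[1, 1], 0)                 # |0.7-0.5| > 0.1
  expect_equal(w[2, 1], 1 / 0.55)
  expect_equal(w[1, 2], 1 / (1 - 0.45))    # symmetric branch
  expect_equal(w[2, 2], 2)                 # continuity limit at 0.5
  expect_equal(w[1, 3], 0)                 # undefined cell
  expect_equal(w[2, 3], 0)                 # 0.2 outside the band
  # symmetry under pbar <-> 1 - pbar inside the band
  expect_equal(overlap_weights(matrix(0.55), 0.1),
               overlap_weights(matrix(0.45), 0.1))
  g <- group_weights(matrix(c(0.6, 0.25, 0.5, NA), 2, 2), delta = 0.05)
  expect_equal(g[1, 1], 0)   # 0.6 > 0.55
  expect_equal(g[2, 1], 4)   # 1/0.25
  expect_equal(g[1, 2], 2)   # 1/0.5
  expect_equal(g[2, 2], 0)
  expect_equal(group_weights(matrix(1e-9), 0.05)[1, 1], 100)  # cap
})

test_that("weight normalisation sums to one and keeps zeros", {
  w <- matrix(c(1, 1, 2, 0), 2, 2)
  wb <- normalize_weights(w)
  expect_equal(as.numeric(wb), c(0.25, 0.25, 0.5, 0))
  expect_equal(sum(wb), 1)
  expect_error(normalize_weights(matrix(0, 2, 2)), "increase delta")
})

test_that("rejection sampling reproduces the weighted prior cell distribution", {
  sc <- small_cohort(n = 200, seed = 84)
  asg <- setNames(rep("none", 9), sc$roles$continuous)
  fit <- synthvae(sc$data, sc$roles$continuous, sc$roles$binary,
                  transforms = asg, config = fast_cfg(epochs = 3))
  # equal weights: accepted cell frequencies ~ prior cell mass (chi-square, 1%)
  g_eq <- toy_grid(matrix(1, 6, 6), d = 1, origin = c(-3, -3))
  syn <- sample_weighted(fit, g_eq, n_target = 20000, seed = 85)
  z <- attr(syn, "z")
  cells <- assign_cells(z, g_eq)
  idx <- factor(paste(cells[, 1], cells[, 2]),
                levels = as.vector(outer(1:6, 1:6, paste)))
  obs <- table(idx)
  br <- pnorm(seq(-3, 3, by = 1))
  mass1 <- diff(br) / (br[7] - br[1])
  expected <- as.vector(outer(mass1, mass1)) * sum(obs)
  keep <- expected >= 5
  chi <- sum((as.numeric(obs)[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)

  # zero-weight cell receives no accepted draws
  w0 <- matrix(1, 6, 6); w0[3, 3] <- 0
  syn0 <- sample_weighted(fit, toy_grid(w0), n_target = 3000, seed = 86)
  c0 <- assign_cells(attr(syn0, "z"), g_eq)
  expect_false(any(c0[, 1] == 3 & c0[, 2] == 3, na.rm = TRUE))

  # two-cell toy grid with weights 2:1 over equal prior mass
  g2 <- toy_grid(matrix(c(2 / 3, 1 / 3), 1, 2), d = 3, origin = c(-1.5, -3))
  g2$maxima <- c(1.5, 3)
  syn2 <- sample_weighted(fit, g2, n_target = 8000, seed = 87)
  z2 <- attr(syn2, "z")
  frac_hi <- mean(z2[, 2] < 0)  # j = 1 cell carries weight 2/3
  se <- sqrt(2 / 3 * 1 / 3 / 8000)
  expect_lt(abs(frac_hi - 2 / 3), 3 * se)
})

test_that("grid construction, overlap sampling and the heat map work end to end", {
  tr <- simulate_two_region(n = 900, seed = 88)
  roles <- attr(tr, "roles")
  pm <- fit_propensity(tr, "region", c(roles$continuous, roles$binary))
  fit <- synthvae(tr, roles$continuous, roles$binary,
                  transforms = c(sbp = "none", age = "none", rdelay = "bimodal"),
                  config = fast_cfg(epochs = 30, fusion = "late"))
  grid <- build_latent_grid(predict(fit), predict(pm), delta = 0.1)
  expect_equal(sum(grid$wbar), 1)
  expect_true(all(grid$w >= 0))
  expect_output(print(grid), "admissible")
  syn <- sample_weighted(fit, grid, n_target = 500, seed = 89)
  # overlap sampling pulls the shifted column between the two group means
  m0 <- mean(tr$age[tr$region == 0]); m1 <- mean(tr$age[tr$region == 1])
  expect_gt(mean(syn$age), min(m0, m1))
  expect_lt(mean(syn$age), max(m0, m1))
  f <- tempfile(fileext = ".png")
  latent_heatmap(fit, grid, tr$region, "pbar", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  f2 <- tempfile(fileext = ".png")
  latent_heatmap(fit, grid, tr$region, "weight", file = f2)
  expect_true(file.exists(f2))
  unlink(c(f, f2))
})
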