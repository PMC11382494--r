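test_that("quantile-normal transform normalises, inverts, and clips", {
  set.seed(23)
  x <- rlnorm(10000)
  qp <- fit_quantile_normal(x)
  y <- apply_quantile_normal(x, qp)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew(y)), 0.1)           # rank transform of any continuous sample
  expect_true(all(is.finite(y)))
  # interior round trip
  interior <- x > quantile(x, 0.01) & x < quantile(x, 0.99)
  back <- invert_quantile_normal(apply_quantile_normal(x, qp), qp)
  expect_lt(max(abs(back[interior] - x[interior])), 1e-6)
  # clipping contract above the training maximum
  above <- max(x) + 5
  expect_equal(invert_quantile_normal(apply_quantile_normal(above, qp), qp),
               max(x))
  expect_equal(attr(apply_quantile_normal(above, qp), "n_clipped"), 1L)
  # monotone nondecreasing inverse
  g <- seq(-4, 4, length.out = 200)
  expect_true(all(diff(invert_quantile_normal(g, qp)) >= 0))
})

test_that("an all-none assignment reduces the pipeline to min-max scaling", {
  sc <- small_cohort(n = 200, seed = 31)
  cont <- sc$roles$continuous
  asg <- setNames(rep("none", length(cont)), cont)
  pl <- fit_pipeline(sc$data, cont, sc$roles$binary, asg)
  fwd <- pipeline_forward(pl, sc$data)
  for (nm in cont) {
    x <- sc$data[[nm]]
    expect_equal(fwd[[nm]], (x - min(x)) / (max(x) - min(x)))
  }
})

test_that("pipeline round trip is tight and binary columns pass through", {
  sc <- small_cohort(n = 300, seed = 32)
  cont <- sc$roles$continuous
  asg <- setNames(rep("none", length(cont)), cont)
  asg["x_bimod"] <- "bimodal"
  asg[c("x_sev_skew", "x_mod_skew1")] <- "boxcox"
  asg["x_mod_skew2"] <- "quantile"
  pl <- fit_pipeline(sc$data, cont, sc$roles$binary, asg)
  fwd <- pipeline_forward(pl, sc$data)
  expect_true(all(vapply(fwd[cont], function(v) min(v) >= 0 && max(v) <= 1,
                         logical(1))))
  back <- pipeline_inverse(pl, fwd)
  for (nm in setdiff(cont, "x_mod_skew2"))
    expect_lt(max(abs(back[[nm]] - sc$data[[nm]])), 1e-6)
  # quantile column: interior points only (clipping at the extremes)
  xq <- sc$data$x_mod_skew2
  interior <- xq > quantile(xq, 0.02) & xq < quantile(xq, 0.98)
  expect_lt(max(abs(back$x_mod_skew2[interior] - xq[interior])), 1e-6)
  for (nm in sc$roles$binary) {
    expect_identical(fwd[[nm]], sc$data[[nm]])
    expect_identical(back[[nm]], sc$data[[nm]])
  }
})

test_that("pipeline configuration errors are caught", {
  sc <- small_cohort(n = 100, seed = 33)
  expect_error(fit_pipeline(sc$data, c("nope")), "unknown column")
  expect_error(fit_pipeline(sc$data, sc$roles$continuous, character(0),
                            c(x_bimod = "boxcox")),
               "no transform assigned")
  asg <- setNames(rep("magic", 9), sc$roles$continuous)
  expect_error(fit_pipeline(sc$data, sc$roles$continuous, character(0), asg),
               "must be one of")
  df <- data.frame(a = rnorm(50), b = rep(2, 50))
  expect_error(fit_pipeline(df, "a", "b"), "outside \\{0,1\\}")
})

test_that("transform auto-suggestion reacts to the marginal shape", {
  set.seed(34)
  df <- data.frame(bi = c(rnorm(600), rnorm(600, 5)),
                   sk = rlnorm(1200),
                   no = rnorm(1200))
  sug <- suggest_transforms(df, c("bi", "sk", "no"))
  expect_equal(unname(sug), c("bimodal", "boxcox", "none"))
})
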