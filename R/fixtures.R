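# Seeded desk-scale cohort generators with the statistical structure the
# method assumes: skewed continuous margins, an exposure-linked bimodal
# variable, binary covariates and a logistic outcome. These emulate the shape
# features of the published breast-cancer-based simulation design and an
# IST-like two-region stroke table; they do not reproduce either source's
# exact dependence structure.

#' Simulate a cohort with skewed and exposure-linked bimodal margins
#'
#' Default preset: 2,500 rows and 21 variables of which 12 are binary
#' (a binary exposure `E`, a binary outcome `y`, and 10 binary covariates)
#' and 9 continuous. The bimodal column is built conditionally on exposure:
#' \eqn{N(0,1)} for \eqn{E=0} and \eqn{N(4,1)} for \eqn{E=1}, so the mixture
#' is asymmetric through the imbalanced exposure prevalence. Skewed columns
#' are lognormal with moderate to severe skewness (sample skewness above 1).
#' The outcome follows a logistic model on the exposure and a subset of
#' covariates.
#'
#' @param n Number of rows.
#' @param exposure_prev Exposure prevalence in \eqn{(0,1)}.
#' @param bimodal_means Conditional means of the bimodal column for
#'   \eqn{E=0} and \eqn{E=1}.
#' @param seed RNG seed; the same seed yields an identical table.
#' @return Data frame with attribute `"roles"`: a list with elements
#'   `continuous`, `binary` (covariates only), `exposure`, `outcome`.
#' @export
simulate_cohort <- function(n = 2500L, exposure_prev = 0.25,
                            bimodal_means = c(0, 4), seed = 1L) {
  stopifnot(n >= 1L, exposure_prev > 0, exposure_prev < 1)
  set.seed(seed)
  E <- stats::rbinom(n, 1L, exposure_prev)
  # continuous block: 1 exposure-linked bimodal + skewed/normal margins
  cont <- data.frame(
    x_bimod = stats::rnorm(n, bimodal_means[E + 1L], 1),
    x_sev_skew = stats::rlnorm(n, 0, 1),            # severe skew (~6)
    x_mod_skew1 = stats::rlnorm(n, 1, 0.6),         # moderate skew
    x_mod_skew2 = 5 + stats::rlnorm(n, 0, 0.7),
    x_mod_skew3 = stats::rlnorm(n, 2, 0.5) - 3,     # shifted, can be negative
    x_skew_exp = stats::rlnorm(n, 0.3 * E, 0.8),    # exposure-shifted skew
    x_norm1 = stats::rnorm(n, 50, 10),
    x_norm2 = stats::rnorm(n, 0, 2),
    x_norm_exp = stats::rnorm(n, 1.5 * E, 1.5)      # exposure-shifted normal
  )
  base_rates <- c(0.5, 0.3, 0.2, 0.6, 0.45, 0.15, 0.35, 0.7, 0.25, 0.55)
  exp_shift <- c(0.8, 0, -0.6, 0.5, 0, 0, 0.9, -0.4, 0, 0)  # log-odds
  bin <- sapply(seq_along(base_rates), function(k) {
    p <- stats::plogis(stats::qlogis(base_rates[k]) + exp_shift[k] * E)
    stats::rbinom(n, 1L, p)
  })
  colnames(bin) <- paste0("b", seq_along(base_rates))
  lp <- -1 + 0.8 * E + 0.15 * scale(cont$x_bimod)[, 1L] +
    0.5 * bin[, 1L] - 0.4 * bin[, 3L] + 0.2 * scale(cont$x_norm1)[, 1L]
  y <- stats::rbinom(n, 1L, stats::plogis(lp))
  out <- cbind(cont, as.data.frame(bin), E = E, y = y)
  attr(out, "roles") <- list(continuous = names(cont),
                             binary = colnames(bin),
                             exposure = "E", outcome = "y")
  out
}

#' Simulate a two-region cohort for propensity-score tests
#'
#' Emulates the structure of a two-site stroke-trial table: a continuous
#' column identically distributed across regions (systolic blood pressure),
#' one mean-shifted by region (age, higher in region 1), one bimodal delay
#' column, binary covariates with region-dependent and region-independent
#' rates, and a logistic outcome. Default size 2,668 rows, matching the
#' record count the propensity application targets.
#'
#' @param n Number of rows.
#' @param prevalence Probability of region 1.
#' @param age_shift Mean age difference between regions (years).
#' @param seed RNG seed.
#' @return Data frame with attribute `"roles"` as in [simulate_cohort()]
#'   (with `group` instead of `exposure`).
#' @export
simulate_two_region <- function(n = 2668L, prevalence = 0.5, age_shift = 8,
                                seed = 1L) {
  stopifnot(n >= 1L, prevalence > 0, prevalence < 1)
  set.seed(seed)
  region <- stats::rbinom(n, 1L, prevalence)
  comp <- stats::rbinom(n, 1L, 0.45)
  cont <- data.frame(
    sbp = stats::rnorm(n, 160, 25),                       # shared across regions
    age = stats::rnorm(n, 64 + age_shift * region, 11),   # region-shifted
    rdelay = stats::rnorm(n, ifelse(comp == 1, 30, 9), c(3.5, 5)[comp + 1L])
  )
  base_rates <- c(sex = 0.54, rsleep = 0.3, ratrial = 0.17, rct = 0.67,
                  rvisinf = 0.35, rhep24 = 0.22, rasp3 = 0.3,
                  rxasp = 0.5, rxhep = 0.5, rconsc1 = 0.22, rconsc2 = 0.03)
  region_shift <- c(sex = 0.4, rsleep = 0, ratrial = 0.6, rct = -0.5,
                    rvisinf = 0.3, rhep24 = 0, rasp3 = -0.4,
                    rxasp = 0, rxhep = 0, rconsc1 = 0.3, rconsc2 = 0)
  bin <- sapply(names(base_rates), function(k) {
    p <- stats::plogis(stats::qlogis(base_rates[k]) + region_shift[k] * region)
    stats::rbinom(n, 1L, p)
  })
  lp <- -2 + 0.04 * (cont$age - 65) + 0.8 * bin[, "rconsc2"] +
    0.5 * bin[, "rconsc1"] + 0.3 * bin[, "ratrial"]
  fdead <- stats::rbinom(n, 1L, stats::plogis(lp))
  out <- cbind(cont, as.data.frame(bin), region = region, fdead = fdead)
  attr(out, "roles") <- list(continuous = names(cont),
                             binary = colnames(bin),
                             group = "region", outcome = "fdead")
  out
}
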