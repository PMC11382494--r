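# cohortsynth

Synthetic clinical-cohort data that preserves — or deliberately controls —
heterogeneity across individuals.

Clinical tables mix continuous and binary variables, and their heterogeneity
comes in two flavours. *Unknown* sub-group structure shows up only in the
margins, as skewness or bimodality of continuous variables; a plain
variational autoencoder (VAE) with a Gaussian latent prior smooths these
features away. *Known* sub-groups carry labels (region, site, exposure arm),
and an analyst may want synthetic data restricted to individuals common to
both groups, or typical of one. `cohortsynth` is for biostatisticians and
data custodians who need synthetic tabular cohorts with both kinds of
structure handled explicitly.

## Method

The generator is a mixed-type VAE wrapped in invertible pre-transformations:

1. **Pre-transformations** map each continuous margin toward unimodal
   near-normality before training, and are inverted after generation:
   - *Box-Cox* for skewness, $f(x) = ((x+\lambda_2)^{\lambda_1}-1)/\lambda_1$
     (log branch at $\lambda_1 = 0$), with $\lambda_1$ fitted by maximum
     likelihood and $\lambda_2$ a deterministic positivity shift;
   - a *signed-power transform* for bimodality,
     $f(x) = \mathrm{sgn}(u)\,|u|^{\rho}$ with $u = (x+\alpha)/\beta^2$,
     fitted by minimising the 1-sigma criterion
     $|Q_{0.84}-Q_{0.5}-\sigma| + |Q_{0.5}-Q_{0.16}-\sigma|$ from a
     KDE-valley initialisation of the shift;
   - an *empirical-quantile normal* baseline with training-range clipping;
   - then min-max scaling to $[0,1]$.
2. **Mixed-type VAE**: a diagonal-Gaussian encoder posterior and a decoder
   with Gaussian heads $(\mu_D, \sigma_D)$ for continuous and Bernoulli
   heads $\pi_D$ for binary columns; the loss is the negative ELBO (exact
   Gaussian + Bernoulli negative log-likelihood plus the closed-form KL to
   the $N(0,I)$ prior). Early or late fusion of the two blocks. Synthetic
   rows come from decoding prior samples, so original rows touch the output
   only through trained parameters.
3. **Propensity-guided sampling** for known sub-groups: logistic-regression
   propensity scores $p(g=1\mid x)$ (with p-value variable selection) are
   averaged per cell of a grid over the latent space, converted to
   IPTW-style weights — overlap weights $1/\bar p$, $1/(1-\bar p)$ inside a
   band $|\bar p - 0.5| \le \delta$, or one-group weights — and used for
   rejection sampling from the prior.
4. **Utility metrics**: the CART-based pMSE statistic
   $\psi = \frac1N \sum_i (\hat y_i - c)^2$, its permutation null
   $\bar\psi$, the ratio $\psi_{ratio} = \psi/\bar\psi$ (near 1 means the
   classifier cannot tell synthetic from original rows), and a k-fold
   cross-validated harness.

The encoder/decoder networks, backprop and Adam are implemented in base R
matrix code and verified against finite differences in the tests. Seeded
fixture generators (`simulate_cohort()`, `simulate_two_region()`) provide
desk-scale cohorts with skewed, exposure-linked-bimodal and two-region
structure, so everything is testable without any download.

## Worked example

```r
library(cohortsynth)

cohort <- simulate_cohort(n = 1000, seed = 1)   # 21 columns, 12 binary
roles  <- attr(cohort, "roles")

asg <- setNames(rep("none", 9), roles$continuous)
asg["x_bimod"] <- "bimodal"
asg[c("x_sev_skew", "x_mod_skew1", "x_mod_skew2",
      "x_mod_skew3", "x_skew_exp")] <- "boxcox"

fit <- synthvae(cohort, roles$continuous, roles$binary,
                transforms = asg, config = vae_config(epochs = 150, seed = 2))
print(fit)
#> Synthetic-cohort VAE generator
#>   n = 1000 rows; 9 continuous, 10 binary columns
#>   transforms: x_bimod=bimodal, x_sev_skew=boxcox, x_mod_skew1=boxcox, ...
#>   latent dim 2 | fusion early | 150 epochs
#>   final loss 2.4586 (recon 2.0754 + KL 0.38317 )

syn <- simulate(fit, nsim = 1000, seed = 3)

kde_valley_init(cohort$x_bimod)$modes   # -0.233  4.105
kde_valley_init(syn$x_bimod)$modes      #  0.023  4.292  (bimodality preserved)

u  <- utility_config(n_permutations = 100, seed = 4)
p  <- pmse(cohort[, c(roles$continuous, roles$binary)], syn, u)
nl <- permutation_null(cohort[, c(roles$continuous, roles$binary)], syn, u)
psi_ratio(p, nl)
#> psi = 0.0534  psi_bar = 0.0473  psi_ratio = 1.128
```

The synthetic table keeps both modes of the exposure-linked bimodal column
(an identically configured fit with `transforms` all `"none"` collapses it
to one mode), and the pMSE ratio near 1 says a CART classifier can barely
distinguish synthetic from original rows.

For known sub-groups:

```r
tr  <- simulate_two_region(seed = 1)
pm  <- fit_propensity(tr, "region", c(attr(tr,"roles")$continuous,
                                      attr(tr,"roles")$binary))
fit <- synthvae(tr, attr(tr,"roles")$continuous, attr(tr,"roles")$binary,
                transforms = c(sbp="none", age="none", rdelay="bimodal"),
                config = vae_config(fusion = "late"))
grid <- build_latent_grid(predict(fit), predict(pm), delta = 0.1,
                          mode = "overlap")
syn  <- sample_weighted(fit, grid, n_target = 1000, seed = 2)
latent_heatmap(fit, grid, tr$region, "pbar", file = "latent.png")
```

Overlap sampling restricts generation to latent regions shared by both
regions: the synthetic mean of the region-shifted column (age) lands between
the two group means.

A command-line wrapper over these functions ships in
`inst/cli/cohortsynth.R` (commands `simulate-fixture`, `fit-transforms`,
`train`, `generate`, `propensity-sample`, `evaluate`, `visualize-latent`).

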