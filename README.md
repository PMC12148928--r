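# spfocc — spatial factor multispecies occupancy models

`spfocc` is an R package for estimating how whole species assemblages respond
to site-scale and landscape-scale drivers when the data are detection /
non-detection records from repeated site visits — the situation of woodland
biodiversity surveys across patch networks, where a species may be present
but missed on any given visit, and where residual correlation among species
and across space would otherwise masquerade as environmental signal.

The core is a hierarchical Bayesian joint-species occupancy model. For
species *i*, site *j*, visit *k*:

```
Y_ijk ~ Bernoulli(P_ijk * z_ij)                         (detection layer)
logit(P_ijk) = a0_i + a1_i day + a2_i day^2 + a3_i year + a4_i var4
z_ij ~ Bernoulli(Psi_ij)                                 (occupancy layer)
logit(Psi_ij) = x_j' b_i + w_i(s_j)
w_i(s_j) = sum_f lambda_if u_f(s_j)                      (spatial factors)
```

where `x_j` holds standardised site and landscape predictors with
interactions, each latent factor `u_f` is a zero-mean Gaussian process over
the site coordinates with exponential correlation `exp(-phi d)`, and the
species loadings `lambda_if` induce correlated residuals among species.
Species coefficients are drawn from community-level normal distributions
(means Normal(0, 2.7²), variances inverse-gamma(0.1, 0.1)), so rare species
borrow strength from the assemblage. A `perfect_detection` variant drops the
detection layer for single exhaustive surveys. Fitting is by Gibbs sampling
with Pólya-Gamma augmentation (exact full conditionals for both logit
layers; the PG(1, c) sampler is implemented in C++ on R's RNG, so fits are
reproducible from one seed).

Around the model sit the rest of the analysis pipeline: a synthetic-data
generator with known truth for recovery experiments, predictor preparation
(patch shape index, centring/scaling with a stored transform, VIF screen,
empirical marginal samplers), convergence diagnostics (rank-normalised split
R-hat, ESS) and posterior predictive checks, counterfactual assemblage
simulation under fixed driver scenarios with species-richness summaries and
probability of direction, and composition analysis (binary Bray–Curtis,
3-axis NMDS, 89% ellipses).

## Worked example

Simulate a 15-species community over 60 sites and 3 visits under a reduced
model, fit it, and explore a woodland-cover scenario:

```r
library(spfocc)

model <- occu_model(
  occupancy = ~ age + area + current_woodland + arable + area:arable,
  detection = ~ day + year, n_factors = 0)
config <- sim_config(n_species = 15, n_sites = 60, n_visits = 3,
                     model = model, n_factors = 0, seed = 1)
dat <- sim_occu_data(config)

fit <- spfocc(dat, mcmc = mcmc_control(n_chains = 4, n_burn = 2000,
                                       n_keep = 500, thin = 2), seed = 2)
fit
#> Spatial factor multispecies occupancy model
#>   species: 15   sites: 60   occupancy terms: 6
#>   detection terms: 3
#>   latent spatial factors: 0
#>   posterior draws: 2000 (4 chains)
#>   max split R-hat: 1.015
```

The summary reports community-level effects — the assemblage-average
response to each predictor on the logit scale — with 95% credible intervals
(here the data are simulated with community means 0, and the intervals cover
0 accordingly):

```r
summary(fit)
#> Community-level occupancy effects (posterior mean, 95% CrI):
#>          parameter    mean    sd  lower  upper
#> 1      (Intercept) -0.0744 0.423 -0.896 0.7619
#> 2              age  0.0210 0.266 -0.500 0.5469
#> 3             area  0.0193 0.274 -0.504 0.5807
#> 4 current_woodland -0.2830 0.167 -0.618 0.0511
#> 5           arable  0.1998 0.250 -0.292 0.6985
#> 6      area:arable  0.0648 0.302 -0.543 0.6731
#> ...
#> 2000 draws, 4 chains; max split R-hat 1.015; min ESS 321
```

Counterfactual assemblages: fix woodland cover low vs high in a 3.5-ha
patch, draw every other predictor from its empirical marginal, one posterior
draw per assemblage, and summarise richness (mode, Monte-Carlo mean, and the
analytic expectation it must match):

```r
grid <- scenario_grid(list(current_woodland = c(0.05, 0.3)), area = 3.5,
                      n_draws = 2000, data = dat$site_covs)
for (g in grid) {
  ens <- simulate_assemblages(fit, g, seed = 3)
  r <- species_richness(ens)
  cat(sprintf("%-25s mode %2d  mean %.2f  expected %.2f\n",
              g$label, r$mode, r$mean, expected_richness(ens)))
}
#> current_woodland=low      mode  8  mean 7.83  expected 7.82
#> current_woodland=high     mode  7  mean 6.70  expected 6.62
#> background                mode  7  mean 7.12  expected 7.17
```

(This simulated community happens to respond negatively to woodland cover —
the community mean above is −0.28.) Composition of a representative 10%
subsample:

```r
sub <- subsample_assemblages(simulate_assemblages(fit, grid[[2]], seed = 4),
                             0.10, seed = 5)
ord <- nmds_ord(bray_binary(sub), k = 3, n_restarts = 5, seed = 6)
ord
#> NMDS (3 axes): stress = 0.1936 over 200 points (6 starts)
```

`ellipse89(ord$coordinates)` then gives the normal-theory 89% ellipse of a
group on the first two axes, and `response_curve(fit, "area")` /
`prob_direction()` give per-species marginal response curves shaded by the
probability of direction.

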