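---
title: "Spatial factor multispecies occupancy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial factor multispecies occupancy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spfocc` fits a hierarchical Bayesian joint-species occupancy model for
communities surveyed by repeated visits with imperfect detection, of the kind
used to analyse woodland biodiversity surveys across networks of discrete
habitat patches embedded in agricultural landscapes.

For species $i$, site $j$ and visit $k$, the detection record is

$$Y_{ijk} \sim \mathrm{Bernoulli}(P_{ijk}\, z_{ij}),$$

where $z_{ij} \in \{0, 1\}$ is the latent occupancy state, constant across
visits. Detection probability is modelled on the logit scale from visit-level
covariates — ordinal day as linear and quadratic terms (the quadratic is the
square of the *scaled* day), survey year, and one taxon-specific covariate
such as trap count:

$$\mathrm{logit}(P_{ijk}) = a0_i + a1_i\,\mathrm{day}_{jk} +
  a2_i\,\mathrm{day}_{jk}^2 + a3_i\,\mathrm{year}_{jk} +
  a4_i\,\mathrm{var4}_{jk}.$$

Occupancy combines four site-scale predictors (age, area, shape index,
vegetation structural heterogeneity), six landscape-scale predictors within a
3-km radius (proportions of current, old and lost woodland, trees outside
woodlands, the arable fraction of farmland, livestock density), six
interactions formed from the scaled main effects, a country indicator, and a
species-specific spatial random effect:

$$\mathrm{logit}(\Psi_{ij}) = x_j^\top b_i + w_i(s_j), \qquad
  z_{ij} \sim \mathrm{Bernoulli}(\Psi_{ij}).$$

The residual term is a low-rank spatial factor expansion
$w_i(s_j) = \sum_f \lambda_{if}\, u_f(s_j)$: each latent factor $u_f$ is a
zero-mean Gaussian process over the site coordinates with exponential
correlation $\exp(-\phi d)$ and unit marginal variance, and the
species-specific loadings $\lambda_{if}$ carry both the amplitude and the
among-species residual correlation. For data from a single exhaustive survey
(vascular plants), `perfect_detection = TRUE` drops the detection layer and
fits $Y_{ij} \sim \mathrm{Bernoulli}(\Psi_{ij})$ directly — a joint species
distribution model with the same right-hand side.

All species-level coefficients are drawn from community-level normal
distributions (`mean` and `variance` per predictor), which is what lets
rarely-detected species borrow strength from the assemblage.

## Priors

Community means have Normal(0, 2.7\^2) priors — 2.7 on the logit scale gives
a near-uniform implied distribution on the probability scale — and community
variances have inverse-gamma(0.1, 0.1) priors. These are the minimally
informative defaults familiar from multispecies occupancy software. The
documented prior on the species intercepts applies to every species-level
coefficient's community distribution here, as the package default; it is
overridable through `prior_spec()`. Free factor loadings are standard normal;
the leading $F \times F$ loading block is constrained lower-triangular with
unit diagonal, the standard factor-model identifiability constraint (the
choice of constraint is ours; rotation of the factors is otherwise
unidentified).

One consequence worth knowing: because the community variance prior is
inverse-gamma with shape 0.1, the *marginal* prior of a species-level
coefficient is extremely heavy-tailed (infinite variance). Prior-predictive
summaries based on sample means of draws are therefore unstable by
construction; the test suite checks prior recovery through the light-tailed
community mean instead.

# Inference

The sampler is a Gibbs scheme with Pólya-Gamma data augmentation on both
logit layers, giving exact full conditionals throughout:

1. latent states $z_{ij}$ from their Bernoulli full conditional (sites with a
   detection are occupied; sites without one weigh $\Psi \prod_k (1-P_k)$
   against $1-\Psi$, masked visits contributing nothing);
2. occupancy auxiliaries $\omega_{ij} \sim \mathrm{PG}(1, \eta_{ij})$ and
   species coefficient blocks from conjugate Gaussians;
3. free factor loadings from conjugate Gaussians, then each factor's score
   vector over all sites from a Gaussian whose precision is the dense inverse
   GP correlation matrix plus the diagonal Pólya-Gamma weights;
4. detection auxiliaries and coefficients for the occupied, observed
   site-visits only (species never detected anywhere draw their detection
   coefficients from the community distribution);
5. community means and variances from Normal / inverse-gamma conjugate
   updates.

The PG(1, c) sampler is implemented in C++ (Devroye's alternating-series
rejection method) on top of R's own RNG, so a single `set.seed()` governs the
whole fit; chains receive seeds derived from the master seed, and results are
bit-identical across runs at fixed seed and chain count.

The GP decay $\phi$ is fixed by default (the dense correlation inverse is
then computed once); `mcmc_control(update_decay = TRUE)` enables a
random-walk Metropolis update under a uniform prior when the decay is to be
learned. A dense solve is entirely adequate at the site counts this design
targets (under ~150 sites); nearest-neighbour approximations are deliberately
out of scope.

## Chain protocol and diagnostics

Two protocols are expressible through `mcmc_control()`: the survey-scale
protocol (4 chains, 50,000 burn-in, 20,000 total posterior samples at
thinning 10) and the default test-scale protocol (4 chains, 2,000 burn-in,
500 kept per chain at thinning 2) used throughout the test suite so the whole
pipeline runs in minutes on one core. Convergence is screened with
rank-normalised split R-hat (the Vehtari–Gelman–Simpson–Carpenter–Bürkner
variant: bulk and folded, the larger reported), with the conventional 1.1
threshold raising a structured warning from `spfocc()` itself;
autocorrelation-based effective sample sizes use Geyer's initial monotone
sequence. Goodness of fit uses posterior predictive checks on site-level
detection counts with a Freeman–Tukey discrepancy by default
(`posterior_check()`); data simulated from the model itself yield p-values
well inside (0, 1), and count patterns no constant-detection binomial can
produce push p to the extremes.

# The synthetic-data generator

`sim_occu_data()` generates full datasets with known truth, emulating the
study conditions the model is meant for: communities of tens of species
(up to ~170), 60–134 sites split between two regions (rectangular blocks in
km coordinates standing in for two countries), 2–4 visits, and covariates on
the published ranges — patch area log-uniform on 0.5–31.9 ha, shape index
$\ge 1$, proportion-type landscape covariates as scaled Beta draws. A
Gaussian copula links old woodland to current woodland (and trees-outside to
current woodland, livestock negatively to arable) so the collinearity screen
has realistic structure to detect; old woodland is generated as the fraction
of the current woodland that is old, which keeps its landscape area within
the current woodland area by construction.

Defaults chosen where the study conditions do not pin a value, fixed once:

* community means 0 with intercept means −0.3 (occupancy; communities with
  somewhat less than half the sites occupied on average) and +0.5 (detection;
  per-visit detectability around 0.6 at average conditions), community sds 1
  for intercepts and 0.5 / 0.3 for occupancy / detection slopes — moderate,
  realistic interspecific spread;
* three latent spatial factors (the source analyses do not report their
  number; three is a deliberate package default, not an inherited value)
  with loading sd 0.5 and GP decay 0.05 per km, an effective range of about
  60 km — correlation within, not across, regions;
* ordinal day uniform on days 120–200 (a survey season), year a site-level
  0/1, trap count an integer 3–15 per site;
* 5% of site-visits masked as missing, encoded `NA` for every species at the
  affected site-visit — never as zeros, which would masquerade as
  non-detections.

What the generator does *not* emulate: spatially autocorrelated covariate
fields (covariates are exchangeable across sites), species traits or
phylogenetic signal, temporal dynamics across seasons, and observation
processes beyond Bernoulli detection (double counting, misidentification).
Passing recovery tests on these data therefore demonstrate correctness of
the inference machinery under the model's own assumptions, not robustness to
the ways real surveys violate them.

# Counterfactual scenarios and composition

`scenario_grid()` crosses low/high levels of 2–3 focal drivers (e.g.
woodland cover 0.01 vs 0.3, old woodland 0.01 vs 0.85, lost woodland 0.01 vs
0.15, arable fraction 0.01 vs 0.9) into $2^k$ scenarios plus a background
scenario, with site area conventionally fixed at the 3.5-ha mean patch size.
`simulate_assemblages()` consumes one posterior draw per assemblage, in
posterior order — uncertainty enters once, through the posterior itself —
fixes the focal predictors (standardised through the transform stored at fit
time), draws every remaining predictor fresh from its empirical marginal in
the original data (country is treated like any other non-focal predictor),
recomputes interaction columns from those mains, and converts the resulting
$\Psi$ to presence/absence by Bernoulli trial. The spatial term is set to
zero by default — the scenario describes a hypothetical patch at no
particular location — with `w = "gp_prior"` available to propagate spatial
uncertainty instead. Requesting more assemblages than there are posterior
draws is an error unless `recycle = TRUE` consciously reuses draws
cyclically.

Richness summaries report the per-draw row sums, their mode (ties broken
towards the smallest value, deterministically) and the analytic expectation
$\bar{\sum_i \Psi_{di}}$, which the Monte-Carlo mean must match within
sampling error — a standing internal consistency check on the Bernoulli
machinery. Composition uses binary Bray–Curtis (Sørensen) dissimilarity on a
representative random 10% subsample, all-empty assemblages removed first
(the index is undefined for a doubly-empty pair; removals are counted), then
3-axis NMDS minimising Kruskal stress-1 via `vegan::monoMDS`, started from
the classical metric-MDS configuration plus 20 random restarts at
convergence tolerance 1e-6, lowest stress kept. Group ellipses are
normal-theory 89% ellipses (chi-square(2) quantile of the group covariance)
on the first two axes.

# Numerical choices and degenerate inputs

* GP correlation matrices carry a 1e-6 diagonal jitter before inversion
  (1e-8 in the generator); the generator samples GP draws through a
  symmetric eigendecomposition so exactly coincident sites degrade
  gracefully (identical scores) rather than failing a Cholesky.
* `center_scale()` uses the sample (n−1) standard deviation, refuses
  zero-variance columns by name, and skips 0/1 indicator columns; the
  returned transform is stored on the fit so predictions and scenarios
  always use training statistics. Interaction columns are always products of
  *scaled* mains (the alternative — scaling the products — is not used; the
  choice matters and is deliberate).
* The VIF screen requires a full-rank design and names the dependent
  column(s) on failure.
* A constant MCMC series returns split R-hat exactly 1 (variance-zero guard)
  and an `NA` sentinel from `effective_size()`.
* The richness mode of an empty ensemble is 0; degenerate (all-equal)
  dissimilarity matrices are flagged as non-informative; collinear point
  sets yield a flagged degenerate ellipse.

# Problem sizes used by the tests

The suite runs simulate-then-fit experiments at 15 species × 60 sites × 3
visits under a reduced model (intercept + 4 occupancy predictors + 1
interaction, 2 detection covariates, no spatial term) with the test-scale
chain protocol; the single-species oracle comparison uses 2,000 sites with
perfect detection; posterior-predictive calibration repeats a 8 species × 40
sites experiment twenty times on one chain. These sizes are the package's
choice of desk-scale experiment: large enough for the asymptotic oracles to
bind, small enough to iterate on.

# Known limitations

Single-season occupancy only; logit link only; dense GP algebra (site counts
in the hundreds, not thousands); the spatial decay is fixed unless the
Metropolis update is switched on; scenario simulation ignores the spatial
term by default; NMDS on large ensembles should go through the subsampling
path (`subsample_assemblages()`), as an all-pairs dissimilarity on 20,000
assemblages is deliberately not attempted.
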