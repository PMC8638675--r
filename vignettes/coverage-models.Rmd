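---
title: "Spatial models for district-level vaccination coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial models for district-level vaccination coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

National household surveys such as the DHS record, for each sampled
cluster, how many children aged 12–23 months were surveyed and how many
were vaccinated, together with the cluster's coordinates, its district,
its urban/rural stratum and a sampling weight. Policy targets (e.g. 80%
or 95% coverage) are set at the district level, where direct survey
estimates can be noisy. `vaxsae` implements the two families of Bayesian
spatial smoothing models used for this problem — discrete (areal) models
fitted to district summaries, and continuous (geostatistical) models
fitted to cluster points — plus the design-based layer beneath them, and
a leave-one-district-out (LODO) harness that scores all models against
the direct estimates.

Because real DHS microdata are restricted, the package ships a
synthetic-country generator that reproduces the *structure* of such
surveys, so every stage is exercised end to end on data with known truth.

## Design-based layer

Within each district the raw weights are normalized so the per-child
weights sum to the number of children surveyed,
$\sum_{k \in A_i} \tilde w_{ki} = N_{A_i}$. The direct estimate is the
Horvitz–Thompson ratio
$\hat p^{DIR}_{A_i} = \sum_k \tilde w_{ki} Y_{ki} / \sum_k \tilde w_{ki}$,
with design variance from Taylor linearization treating clusters as PSUs
within urban/rural strata (with-replacement approximation, no finite
population correction). Replication-weight variance estimation is out of
scope. Two derived quantities feed the weighted discrete models:

* the empirical logit $Y_L = \mathrm{logit}(\hat p^{DIR})$ with known
  variance $\hat\sigma^2_Y = \hat\sigma^2_{pDIR}/(\hat p(1-\hat p))^2$;
* the effective sample size $N_E = \hat p(1-\hat p)/\hat\sigma^2_{pDIR}$
  and effective cases $Y_E = N_E \hat p$.

Boundary districts ($\hat p \in \{0,1\}$) have undefined logit variances
and are treated as *missing observations*: the model fitters exclude
them from the likelihood and return their posterior predictive instead.
Zero-variance districts (all cluster proportions identical) and lone-PSU
districts are flagged missing the same way rather than patched with
ad-hoc continuity corrections. Single-PSU strata are collapsed with the
other stratum in the same district, mirroring common survey-software
behaviour; normalization is applied per district after collapse (the
alternative order is not distinguishable from the problem statement, and
the estimator is invariant to uniform rescaling either way).

## Discrete models

All three areal models share the linear predictor
$x'_{A_i}\beta + \phi_{A_i}$ with a Leroux CAR prior
$\phi \sim N(0, \sigma^2_\phi Q(W)^{-1})$,
$Q(W) = \rho(\mathrm{diag}(W\mathbf 1) - W) + (1-\rho)I$, which
interpolates between iid effects ($\rho = 0$) and the intrinsic CAR
($\rho = 1$; permitted for construction, rejected for sampling since the
prior is then improper). The likelihoods:

* **D-UNWB** — unweighted binomial on raw district counts;
* **D-LN** — Gaussian on the empirical logit with *known*
  heteroscedastic design variances;
* **D-ESS** — binomial on effective counts; non-integer $Y_E, N_E$ enter
  a continuous binomial log-likelihood
  $Y_E \log p + (N_E - Y_E)\log(1-p)$ (the normalizing constant is free
  of $p$), preserving smoothness in the sampler.

Priors follow standard practice for these models:
$\beta \sim N(0, 10^6)$ per coefficient,
$\mathrm{logit}(\rho) \sim N(0, 0.45)$ (0.45 is the variance), and
$\sigma_\phi^{-2} \sim \mathrm{Gamma}(0.1, 0.1)$. Covariates are
standardized internally and coefficients back-transformed; district
coverage estimates are invariant to this.

## Continuous models

The geostatistical models are binomial at cluster level with
$\mathrm{logit}\,p(s_i) = x(s_i)'\beta + \omega(s_i) + \epsilon(s_i)$
(**C-GPIID**) or without the nugget $\epsilon$ (**C-GP**). The spatial
process $\omega$ is a zero-mean Gaussian process with Matérn covariance,
smoothness fixed at $\nu = 1$ for identifiability, parameterized by the
marginal variance $\sigma_\omega^2$ and the practical range
$r = \sqrt{8\nu}/\kappa$, the distance at which correlation falls to
roughly 0.1 (numerically $\sqrt 8 K_1(\sqrt 8) \approx 0.14$).

A joint penalized-complexity prior is placed on $(r, \sigma_\omega)$
using the standard two-dimensional construction
$\pi(r,\sigma) = \lambda_r \lambda_\sigma r^{-2}
\exp(-\lambda_r/r - \lambda_\sigma\sigma)$, calibrated by
$P(r < r_0) = 0.01$ with $r_0$ defaulting to 5% of the study region's
north–south extent, and $P(\sigma_\omega > 5) = 0.01$. The nugget sd has
the exponential PC prior with $P(\sigma_\epsilon > 5) = 0.01$.

No SPDE/mesh approximation is used: at the problem sizes this package
targets (up to a few hundred clusters, a few thousand grid cells) the
dense Matérn covariance with exact Cholesky factorization is affordable,
and exactness makes the fitters directly checkable against brute-force
quadrature oracles in the test suite.

**Prediction.** Per posterior draw, $\omega$ at grid centroids is drawn
from the exact Gaussian conditional given $\omega$ at the data
locations (district-blocked to keep the conditional covariances small),
and $p_r(s) = \mathrm{expit}(x(s)'\beta_r + \omega_r(s))$. The nugget is
*not* added to grid predictions: it models between-cluster (excess
binomial) variation, a property of sampled clusters rather than of
locations. Marginalizing over it instead would inflate grid-level
uncertainty; the choice is deliberate and documented here because either
convention appears in practice.

## Posterior computation

Inference is MCMC, designed so that every jointly-Gaussian block is
updated by elliptical slice sampling (rejection-free, tuning-free) and
the low-dimensional hyperparameter block by per-coordinate adaptive
random-walk Metropolis (Robbins–Monro adaptation toward 0.44 acceptance
during warmup only):

* the areal/spatial field is kept in a *non-centered* (whitened)
  parameterization for hyperparameter moves — the field is mapped
  deterministically through proposed $(\rho, \tau)$ or
  $(\sigma_\omega, r)$ with the whitened coordinates held fixed — which
  removes the classic variance–field funnel;
* a likelihood-preserving "ridge" move shifts the intercept and
  counter-shifts the field mean, the direction in which the posterior is
  otherwise nearly flat;
* for the Matérn models, an additional joint proposal moves
  $(\log\sigma_\omega, \log r)$ along their ridge (only the combination
  $\sigma^2_\omega/r^2$ is well identified in-fill).

Defaults are 4 chains of 1000 warmup + 1000 kept draws; split-$\hat R$
is computed for every scalar parameter and linear predictor, and a fit
whose worst $\hat R$ exceeds 1.01 carries `converged = FALSE` (the fit
is still returned). Cross-validation refits use lighter chain settings
(reported in each function's arguments) because LODO requires
$n_A \times$ models refits; the study-level conclusions are driven by
posterior means of held-out coverage, which stabilize much faster than
extreme quantiles.

Numerical choices: Cholesky factorizations retry with escalating jitter
$10^{-8}\sigma^2 \times 10^k$ up to $10^{-4}\sigma^2$; inside the MCMC
hot path the Matérn kernel $x K_1(x)$ is evaluated through a dense
natural-spline interpolant (knot spacing 0.005, absolute error below
$5\times10^{-7}$); the public covariance functions and predictions use
exact Bessel evaluations. The binomial log-likelihood is computed in the
numerically stable form $y\eta - n(\max(\eta,0) + \log(1+e^{-|\eta|}))$.

## Aggregation

District summaries of gridded quantities are population-weighted means
over cells whose centroids fall in the district,
$x(A_i) \approx \sum_j x(s_j) q(s_j)$ with within-district shares
$\sum_j q(s_j) = 1$ (audited before every aggregation call). Posterior
surfaces are aggregated per draw, preserving joint posterior structure;
exceedance probabilities $P(p(A_i) \ge t)$ are reported for the 80% and
95% programmatic thresholds by default. Centroid containment is the only
supported cell-assignment rule; border ties go to the smaller district
id. Cluster-level covariates are carried to the grid by ordinary kriging
on the logit scale with an exponential covariance, no nugget, and range
set to the first quartile of pairwise inter-cluster distances; the
covariance family is an assumption (the convention this recipe follows
does not pin it down) and is deliberately not configurable.

## Evaluation

LODO cross-validation: discrete models have the held-out district's
response set missing (covariates retained, so the CAR prior and
regression impute it); continuous models drop all clusters in the
district and predict its grid cells. Following standard practice the
reference values are the direct survey estimates, and the scores are
RBias, RMSE, MAE (on posterior means) and CRPS (on full predictive
draws, using the sorted $O(m\log m)$ form of the double-sum estimator;
the two forms agree to $10^{-12}$ and this is asserted in the tests).
Districts with boundary or degenerate direct estimates are excluded from
the metric averages and counted. A constant national-mean predictor is
scored alongside as the baseline any spatial model should beat.

## The synthetic country

The generator emulates the structure the models assume, with defaults
chosen once to resemble a mid-sized high-coverage country:

* 25 districts as Voronoi cells of random seeds (two Lloyd relaxation
  steps; adjacency = shared border of positive length) on a
  300 × 300 km rectangle, 5 km grid;
* population: a log-Gaussian field (range 25% of the short extent),
  normalized to within-district shares; urban stratum = top 20% of cells
  by population within each district;
* latent surface: $\mathrm{expit}(\beta_0 + \beta_1 x(s) + \omega(s))$
  with $\beta = (1, -0.5)$, a "remoteness" covariate (standardized
  distance to a random city), and Matérn $\nu=1$ field with
  $\sigma_\omega = 0.6$, $r = 75$ km (range/extent ratio comparable to
  published country analyses); mean coverage ~70–85%;
* survey: ~300 clusters allocated to districts proportionally to
  population (minimum two), 40% to the urban stratum (oversampled
  relative to its 20% cell share), cells drawn PPS without replacement,
  weight = 1/inclusion probability; 10–30 children per cluster; cluster
  outcomes binomial with a logit-scale nugget $\sigma_\epsilon = 0.3$;
  clusters with $\le 1$ child are redrawn, matching the exclusion rule
  applied to real surveys.

All randomness flows from one master seed through named substreams, so
stages can be re-run independently and artifacts are byte-reproducible.
What the generator does **not** emulate: cluster coordinate displacement
(DHS jitter) and displacement-aware covariate extraction, nonresponse,
multiple survey rounds, and real covariate measurement error. Passing
tests therefore demonstrate correctness of the estimators under the
models' own assumptions, not robustness to those real-data features.

The hyperparameter-recovery experiment in the test suite simulates 200
clusters from C-GPIID on a 600 × 600 km domain at
$(\sigma_\omega, r, \beta_0, \sigma_\epsilon) = (0.8, 150, 0.5, 0.3)$ —
a range-to-extent ratio of 0.25, matching the upper end of published
estimates — and checks 90% interval coverage across 5 replicates; the
test-suite problem sizes (toy quadrature oracles, 5 replicates, lighter
CV chains) are the package's choice of a scale at which exact oracles
are computable.

## Known limitations

* Dense-covariance inference scales as $O(n^3)$ in clusters and
  per-block grid cells; beyond ~1000 clusters an SPDE or low-rank method
  would be needed (deliberately out of scope).
* The adaptive Metropolis hyperparameter updates mix slowly when the
  range approaches the domain size; `converged = FALSE` flags this, and
  longer chains are the remedy.
* The prior `logit(rho) ~ N(0, 0.45)` reads 0.45 as a variance; software
  conventions differ (some parameterize by precision), so comparisons
  with other implementations should match this explicitly.
* Weights are treated as known inverse inclusion probabilities;
  nonresponse adjustment and raking are out of scope.

## Reproducing a study

```{r example}
library(vaxsae)
res <- run_study(country_config(seed = 1), out_dir = "study-artifacts",
                 models = c("dunwb", "dln", "dess", "cgpiid", "cgp"),
                 covariates = "with", cv = TRUE, seed = 1)
res$comparison
```

`scripts/acceptance.R` runs the same pipeline non-interactively and
writes the headline quantities as JSON (see the README).
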