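---
title: "Methods: spatially misaligned ecological regression of soil trace elements and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially misaligned ecological regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Topsoil element concentrations (arsenic, chromium) are measured at scattered
sampling points; cancer deaths are counted by municipality. Relating the two
is an ecological regression with *spatially misaligned data*: the exposure is
observed at point locations that do not coincide with the outcome's areal
support. `soilrisk` implements the full chain — indirect standardisation,
geostatistical exposure construction, Bayesian disease mapping, and a joint
model that propagates exposure uncertainty — together with a synthetic study
universe with known ground truth on which every stage can be validated.

## Models

**Disease model.** For area $i$ with observed deaths $O_i$ and expected
deaths $E_i$,
$$O_i \sim \mathrm{Poisson}(E_i \lambda_i), \qquad
\log \lambda_i = \alpha + \beta\,\mathrm{expos}_i + \textstyle\sum_j \delta_j
\mathrm{Soc}_{ij} + \gamma\,\mathrm{Indus}_i + u_i + v_i,$$
the Besag–York–Mollié decomposition: $u$ follows an intrinsic CAR prior on
the municipal adjacency graph (conditional SD $\sigma_u$, sum-to-zero
constraint per connected component, unscaled structure matrix $R = D - W$)
and $v_i \sim N(0, \sigma_v^2)$ is unstructured. $\mathrm{Soc}_{ij}$ are
socio-demographic confounders (continuous indicators plus a three-level
population-size class) and $\mathrm{Indus}_i$ flags an industrial emitter
within 5 km of the centroid (closed boundary: exactly 5 km counts).

**Exposure model.** Observed concentrations are lognormal around a latent
stationary Matérn Gaussian field $x(s)$ (smoothness $\nu = 1$):
$$\log c_j \sim N(\mu_x + x(s_j), \sigma_x^2),$$
with $\sigma_x$ a measurement-error SD on the log scale. The field is
parameterised by its practical range $\rho = \sqrt{8}/\kappa$ and marginal SD
$\sigma_f$. Smoothness is fixed at $\nu = 1$ — the standard choice for the
two-dimensional SPDE operator with $\alpha = 2$, which keeps the precision
assembly closed-form; all logs are natural logs.

**Approach A (plug-in).** The exposure at each centroid is predicted by
ordinary kriging of the sample log concentrations (Matheron empirical
variogram, weighted-least-squares model fit, covariance-form kriging system
with a Lagrange multiplier). The prediction is plugged into the disease
model as if known; the kriging variance is retained for diagnostics only —
this is precisely the approximation whose consequences the package is built
to examine. Exposure can enter as quartile factor (first quartile reference),
as the quartile ordinal treated as continuous (trend test, RR per quartile
step), or as continuous log concentration.

**Approach B (joint).** The field is represented on a triangulated mesh by
the finite-element SPDE construction, $Q = \tau^2(\kappa^4 C + 2\kappa^2 G +
G C^{-1} G)$ with lumped (diagonal) mass matrix $C$, and linked to sample and
centroid locations by barycentric projector matrices. The disease and
concentration likelihoods are fitted jointly, with the latent centroid value
$\mu_x + x(s_i)$ as the exposure covariate, so the relative risk per unit
log concentration reflects the exposure uncertainty. Because the exposure is
a latent Gaussian variable here, only the continuous coding applies. The
latent exposure is the field value *at* the centroid, not an areal average,
matching the construction the plug-in approach also uses.

## Inference

All posteriors are sampled by seed-deterministic Markov chain Monte Carlo
built on sparse-matrix Gaussian approximations:

* **Latent blocks** (fixed effects + $u$ + $v$; field mean + mesh weights)
  are updated jointly by independence Metropolis–Hastings. The proposal is
  the Gaussian (Laplace) approximation of the block's full conditional,
  obtained by a second-order Taylor expansion of the Poisson term at the
  conditional mode; the mode is found by Newton iteration (tolerance
  $10^{-3}$, warm-started from the previous iteration) and is unique because
  the conditionals are log-concave. The ICAR sum-to-zero constraint is
  enforced by conditioning the Gaussian by kriging, with the matching
  conditional proposal density in the acceptance ratio. Acceptance rates are
  typically 0.4–0.7; chains start from a draw of the initial approximation
  so the first state is inside the proposal's typical set. On a fixed
  alternating schedule the independence step is followed by a state-centred
  autoregressive step — a partial Newton move toward the local expansion's
  mean with matched noise, exact for Gaussian conditionals at any step size,
  with the step size adapted during burn-in — which keeps a block tracking
  its conditional when the other blocks have moved it off-mode.
* **Variance parameters** $\sigma_u, \sigma_v$ use three complementary
  moves per iteration: centred random-walk MH given $(u, v)$; an
  interweaved (ancillary) rescaling move that multiplies the random-effect
  vector and its SD together, judged by the Poisson likelihood; and a
  one-block move that proposes new SDs and regenerates the whole latent
  block from its Laplace approximation under the proposal, accepted jointly.
  The last move is what decouples the SD chains from the latent vectors.
* **Field hyperparameters** $(\rho, \sigma_f)$ use the same one-block
  strategy (random walk on the log scale with the field regenerated under
  the proposal), plus an interweaved field-scale move that exploits
  $\tau^2 \propto \sigma_f^{-2}$, so the precision and its determinant
  rescale analytically. $\sigma_x$ uses scalar MH on the log scale.
* Scalar proposal scales adapt only during burn-in (target acceptance
  0.25–0.44), so kept draws come from a fixed-kernel Markov chain;
  everything is reproducible from the seed.

Convergence is reported, not assumed: split-$\hat R$ and autocorrelation-based
effective sample sizes for every reported parameter, with the fit flagged
when any $\hat R > 1.05$. The weakly identified BYM SDs are the slowest
movers; at the short chain lengths used in examples they are occasionally
flagged while the exposure effects mix with hundreds of effective draws.
Warm-starting Newton from the previous mode makes the proposal centre depend
(to within the Newton tolerance) only on the current conditioning blocks;
the residual history dependence is bounded by that tolerance, and the
calibration checks below back the resulting chains empirically.

## Priors

Fixed effects: Normal(0, 10²). $\sigma_u, \sigma_v, \sigma_x$:
half-Normal(0, 1). Field hyperparameters: penalised-complexity-style priors,
$P(\rho < 10\,\mathrm{km}) = 0.05$ and $P(\sigma_f > 2) = 0.05$ by default.
All of these are exposed in `prior_config()`; they are weakly-informative
reconstructions chosen on the scale of log-concentration data, not a
reproduction of any published analysis.

## The synthetic study universe

`sim_config()` / `simulate_universe()` generate the study conditions the
analysis assumes, at desk scale: a 20 × 20 grid of 5 km municipal cells
(400 areas, 100 × 100 km) and about 1,600 sampling points in three
west-to-east density bands (0.30, 0.15, 0.03 points/km²) — a scaled-down
analogue of a national universe of ~8,000 towns and ~13,000 points sampled
at one point per 10, 20 and 100 km². Populations are lognormal
(median ≈ 1,800 inhabitants) with a fixed 18-group age pyramid, two sexes
and two quinquennia (person-years = mid-period population × 5); reference
death rates rise log-linearly with age group to all-cancer-like magnitudes,
with a male excess and a small second-period decline. Ground truth defaults:
$\beta = \log 1.2$ per unit log concentration (alternatively a quartile
profile or a per-quartile trend), small positive confounder effects,
$\gamma = 0.1$, $\sigma_u = 0.3$, $\sigma_v = 0.1$; field range 30 km,
$\sigma_f = 0.7$, mean $\log 9$ (median ≈ 9 mg/kg, arsenic-like),
$\sigma_x = 0.45$. Emitters are placed uniformly (one per ten areas) and add
a Gaussian-kernel bump of 0.1 log units to the nearby field — roughly a ten
percent concentration excess near industry. These defaults are fixed once;
tests and the acceptance script run against them.

What the generator does *not* emulate: real geography (areas are a regular
grid with rook adjacency; no islands or irregular polygons), compositional
closure of multi-element geochemistry, preferential sampling, spatially
structured covariates, or age–period–cohort structure in risk. Passing
parameter-recovery tests on this universe therefore demonstrates internal
consistency of the estimators under the model's own assumptions — not
robustness to the ways real data violate them.

## Numerical choices

* Quartile cut points use the linear-interpolation percentile rule (type-7
  quantiles), intervals half-open on the right except the last; ties that
  empty a quartile are an error suggesting continuous coding.
* Significance = the 95% credibility interval strictly excludes RR 1.
* The mesh is a graded tensor-product triangulation: uniform cells sized so
  every interior edge (including diagonals) is at most the configured
  maximum, a geometrically coarsening extension ring against boundary
  effects, each cell split along the same diagonal. It is conforming and
  fully deterministic; the trade-off is that non-rectangular domains are
  meshed via their bounding box (vertices are still classified against the
  polygon). General constrained Delaunay meshing is out of scope for the
  rectangular synthetic domains used here.
* Projector tie-breaks: a point on a cell boundary belongs to the
  right/upper cell; on a cell diagonal, to the lower triangle.
* Mesh-resolution selection reconstructs an information-criterion scan over
  candidate maximum edge lengths: each candidate is scored by DIC (WAIC
  optional) of the Gaussian field-only model for the sample concentrations —
  both available in closed form — and the coarsest candidate within 2 points
  of the best score wins. This is a reconstruction of a described mechanism,
  not a reproduction of any particular published scan.
* Kriging neighbourhoods use the 64 nearest samples by default (ties broken
  by sample order); the dense global solve is retained and is checked against
  an independently coded oracle to $10^{-10}$.
* Dense Matérn simulation adds a $10^{-10}$ diagonal jitter; duplicate
  locations are reported by index pair. SPDE factorisation retries once with
  a $10^{-8}$ relative jitter.
* Isolated areas (no neighbours) get a stiff prior pinning their structured
  effect at zero; the unstructured term covers them. Connected components
  are constrained to sum to zero separately.
* The difference-of-means comparison (emitter vs non-emitter towns) uses
  flat priors on means and Jeffreys priors on variances, simulated by
  composition; a Student-t likelihood (fixed df, scale-mixture Gibbs) is the
  robust option. Group seed streams are derived from a canonical ordering of
  the inputs so swapping arguments negates the posterior exactly. The
  comparison is made on the mg/kg scale of interpolated municipal values.

## Problem sizes used by the test suite

Unit tests run on 400-area universes (with and without samples) and a
compact 150-area universe for the joint model. The end-to-end property
checks use: 40 replicates of the 400-area quartile-recovery experiment
(chains of 450 kept / 250 burn-in draws), 10 replicates for the trend test,
20 paired replicates of approach A vs approach B at 150 areas with the
sampling density scaled to two soil samples per municipality — the
area-to-sample ratio at which the kriging error the plug-in ignores is
material, mirroring a national study with fewer sampling points than towns —
using 800 kept draws for the joint fits because 95% quantile estimates
stabilise more slowly than posterior means, and a fine 100 × 100 km mesh at 2.5 km edge length for the
SPDE-versus-Matérn correlation check. These sizes are the package's chosen
compromise between Monte Carlo resolution and a test suite that runs in
minutes; all of them are scaled up simply by changing `sim_config()` and
`mcmc_config()`.

## Known limitations

* The ICAR structure matrix is unscaled, so $\sigma_u$ is a conditional,
  graph-dependent scale not directly comparable across adjacency structures.
* Approach B assumes the measurement-error and field models are correct;
  there is no robust (non-Gaussian) concentration likelihood.
* Exposure at an area is the centroid value of the field; areal averaging is
  not implemented.
* Anisotropy, non-stationarity, universal kriging and cross-validation-based
  variogram selection are out of scope.
* Short chains can flag the BYM SDs as unconverged; the flag is honest —
  lengthen the chains rather than ignoring it.
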