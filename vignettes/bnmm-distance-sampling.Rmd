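---
title: "Hierarchical N-mixture distance sampling: model, diagnostics and overlap metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical N-mixture distance sampling: model, diagnostics and overlap metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nmixds)
```

## The model

`nmixds` fits a single-step Bayesian binomial N-mixture model to
line-transect survey counts. The sampling unit is an effort *segment*: a
contiguous stretch of trackline of length $L_i \le 10$ km. Within the
truncation strip of half-width $W$ km either side of the trackline, the
latent number of animal groups $N_i$ follows a zero-inflated Poisson
(ZIP),

$$
\Pr\{N_i = 0\} = (1-\psi) + \psi e^{-\lambda_i}, \qquad
\Pr\{N_i = k > 0\} = \psi \frac{\lambda_i^k e^{-\lambda_i}}{k!},
$$

with $\psi$ the probability that the segment belongs to the non-zero
(occupied) component and

$$
\lambda_i = 2 W L_i \, e^{\beta_0 + \beta X_i + \tau_i},
\qquad \tau_i \sim \mathrm{Normal}(0, \sigma_\tau^2).
$$

$2WL_i$ is the searched area in km² and acts as an offset, so
$e^{\beta_0}$ is a baseline density in groups/km²; $X_i$ are
environmental covariates extracted at the segment midpoint (centred and
scaled), and $\tau_i$ is an observation-level random effect absorbing
overdispersion.

Observed counts are thinned by imperfect detection,
$n_i \sim \mathrm{Binomial}(N_i, p_i)$. Detection declines with
perpendicular distance $y$ as a half-normal, $g(y) = e^{-y^2/2\sigma_i^2}$,
whose scale is log-linear in binary sea-condition covariates (wave
height, wind speed, sea state, each coded 0/1 at an operational cutoff):
$\sigma_i = e^{Y_i \alpha}$. Since groups are uniform in perpendicular
distance within the strip,

$$
p_i = \frac{1}{W}\int_0^W e^{-y^2/2\sigma_i^2}\,dy
    = \frac{\sigma_i\sqrt{2\pi}}{W}\Big(\Phi(W/\sigma_i)-\tfrac12\Big),
$$

and each observed distance $y_d$ contributes its conditional density
$e^{-y_d^2/2\sigma_i^2} / (W p_i)$ to the likelihood. Counts and
distances are fitted **jointly** in one step, so detection uncertainty
propagates into the density coefficients and everything downstream.

$\alpha$ carries an intercept even though the covariates are all binary:
without it the baseline detection scale would be pinned at 1 km, an
arbitrary unit choice rather than an estimate.

### Marginalization

A binomially thinned Poisson is again Poisson, with mean
$\lambda_i p_i$. The sampler therefore never carries $N_i$: a zero count
contributes $\log[(1-\psi) + \psi e^{-\lambda_i p_i}]$ and a positive
count $\log\psi + \log \mathrm{Poisson}(n_i;\lambda_i p_i)$. The test
suite verifies this identity against brute-force summation over the
latent count up to $N = 500$ at tolerance $10^{-8}$. When latent counts
are wanted (e.g. for mapping realized abundance) `latent_counts()`
reconstructs them exactly from their conditional distribution, which
guarantees $N_i \ge n_i$ draw by draw.

### Priors and sampling

Priors are vague on the sampling scale: $\mathrm{Normal}(0, 10)$ on
$\beta_0$, $\beta$ and $\alpha$; $\mathrm{Uniform}(0,1)$ on $\psi$;
half-normal with scale 2 on $\sigma_\tau$. All are configurable through
`bnmm_priors()`.

`fit_bnmm()` runs an adaptive component-wise random-walk Metropolis
sampler on $(\beta_0, \beta, \operatorname{logit}\psi, \alpha,
\log\sigma_\tau)$, with proposal scales adapted toward 44% acceptance by
a diminishing Robbins–Monro rule during burn-in only (so the retained
chain is a genuine Markov chain). The $\tau_i$ are conditionally
independent given the top level, and are updated in one vectorized
Metropolis sweep per iteration. Convergence is monitored with
split-$\widehat{R}$ per top-level parameter; `fit_bnmm()` warns and
flags the fit when any exceeds 1.1. Because detection covariates are
binary, segments collapse into at most 8 detection classes and the
distance likelihood reduces to per-class sufficient statistics, which is
what makes long chains affordable in plain R.

The retained posterior sample follows the classical
chains × (iterations − burn-in)/thinning bookkeeping
(`mcmc_retained()`); the survey protocol of 3 chains × 70,000
iterations, 40,000 burn-in, thinning 50 retains 1,800 draws.

### Group size

Group sizes enter abundance as a multiplicative factor, not through the
count likelihood. Sizes (minimum 1) are modelled as a shifted negative
binomial, `size − 1 ~ NegBin(mu, k)`, which spans whale-like samples
(mean ≈ 2, variance ≈ 2) through dolphin schools (mean ≈ 47, variance in
the thousands). The posterior uses a $\mathrm{Normal}(0,3)$ prior on
$\log\mu$ and a $\mathrm{Gamma}(2, 0.5)$ prior on $k$. The Gamma shape
matters: with an all-ones (or any constant) size sample the likelihood
is flat along the ridge $k \to 0$ at arbitrary $\mu$, and a prior that
does not vanish at $k = 0$ lets the variance posterior diverge. A
consequence worth knowing: a negative binomial cannot have variance
below its mean, so a constant sample at size $s > 1$ yields a variance
posterior near $s - 1$, not near 0 — a model limitation, not a bug.

## Survey preparation choices

* **Truncation distances are in km** (e.g. 2.5 for large whales, 1.5
  for dusky dolphins, 2 for common dolphins), the only unit under which
  $2WL$ is an area in km² consistent with segment lengths in km.
* **Sea-condition cutoffs** are intervals in operational practice (wave
  1.75–2.25 m, wind 17–21 kn); the package defaults to the interval
  midpoints (2.0 m, 19 kn) and Beaufort 2, all configurable. Values
  exactly at a cutoff code 0 (the ≤ rule). Beaufort ≥ 4 flags the record
  off-effort rather than coding 1, since searching stops there.
* **Covariate extraction** takes the raster cell containing the segment
  midpoint, without interpolation, and `standardize_covariates()` stores
  the training centring/scaling constants so prediction grids are
  standardized with them, never re-estimated.
* Species with fewer than 30 retained sightings are flagged as excluded
  from modelling; their zero-count tables are still produced.

## Model checking

`check_model()` bundles the battery:

* **Scaled (PIT) residuals** against posterior replicates with
  randomized tie-breaking:
  $r_i = (\#\{rep < obs\} + U(\#\{rep = obs\}+1))/(R+1)$. Under the true
  model these are i.i.d. uniform; the suite verifies the nominal
  rejection rate of the KS test by simulation.
* **Dispersion, outlier, uniformity and zero-percentage tests** on the
  replicate distribution, with two-sided Monte-Carlo p-values (ties
  count toward both tails).
* **Posterior-predictive chi-squared**: Pearson discrepancy with a floor
  of $\varepsilon = 10^{-6}$ on expected counts, giving a Bayesian
  p-value ($\Pr(D^{rep} \ge D^{obs})$, ties counting as ≥) and
  $\hat{c} = \sum D^{obs} / \sum D^{rep}$.
* **Moran's I** on the residuals with inverse-Euclidean-distance weights
  (zero diagonal; coincident points capped at the largest finite
  weight), permutation p-value from ≥ 999 shuffles; k-nearest-neighbour
  binary weights are available as an alternative.

Replication is **conditional** by default: each replicate reuses its
draw's own $\tau_i$, matching standard residual practice for
observation-level effects; `condition = "marginal"` redraws them.

## Prediction, abundance, pooling

`predict_group_density()` evaluates $\psi\, e^{\beta_0 + \beta X_g}$
per draw on a grid (default 7 × 7 km cells, 49 km²). Two deliberate
defaults, both switchable:

* $\psi$ **is included** — predictions are unconditional expectations of
  the ZIP, not densities conditional on occupancy;
* $\tau$ **is excluded** (no $e^{\sigma_\tau^2/2}$ lognormal
  correction) — the observation-level effect is treated as segment-level
  sampling noise rather than habitat signal. `tau_correction = TRUE`
  applies the correction for sensitivity analysis.

Cells whose covariates fall outside the training range are predicted but
flagged in an extrapolation mask.

Abundance per draw is $\sum_g N_g \cdot \mathrm{area}_g \cdot
\bar{s}$, with $\bar{s}$ a mean-group-size draw aligned one-to-one with
the density draws. Seasonal abundance posteriors (e.g. January, April
and October grids for austral summer, autumn, spring) are pooled by
concatenating draw vectors with equal weight — the pooled interval
expresses uncertainty over which seasonal conditions are the right ones,
and is deliberately wider than any single season's.

## Vessel overlap

`vessel_density()` turns daily tracking pings into a vessels/day layer:
within each month, the number of distinct vessels with at least one ping
in a cell per day is summed and divided by the days with available data
(normally 25–31; sparser months are kept with a warning), and monthly
layers are averaged. A vessel pinging five times in a cell on one day
counts once; no trajectory interpolation is attempted between pings, and
cells without pings are genuine zeros, not missing data.

The risk layer is the relative probability of cetacean–vessel encounter,
$RPCVE_i = P_{w,i} P_{v,i} / \sum_j P_{w,j} P_{v,j}$ with
$P_w$, $P_v$ the cell-normalized cetacean and vessel layers; it is
invariant to rescaling either input. Distribution overlap is quantified
by Schoener's $D = 1 - \tfrac12\sum|p_i - q_i|$ and Warren's
$I = 1 - \tfrac12\sum(\sqrt{p_i}-\sqrt{q_i})^2$ after min–max rescaling
each layer to $[0,1]$ and normalizing to probability vectors — the
convention of the niche-overlap literature. Min–max rescaling of a
constant layer is undefined and errors; `rescale = "none"` accepts
already-normalized layers (and is the mode in which the textbook
two-cell identities $D=1$, $D=0$, $I=\sqrt{0.5}$ hold exactly).

## The synthetic-data generator

`simulate_survey()` generates data with exactly the structure the model
assumes: smooth standardized environmental fields (low-pass-filtered
Gaussian noise on the grid), straight tracklines cut into ≤ 10 km
segments, ZIP counts with the area offset and lognormal overdispersion,
uniform perpendicular placement thinned by the covariate-dependent
half-normal, and port-clustered daily vessel pings with occasional
whole-day gaps. All randomness flows through the configuration seed;
identical configurations reproduce identical surveys.

Defaults describe a mid-density survey: baseline density
$e^{-3.9} \approx 0.02$ groups/km², occupancy $\psi = 0.75$,
environmental effects $(0.5, -0.3)$ on two fields, baseline detection
scale 1 km over a 2.5 km strip ($p \approx 0.5$) with poorer conditions
shrinking it by factors $e^{-0.5}, e^{-0.4}, e^{-0.3}$, overdispersion
$\sigma_\tau = 0.3$, and shifted-negative-binomial group sizes of mean
2. A 100-transect configuration yields roughly 400 segments, the size
used by the recovery experiments.

What passing tests on these data do **not** show: robustness to
misspecified detection shapes (hazard-rate tails), non-ZIP zero
mechanisms, spatially autocorrelated residual structure beyond the
random effect, responsive animal movement, or measurement error in
distances. The generator is a correctness instrument, not an
oceanographic simulator (no ENSO, no upwelling dynamics).

## Problem sizes and numerical choices

The shipped experiments use sizes chosen to make the statistics
informative at interactive cost: 20 replicate surveys of ~400 segments
with 2 × 5,000-iteration chains for interval coverage; 50 replicate
25-transect surveys with single 2,200-iteration chains for
posterior-predictive calibration; 100 trials of 100 segments × 100
replicates for residual calibration; 10⁴ segments for the
thinned-Poisson goodness-of-fit check; 10⁵ groups for detection-fraction
checks. Monte-Carlo assertions use 3-standard-error bands.

Other numerical details: the ZIP zero term uses the exact $-\mu$ branch
at $\psi = 1$; degenerate likelihood corners ($\sigma \to 0$ with
observed distances) evaluate to $-\infty$ and are rejected by the
sampler rather than propagating NaN; the coordinate system is a planar
km grid with row-major half-open cells, with any lon/lat projection left
to a shim upstream.

## Known limitations

* The Metropolis sampler is adequate for the ~10 top-level parameters of
  these models but mixes slowly for $\sigma_\tau$ when counts are
  sparse; split-$\widehat{R}$ flags this honestly.
* Detection-probability covariates are evaluated at the segment's
  recorded conditions; if conditions change mid-segment between effort
  updates, sightings inherit the segment values.
* Model comparison (WAIC/DIC) is out of scope; alternative covariate
  sets are compared by repeated fits and the checking battery.
* Hazard-rate and adjusted-term detection functions, left-truncation,
  and spatial random fields are not implemented.
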