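---
title: "The joint consumption model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The joint consumption model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Household recall surveys of wild meat consumption come in three datatypes of
increasing richness: a binary consumption/non-consumption flag per recall
event, a frequency of consumption per household (the proportion of monitored
days with a consumption event), and a quantity of undressed meat consumed,
standardized to kg per adult male equivalent (AME) per day. Any one survey
rarely provides all three, so the package fits a joint model whose product

$$\text{consumption rate} = \text{consumption} \times \text{frequency}
  \times \text{quantity}$$

defines the daily consumption rate in kg/AME/day. The three submodels share
survey locations, and two of them share a latent spatial field, so sparse
datatypes borrow strength from rich ones.

## Consumption probability

Each recall event $r$ is Bernoulli with logit-linear probability:

$$\mathrm{consumption}_r \sim \mathrm{Bernoulli}(\pi_r), \qquad
  \mathrm{logit}(\pi_r) = \mathbf{x}_r^\top \boldsymbol\alpha +
  \varepsilon_{l(r)}$$

where $\mathbf{x}_r$ holds the fixed effects (settlement type, the four
continuous covariates, education, optionally the recall duration in days —
longer recalls are more likely to contain at least one consumption event)
and $\varepsilon$ is the spatial effect of the recall's location. Recalls
sharing a design row are reduced to binomial counts internally; the
reduction is exact.

## Frequency of consumption

The observed frequency of household $h$ lies in $[0,1]$ and follows a Beta
distribution parameterized by its mean $\phi_h$ and sample size $\kappa$:

$$\mathrm{frequency}_h \sim \mathrm{Beta}(\phi_h \kappa, (1-\phi_h)\kappa)$$

The mean is a noisy version of the regression surface, with noise scaled by
how briefly the household was monitored:

$$\mathrm{logit}(\phi_h) = \underline\phi_h + \Sigma_h \tau_h, \qquad
  \Sigma_h = \sigma\,(365 - \mathrm{mdays}_h), \qquad
  \tau_h \sim \mathcal N(0, 1)$$

A household monitored on all 365 days reports its frequency without
monitoring noise ($\Sigma_h = 0$); one monitored a single day has the
maximum noise $364\sigma$. The non-centred form (sampling $\tau_h$ rather
than $\mathrm{logit}\,\phi_h$) is used throughout; `log_posterior()` also
evaluates the centred form, and the two are tested to define the same joint
density under the linear change of variables.

Observed frequencies of exactly 0 or 1 are clamped to
$[10^{-4}, 1-10^{-4}]$ before the Beta likelihood; the count of clamped
records is carried in the model data and the fit object.

## Quantity per AME

Quantity recalls with positive consumption follow a Gamma model on the
per-AME ratio, parameterized so that $\mu_r$ is the mean:

$$\mathrm{quantity}_r / \mathrm{AME}_r \sim
  \mathrm{Gamma}(\mu_r \theta, \theta), \qquad
  \log(\mu_r) = \mathbf{z}_r^\top \boldsymbol\gamma +
  \gamma_{\mathrm{AME}} \mathrm{AME}_r$$

The AME count enters the mean itself (quantity per person falls as more
people share the meal), which is why missing AMEs must be imputed inside
the model rather than dropped.

**Change of variables.** The observed datum is the quantity, not the ratio.
When $\mathrm{AME}_r$ is known this distinction is a constant, but when it
is a model parameter (an imputed value $A$) the density of the observation
is $\mathrm{dgamma}(q/A)\cdot 1/A$. The $-\log A$ term matters: without it
the log-density grows like $(1-\mathrm{shape})\log A$ whenever the Gamma
shape $\mu\theta$ falls below 1, an improper ridge that drags imputed AMEs
(and with them $\nu$, $\psi$ and the quantity coefficients) to absurd
values. The package therefore includes the Jacobian for imputed-AME rows.

## Spatial autocorrelation

Locations close to each other share unmeasured cultural and environmental
drivers of consumption. Each spatial submodel carries a latent Gaussian
process over the survey locations with the exponentiated-quadratic kernel

$$X_{l,j} = \zeta^2 \exp(-\rho^2 D_{l,j}^2) + \delta\,[l = j]$$

where $D$ is the great-circle distance matrix in km (haversine, mean earth
radius 6371 km; a planar option exists for projected coordinates), $\zeta$
is the marginal sd, $\rho$ the inverse length scale (1/km) and
$\delta = 10^{-9}$ a fixed diagonal jitter. The field is sampled
non-centred: $\boldsymbol\varepsilon = L_X \boldsymbol\eta$ with
$\boldsymbol\eta \sim \mathcal N(0, I)$ and $L_X$ the lower Cholesky factor.
By default the consumption and frequency submodels each carry their own
independent field over the shared distance matrix (`spatial =
c("consumption", "frequency")`); the simulation fits use
`spatial = "consumption"`, matching the generator.

## AME imputation

Household AMEs are modelled with a truncated-normal population distribution
$\mathcal N(\nu, \psi)$ on $(0, \infty)$. Observed household AMEs enter this
term and pin $(\nu, \psi)$ near the sample mean and sd; missing AMEs are
parameters drawn from the same distribution and updated against their
households' quantity recalls. Anchoring the population model on the observed
values is what makes the imputation well behaved: if only the missing values
informed $(\nu, \psi)$, the ridge described above could inflate $\psi$ and
run away. The prior for $\nu$ is centred at the observed mean AME
(5.09 in the real database; the value is recomputed from the data at hand).

# Priors

All priors are overridable through `default_priors()`:

* coefficients (logit/log scale): Normal(0, 2.5);
* $\zeta$, $\sigma$, $\psi$: half-Normal(0, 2);
* $\rho$: half-Normal(0, 0.05) — with distances in km this spans length
  scales from roughly 20 km upward, the range over which village clusters
  plausibly share unmeasured drivers;
* $\kappa$: the prior is placed on the Beta noise *scale*,
  $1/\sqrt{\kappa} \sim \text{half-Normal}(0, 1)$. A prior with an
  exponential tail in $\kappa$ itself (any Gamma) pays linearly for large
  precisions and therefore caps $\kappa$; when the data carry little
  observation noise beyond the monitoring channel, that cap imposes a
  spurious Beta noise floor whose skew biases the frequency intercepts
  upward. The sd-scale prior is flat as the noise vanishes, so the
  posterior is free to push $\kappa$ as high as the data warrant;
* $\theta$: Gamma(2, 0.1);
* $\nu$: Normal(observed mean AME, 2) truncated at 0;
* random-intercept sds: half-Normal(0, 1).

# The synthetic world

`landscape_spec()` / `generate_landscape()` / `simulate_truth()` /
`observe()` reproduce the structure of a designed simulation study: a
900-cell landscape in three contiguous regions (360/180/360 cells) with
contrasting covariates ($V_1$ high in region 1, $V_2$ high in region 2,
both intermediate in region 3), one location per cell, Poisson household
counts around means 40/100/65, Poisson AMEs around mean 5, and a two-level
household covariate $V_3$ with probabilities 0.30/0.70. Truth is simulated
as: $\pi$ logit-linear in $V_1$, $V_3$ and a GP draw over the cell distance
matrix; $\phi$ logit-linear in $V_2$, $V_3$; $\mu$ log-linear in $V_2$ and
the household AME — all with region-varying intercepts and slopes.

The observation step surveys a fraction of cells (the coverage scenarios
are 5/10/15%), lets 80% of surveyed locations report frequency and 50%
quantity, hides 20% of household AMEs, interviews 20% of each surveyed
cell's households, and draws monitored days log-uniformly on 1..365.
Observed frequencies apply logit-normal monitoring noise with sd
$\sigma(365-\mathrm{mdays})$ to the true value — no extra Beta draw — so a
fully monitored household reports its true frequency exactly. Consumption
flags are per-day Bernoulli draws and quantities per-recall Gamma draws.

The generative intercepts and slopes are stand-ins chosen once so that
roughly 16% of recall events are consumption events (the real database is
84% non-consumption) and so that quantities sit at plausible fractions of a
kg per AME per day; they are printed in `landscape_spec()` and fully
overridable.

What the generator does *not* emulate: real covariate surfaces (the four
continuous drivers are placeholders in the synthetic locations table),
study-level heterogeneity (one synthetic study), education structure,
seasonality, or reporting biases such as the cooking-pot overestimate.
Passing recovery tests therefore demonstrate that the machinery is
self-consistent at survey-like sizes — not that the model is correct for
any real survey.

Because the generator follows the published simulation design rather than
the fitted model, the Beta sample size $\kappa$ has no generative truth
(the generator's frequency noise is purely logit-normal, which the model
approaches as $\kappa \to \infty$); recovery checks therefore target the
regression coefficients, and $\sigma$, $\theta$, $\zeta$, $\rho$ are
monitored descriptively.

# Posterior computation

`sample_posterior()` runs an adaptive block sampler written for the
specific geometry of this posterior:

* adaptive-Metropolis blocks (proposal covariances seeded from GLM fits of
  each submodel and adapted during warmup) for the coefficient vectors and
  the log GP hyperparameters, plus a component-wise refresh of the
  consumption block;
* elliptical slice sampling for $\boldsymbol\eta$ and $\boldsymbol\tau$,
  whose priors are standard normal, plus an element-wise refresh of the
  household logit-frequencies $u_h$ (conditionally independent given the
  rest, each is re-proposed from the Gaussian approximation of its
  conditional and accepted with the exact densities — vector-wise slice
  moves alone cannot re-randomize the field when $\kappa$ is large);
* likelihood-invariant "ridge" moves that shift location-level coefficients
  and compensate the spatial field exactly (the two are confounded at short
  range, and the move samples the ridge the prior defines);
* interweaving moves for $(\sigma, \boldsymbol\tau)$ and
  $(\kappa, \boldsymbol\tau)$ — rescaling or contracting the non-centring
  variates jointly with the hyperparameter so the chain can traverse the
  noise-attribution funnels;
* an exact Gibbs draw of $\boldsymbol\beta$ in the centred
  parameterization (holding the household logit-frequencies fixed the full
  conditional is Gaussian), which removes the $\beta$–$\tau$ funnel;
* element-wise vectorized Metropolis for imputed AMEs and random
  intercepts, which are conditionally independent.

Each recorded iteration comprises `sweeps = 3` passes over this schedule.
Adaptation is frozen after warmup. Runs are deterministic given the seed.
Split-Rhat is reported for every monitored scalar and parameters exceeding
1.01 are named in a warning — with the desk-scale defaults (2 chains of
1,500 iterations, 1,000 warmup) some hyperparameters can sit above that
bar, and longer runs (the published analysis scale is 4 chains of 5,000)
are a configuration change away.

Numerical details: Cholesky failures of the GP kernel raise an error
suggesting a larger jitter rather than silently repairing the matrix;
degenerate proposals (non-positive scales) are rejected through the prior;
the boundary clamp count and all block acceptance rates are reported in the
fit.

# Prediction

`predict_cells()` evaluates the fitted submodels on grid cells. Categorical
covariates without a single cell-level value — settlement type, education —
are handled by weighting the level parameters with the proportions of
people in each level; `build_cell_design()` implements this as a weighted
average of level-wise design rows, which is algebraically identical.
Settlement classification uses the population thresholds (villages up to
10,000 people, towns to 100,000, cities above; boundary values go to the
larger class), and cell AMEs convert population through an adult sex ratio
of 0.5 and the adult-female (0.86) and child (0.78) multipliers.

Per posterior draw and cell the predicted probability, mean frequency and
mean quantity are computed with random effects at their means and the
spatial field at its prior mean, then a Bernoulli, Beta and Gamma draw are
taken and multiplied into the consumption rate; annual biomass is
rate × AME × 365 kg, and regional totals are sums over cells (additive
over any partition). The quantity prediction is evaluated at the observed
mean AME per recall, and the consumption prediction at a one-day recall
(daily rates). Posterior medians, means, sds and 95% intervals are
reported per cell; the per-cell sd maps and the covariate dissimilarity
index $\Delta \in [0, 4]$ (sum over the four continuous covariates of the
absolute difference from the recall-weighted data mean, normalized by its
maximum across cells) serve as the two uncertainty maps.

The conventional cell geometry is the 40-km covariate circle
($\pi \cdot 40^2 \approx 5{,}027$ km²) with cell side 70.09 km and forest
buffer radius twice the side (140.18 km); the printed side is kept although
$\sqrt{5027} = 70.90$, because the buffer is defined from it.

# Desk-scale checks

The test suite exercises the whole chain at sizes that run on one CPU in
minutes: the `tiny` fixture (100 cells, 20 surveyed locations, ~200
households) drives the unit and pipeline tests, and the recovery study
runs ten replicates of the full 900-cell landscape at the 10% coverage
scenario with one chain of 1,500 iterations each, checking that at least
90% of generative coefficients fall in their 95% credible intervals and
that the posterior median of total consumed tonnes lands within 25% of the
truth in at least 8 of 10 replicates. The published analysis used 100
replicates per scenario; ten keep the check affordable while still making
systematic miscalibration visible.

# Known limitations

* The sampler is exact but not gradient-based; posteriors with many more
  locations (thousands) would warrant a sparse-GP approximation and a
  compiled implementation.
* Study-type and period effects are plumbing-complete (any column of the
  survey tables can enter the formulas) but the synthetic world generates a
  single study and period, so they are untested against ground truth.
* Household random intercepts are supported but off by default; with one
  recall per household they are unidentifiable, and the simulation
  generator creates none.
* The dissimilarity index normalizes by the maximum absolute difference
  across the supplied grid, so its scale depends on the grid's extent.
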