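---
title: "Optimizing high-moisture extrusion: response surfaces and pool-constrained Bayesian optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing high-moisture extrusion: response surfaces and pool-constrained Bayesian optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmeopt)
```

## The problem

High-moisture extrusion (HME) pushes a hydrated plant-protein blend through
a heated twin-screw barrel into a cooling die, where the melt solidifies
into a fibrous, meat-like structure. The texture of the extrudate depends
strongly on a handful of process settings; here three are tuned:

* **barrel temperature** (last two barrel zones), 110–140 °C,
* **water content**, 55–65 % of total mass,
* **cooling-die temperature** (section a), 60–80 °C, with section b paired
  to it (60→55, 70→60, 80→65 °C; the models treat the cooling die as the
  single section-a scalar, and section b is derived reporting metadata).

The goal is to make the extrudate's mechanical texture profile — hardness,
springiness, chewiness, transverse/longitudinal cutting force, and
optionally transverse/longitudinal tensile strength — as close as possible
to a reference product (ready-to-eat chicken breast). Each pilot-scale run
is expensive, so the question the package addresses is not only *where* the
optimum lies but *how few runs* are needed to find it.

## The objective: weighted-sum scalarization

Multi-property closeness is collapsed to a single score,

$$S(\theta) = \sum_{i=1}^{n} w_i \,
  \frac{|x_i(\theta) - x_{i,\mathrm{ref}}|}{x_{i,\mathrm{ref}}},$$

the weighted sum of normalized absolute deviations of each texture property
from its reference value (`scalarize()`). Weights default to 1
(no empirical basis for differential weighting); normalization by the
reference makes the score unit-free, so the dimensionless springiness is
treated identically to the force-valued properties. $S = 0$ exactly at the
reference; larger is worse, and the optimization problem is
$\min_\theta S(\theta)$.

Two property subsets are predefined: `without_tensile` (the five
compression/cutting properties) and `with_tensile` (adding the two tensile
strengths). The packaged case study distributes the tensile-inclusive
responses at run level. When replicated measurements are present the
default is to average the replicate profiles and scalarize the mean
(`mean_then_scalarize`); the reverse order is exposed because neither
convention is externally fixed, and on noisy replicates the two differ
(the absolute value does not commute with averaging).

## Design of experiments and the response surface

The three-factor Box-Behnken design (`generate_bbd()`) has 15 runs: 12 edge
midpoints (each pair of factors at coded ±1 with the third at 0) plus 3
center replicates. It deliberately avoids the cube corners — extreme
combinations risk unstable extrusion — while supporting a full quadratic
model. Run order is fixed, not randomized, so that fixtures and regression
tests are bit-stable; randomization schedules are out of scope.

The response surface is the second-order polynomial

$$\hat S = \beta_0 + \sum_i \beta_i \theta_i + \sum_i \beta_{ii} \theta_i^2
  \;\left(+ \sum_{i<j} \beta_{ij} \theta_i \theta_j\right),$$

fit by ordinary least squares **on coded units** (`fit_quadratic()`).
Coded-unit regression makes the linear columns orthogonal and is what makes
the conventional adjusted-sums-of-squares ANOVA reproducible; actual-unit
coefficients are derived from the same fit and give identical predictions.
Interactions are excluded by default — the usual final-model choice when
screening shows them insignificant on this design — but can be included for
term screening.

`rsm_anova()` reports the standard decomposition: model, pooled linear and
square rows, per-factor rows with adjusted (drop-one-term, type-III) sums
of squares, and the residual split into lack-of-fit and pure error. Pure
error comes from the center replicates only; its mean square doubles as the
observation-noise estimate used later by the surrogate. Per-term SS are
adjusted rather than sequential because the squared-term columns of a
Box-Behnken design are not mutually orthogonal; only adjusted SS reproduce
the per-factor F statistics together with the pooled rows. `r2_metrics()`
adds $R^2$, adjusted $R^2$, and predictive $R^2$ from PRESS via the
leverage shortcut $\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$; equivalence
with explicit leave-one-out refits is asserted by a test rather than being
a runtime path. A replicate-free dataset still yields a table, with a
warning and no lack-of-fit split; a lone center point then carries leverage
1 and PRESS is flagged undefined rather than silently extrapolated.

### Locating and reporting the optimum

`find_optimum()` minimizes the fitted polynomial over the operational box
by dense grid search (default 1 °C × 0.5 % × 1 °C) followed by L-BFGS-B
polish, and returns both the continuous minimizer and a reported setting
snapped to the operational grid. The default snap direction is **down**
(truncation toward the lower bound) rather than round-to-nearest. This is a
deliberate reporting convention: process setpoints for this line are quoted
as the grid value actually reachable below the continuous optimum, and it
is the convention consistent with every optimum quoted in the packaged
validation records. Near the optimum the surface is flat (the fitted
curvature changes the prediction by ~0.003 score units across one grid
step), so the snap direction never affects the predicted value materially;
`snap = "nearest"` and `snap = "none"` are available.

On the packaged case study:

```{r}
cs <- load_case_study()
fit <- fit_quadratic(cs$dataset)
rsm_anova(fit)
find_optimum(fit)[c("point", "value")]
```

## The Gaussian-process surrogate

The surrogate is a zero-mean GP with the anisotropic constant × RBF kernel

$$k(\theta, \theta') = \sigma^2 \exp\!\Big(
  -\tfrac12 \textstyle\sum_d (\theta_d - \theta'_d)^2 / l_d^2 \Big),$$

over coded inputs, with a fixed noise variance $\alpha$ added to the kernel
diagonal. Responses are left on their raw scale so that $\alpha$ can be set
directly to the sample variance of the three center replicates (equal to
the ANOVA pure-error mean square, 34.35 on the case study) — the
measurement-noise estimate obtained without any modeling assumption.
$\sigma^2$ and the per-dimension length scales are optimized by maximizing
the log marginal likelihood with L-BFGS-B on log parameters, from the
configured start plus 10 seeded log-uniform restarts; $\alpha$ is never
optimized. Bounds default to $l_d \in [0.1, 10]$ coded units and
$\sigma^2 \in [10^{-2}, 10^4]$, spanning the design box by roughly two
orders of magnitude in each direction. The posterior standard deviation
reported is that of the latent noise-free function (it excludes $\alpha$).

Candidates are scored by expected improvement for minimization,

$$\mathrm{EI}(\theta) = \mathrm{E}\big[\max(S_{\mathrm{best}} - S(\theta),
  0)\big] = (S_{\mathrm{best}} - \mu)\,\Phi(z) + \sigma\,\phi(z),
  \qquad z = (S_{\mathrm{best}} - \mu)/\sigma,$$

and the next point is the EI **maximizer** — the standard closed form of
the expected reduction below the incumbent, which realizes the intended
minimization of expected loss (a sign-convention correction relative to
some printed statements of the acquisition in the applied literature).
The incumbent $S_{\mathrm{best}}$ is the minimum *posterior mean* over the
points observed so far, not the minimum raw observation; with
$\alpha$-level noise a raw minimum would chase noise excursions.

## The pool-constrained loop

`run_constrained_bo()` replays BO against the pre-measured design to make
the two strategies directly comparable on identical data:

1. initialize with the three center replicates as three separate
   observations (3 experimental trials) — the trial accounting only
   balances this way, and `init = "mean"` is exposed as the alternative;
2. each iteration scores the remaining design points by EI, selects the
   maximizer, retrieves its pre-measured response, refits the GP, and
   records (a) the best observed response so far and (b) the argmin of the
   posterior mean over the full operational box on a dense grid — the
   search is confined to the pool but the *estimate* of the optimum is not.

Tie-breaking in the acquisition adds a reproducible perturbation below
$10^{-12}$ (per iteration, independent of the run seed) and then takes the
lowest run id; consequently a noise-free dataset with `restarts = 0` yields
bitwise-identical traces for every seed, and the run-to-run stochasticity
of the replicated study comes from the hyperparameter-restart draws alone.

`convergence_analysis()` repeats the loop across seeds (default 50) and
aggregates the best-observed and predicted-minimum curves with
percentile 95 % bands. Convergence is declared at the first iteration after
which the mean best-observed curve changes by less than 1 % of its total
range over all remaining iterations; the threshold is a config knob because
no sharper external criterion exists, and 1 % of range is below any
practically meaningful texture difference. Trials-at-convergence adds the
three initialization trials.

```{r, eval = FALSE}
conv <- convergence_analysis(cs$dataset, n_runs = 50)
conv$trials_at_convergence
plot(conv)
```

On the packaged study this converges well within the 10-trial budget that
motivated the surrogate route, against 15 trials for the full design that
the polynomial model requires before it can be fit at all.

## Validation reporting

`prediction_error()` is the relative error in percent with the
*experimental* value as denominator — the only convention under which every
percentage in the packaged validation table is an arithmetic identity of
its printed (predicted, experimental) pair, which a test verifies row by
row. `build_comparison()` tabulates per-model error ranges and flags the
model with the lowest worst-case error. Reproducing the ±SD values attached
to predictions in the validation source is out of scope (their convention
is unstated).

## The synthetic generator

`surface_spec()`/`simulate_responses()` draw scalar responses from a known
quadratic (optionally with interactions and a sine-product ripple emulating
model-form misfit) plus homoscedastic Gaussian noise. The defaults are
anchored to the packaged study: coefficients near the fitted
tensile-inclusive surface and noise SD $\sqrt{34.35}$, the pure-error MS,
so synthetic and measured pipelines are statistically comparable.
`texture_surface_spec()`/`simulate_texture_dataset()` go one level deeper
and generate the seven texture properties themselves: each property follows
`scale * exp(latent(coded))` with a gentle log-scale quadratic latent and
multiplicative log-normal replicate noise. The exponential transform
guarantees strict positivity (the scalarization divides by reference
values) without truncation artifacts. Property scales are
order-of-magnitude placeholders for a chicken-breast-like reference
(hardness 30 N, springiness 0.85, chewiness 25 N, cutting forces 20/18 N,
tensile strengths 5/7 N); the study's raw per-property data are not
publicly deposited, so these are labeled synthetic stand-ins, and nothing
downstream depends on their absolute magnitudes.

What passing synthetic tests do show: unbiased coefficient recovery,
correct noise calibration (center-replicate variance matching the set
noise), EI/GP numerics against independent oracles, and that sequential
EI selection locates good pool points faster than random ordering. What
they cannot show: fidelity to real extrusion physics — heteroscedastic
noise, drift between center replicates run at intervals across a campaign,
or non-smooth responses near process instabilities are all outside the
generator.

## Numerical choices and limitations

* **Grid resolutions.** 1 °C × 0.5 % × 1 °C for both the polynomial
  optimum and the GP predicted-minimum report; fine enough that grid error
  is far below prediction uncertainty, coarse enough to keep a 50-run
  replicated study around a minute.
* **Kernel conditioning.** A jitter of $10^{-10}$ is always added to the
  kernel diagonal; a Cholesky failure after regularization raises an error
  suggesting a larger $\alpha$ rather than silently pseudo-inverting.
* **Location vs value of the surrogate optimum.** With 15 points and ARD
  length scales, weakly identified dimensions flatten and the posterior
  argmin can sit several degrees from the true one at nearly identical
  predicted value (the study's own two routes report 110 °C and ~115 °C
  at indistinguishable predicted responses). Properties of the recovered
  optimum are therefore asserted in *value* (regret within two noise SDs)
  rather than location; location-level agreement in the well-identified
  water-content dimension is tight.
* **Problem sizes in the test suite.** The replicated convergence studies
  use 50 seeds at 12 iterations; simulation-based calibration checks use
  500–1000 replicates; Monte-Carlo oracles use $10^6$ draws. These sizes
  put every stochastic assertion several standard errors away from its
  threshold while keeping the whole suite under a couple of minutes.
* **Out of scope.** Continuous-domain (unpooled) BO, batch acquisition,
  alternative acquisitions, learned noise (white-noise kernel), Chebyshev
  or epsilon-constraint scalarizations, multivariate (PCA/PLS-DA) texture
  analysis, and any modeling of the extruder physics itself.
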