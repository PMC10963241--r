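---
title: "Surface-crowding kinetics of interfacial depolymerases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-crowding kinetics of interfacial depolymerases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfcrowd)
```

## The scientific problem

Enzymes that depolymerize solid substrates — PET hydrolases on plastic
film, cellulases on cellulose, PHA depolymerases — act at a
solid/liquid interface. A well-documented and practically important
anomaly of such systems is the *inhibition effect*: past a certain
enzyme loading, adding more enzyme *decreases* the macroscopic product
formation rate, even though more enzyme is bound to the surface. The
conventional rate laws for heterogeneous biocatalysis (in particular
the inverse Michaelis–Menten law, in which substrate sites are limiting
and rate saturates monotonically in enzyme) cannot produce this
maximum.

`surfcrowd` implements a two-state *surface-crowding* (SC) kinetic
model that explains the inhibition effect mechanistically: as surface
coverage rises, adsorbed enzymes increasingly sit in *crowded*
configurations with a reduced catalytic rate constant. The package
provides the closed-form forward model, a two-step estimation workflow
(adsorption maximum likelihood, then kinetic maximum a posteriori),
local sensitivity analysis, BIC-based model comparison against the
inverse Michaelis–Menten law, and the surface-geometry calculations
(areal densities, nearest-neighbor distances of planar point
processes, localization-microscopy quadrant analysis) used to argue
that surfaces are in fact crowded at the relevant loadings.

## The model

Units are fixed package-wide: enzyme concentrations in nM, substrate
surface concentration $N_0$ in cm²/L, site density $\Gamma$ in
nmol/cm², rates in mA260/min. $\Gamma N_0$ is then in nmol/L = nM with
no conversion factor; film areas count both faces and neglect edges
(a 2 × 5 mm film is 0.2 cm², i.e. 200 cm²/L in 1 ml).

**Adsorption quasi-equilibrium.** Adsorption/desorption is fast
relative to catalysis. With total enzyme $E_T$, total sites
$N_T = \Gamma N_0$ and adsorption equilibrium constant $K_a$ (1/nM),
the adsorbed complex $EN$ solves
$K_a\,(E_T - EN)(N_T - EN) = EN$, whose physical root is

$$EN = \tfrac{1}{2}\Big[\Gamma N_0 + E_T + 1/K_a -
\sqrt{(E_T + \Gamma N_0 + 1/K_a)^2 - 4\,E_T\,\Gamma N_0}\Big].$$

Numerically we evaluate the *larger* root of the quadratic and obtain
the smaller one from the product of roots $E_T N_T$, which avoids
catastrophic cancellation when $1/K_a$ dominates the bracket. Site
coverage is $\theta = EN/(\Gamma N_0) \in [0, 1]$.

**Crowded/uncrowded partition.** Adsorbed enzymes exchange between an
uncrowded state (catalytic constant $k_{cat,uc}$) and a crowded state
($k_{cat,c} \le k_{cat,uc}$) fast relative to catalysis, governed by a
single equilibrium constant $K_c$:

$$EN_{uc} = EN\,\frac{1-\theta}{K_c\theta + 1 - \theta}, \qquad
EN_c = EN - EN_{uc}.$$

Computing $EN_c$ by difference makes the conservation
$EN_{uc} + EN_c = EN$ exact in floating point.

**Rate law.** The macroscopic rate is
$dP/dt = k_{cat,uc} EN_{uc} + k_{cat,c} EN_c = k_{app}(\theta)\, EN$
with

$$k_{app}(\theta) = k_{cat,uc}\,
\frac{1 - \theta + c\,K_c\,\theta}{K_c\theta + 1 - \theta},
\qquad c = \frac{k_{cat,c}}{k_{cat,uc}}.$$

$k_{app}$ interpolates from $k_{cat,uc}$ at $\theta = 0$ to
$k_{cat,c}$ at $\theta = 1$, and is strictly decreasing in $\theta$
whenever $c < 1$; $K_c$ sets how early the decay bites. The ratio $c$
is always derived, never an independent parameter. At $K_c = 1$ and
$k_{cat,c} \to 0$ the law collapses to the classical
adjacent-free-site depolymerase model,
$dP/dt = k_{cat,uc}\,EN\,(1-\theta)$
(`mukai_limit_rate()` evaluates this limit analytically, since a
strictly zero rate constant is outside the parameter domain).

The comparison inverse Michaelis–Menten law is taken as
$rate = k_{inv}\,\Gamma_{inv}\,N_0\,E_T/(K_{inv} + E_T)$ — an
enzyme-saturating hyperbola scaled by available surface, with three
free parameters. The literature this model comes from does not print a
single canonical parameterization; fixing this form makes the BIC
penalty ($k = 3$ vs $k = 5$) well defined.

```{r forward}
wt <- petase_params("WT", "30C")
head(degradation_rate(wt, E_T = c(25, 100, 400), N_0 = 500))
```

## Two-step estimation

The five parameters $(K_a, \Gamma, K_c, k_{cat,uc}, k_{cat,c})$ are
not comfortably identifiable from a rate surface alone: adsorption
strength and catalytic constants trade off. The workflow therefore
mirrors how the experiments are actually done:

1. **Adsorption step** (`fit_adsorption()`): $(K_a, \Gamma)$ are fit
   to a solution-depletion isotherm by minimizing
   $(y-\tilde y(\theta))^\top V_\epsilon^{-1}(y-\tilde y(\theta))$
   in the log space of the parameters.
2. **Kinetic step** (`fit_kinetics()`): all five parameters are fit to
   the rate table by minimizing the same weighted SSR *plus* the prior
   quadratic $(\theta-\mu)^\top V_\mu^{-1}(\theta-\mu)$, where $\mu$
   and $V_\mu$ are the step-1 log-space estimates and their
   Gauss–Newton covariance (`as_prior()`). Parameters fit for the
   first time carry no prior cost. The chaining is composable: a
   third stage (say, a per-temperature refit) can consume the step-2
   result the same way.

Design choices the data sources leave open, resolved here:

* **$V_\epsilon$** is diagonal with entries equal to the replicate
  variances of each mean (sd²/n), floored at (1% of the largest
  observation)² so zero-variance replicates cannot dominate.
* **$V_\mu$** is the log-space Gauss–Newton covariance
  $(J^\top V_\epsilon^{-1} J)^{-1}$ of the step-1 fit.
* **Positivity and ordering.** All parameters are optimized as logs.
  The constraint $k_{cat,c} \le k_{cat,uc}$ is enforced by
  reparameterizing $k_{cat,c} = c\,k_{cat,uc}$ with $c$ on a logit
  scale, so the box-constrained optimizer never sees an infeasible
  point.
* **Adsorption capacity as an upper bound for $\Gamma$.** The kinetic
  step hard-bounds $\Gamma$ at the step-1 estimate inflated by twice
  its relative standard error. A fit pinned at this bound is flagged
  (`gamma-at-capacity`).
* **Multi-start.** Starting points are sampled log-uniformly in boxes
  bracketing plausible values by at least an order of magnitude
  ($K_a \in [10^{-5}, 1]$ 1/nM, $\Gamma \in [10^{-4}, 10]$ nmol/cm²,
  $K_c \in [10^{-3}, 10^3]$, $k_{cat,uc} \in [10^{-3}, 10^2]$), each
  start refined with bounded L-BFGS. The default of 64 starts finds
  the optimum reliably on grids of this size (the objective is smooth
  with a single dominant basin); an exhaustive profile is available by
  raising `n_starts` (e.g. to 2000). The fraction of starts ending
  within 1% of the best objective is reported as a basin diagnostic.
* **Degenerate designs.** A single-$N_0$ rate table is accepted;
  $K_a$ and $\Gamma$ then lean almost entirely on the prior, which is
  the documented limitation of such designs, and plateau-only
  adsorption data flag $K_a$ as weakly identified instead of failing.

Uncertainty is reported two ways: Wald intervals from the log-space
Gauss–Newton covariance at the optimum (always), and seeded residual
bootstrap percentile intervals (`bootstrap_ci()`) on request. The
bootstrap refits warm-start from the original optimum, which keeps
200 replicates affordable.

Model comparison uses the Gaussian-likelihood BIC convention
$n\ln(SSR/n) + k\ln n$ on the *weighted* SSR with the same
$V_\epsilon$ for both models (`compare_models()`), so the comparison
is apples-to-apples.

```{r fit, eval = FALSE}
ads <- generate_adsorption(wt, cv = 0.05, seed = 1)
prior <- as_prior(fit_adsorption(ads, N_0 = attr(ads, "N_0"), seed = 1))
kin <- generate_kinetics(sim_config(wt, cv = 0.05), seed = 2)
fit <- fit_kinetics(kin, prior, seed = 1)
fit
```

## Sensitivity analysis and the productivity optimum

`normalized_sensitivity()` computes
$s_{\theta_i} = \theta_i\,\partial(dP/dt)/\partial\theta_i$ — the
derivative with respect to $\ln \theta_i$ — by central differences
with a multiplicative step of $10^{-5}$, cross-checked at $10^{-4}$.
Differentiating on the log scale respects positivity and makes the
step size scale-free. The identity
$s_{k_{cat,uc}} + s_{k_{cat,c}} = dP/dt$ (the rate is degree-1
homogeneous in the two catalytic constants) is a built-in correctness
check. Sensitivities are conventionally evaluated at the enzyme
loading of maximum productivity (`optimal_loading()`: grid scan plus
golden-section refinement to 0.1 nM; monotone profiles return the
grid boundary with a flag rather than a spurious optimum). For all
four 30 °C reference parameter sets the ranking at the optimum is
$s_\Gamma > s_{k_{cat,uc}} > 0 > s_{K_c}$: more sites and faster
uncrowded catalysis help, stronger crowding hurts. Both raw
(units of rate) and rate-normalized sensitivities are reported, since
either normalization is defensible.

## Surface geometry

The crowding hypothesis rests on how closely packed adsorbed enzymes
actually are. The geometry module provides:

* `areal_density()` — adsorbed amount over film area (both faces) to
  molecules/nm²; 4 pmol on a 0.25-inch disc gives
  $\lambda \approx 0.038$ nm⁻².
* `grid_spacing()` = $1/\sqrt\lambda$ (even square lattice; the square
  convention reproduces the conventionally quoted ~5 nm for the
  density above, where a hexagonal convention would not) and
  `poisson_nn_mean()` = $1/(2\sqrt\lambda)$, the exact mean
  nearest-neighbor distance of a homogeneous planar Poisson process —
  the closed-form oracle for the Monte Carlo.
* `simulate_point_pattern()` / `mean_min_distance()` — seeded Poisson
  patterns and per-point nearest-neighbor distances. Toroidal
  (periodic) windows are the default for oracle-matching simulations
  because they remove edge bias; the bounded estimator — which is what
  one computes on real localization data, where no edge correction is
  applied — is biased high, and the tests quantify that the bias
  shrinks with window size. Pairwise distances are evaluated in blocks
  (`method = "blocked"`) so 10⁴-point patterns stay within modest
  memory; `method = "brute"` is the O(n²) reference path and returns
  identical values.
* `scale_density_linear()` — inverts the Poisson formula at a measured
  reference (400 nm mean NN at 200 pM) and scales density linearly
  with solution concentration, the sub-saturating assumption.
* `molar_to_spacing_3d()` / `spacing_to_molar_3d()` — cubic-lattice
  spacing for bulk crowding arithmetic (2 mM ↔ ≈ 9.4 nm).
* `tirf_quadrant_analysis()` — splits each circular field of view into
  four quadrants through its center (points exactly on an axis go to
  the lower-index quadrant), removes the blank-control count of
  coordinates uniformly at random per field (seeded), and summarizes
  counts and mean minimum distances over the eight quadrants. Blank
  subtraction is per-field; a per-quadrant variant would differ only
  in how the removals distribute, and per-field matches how blanks
  are measured.

## Synthetic data: what it emulates and what it does not

`generate_kinetics()`, `generate_adsorption()`,
`generate_timeseries()`, `generate_point_patterns()` and
`generate_calibration_curves()` produce every input class the
analysis consumes. Defaults encode the study conditions: enzyme grids
of 10–600 nM (30 °C) or 20–1500 nM (55 °C), film loadings of
200–1900 cm²/L (the standard film sizes, both faces, 1 ml), 3
replicates per cell, and truncated-Gaussian noise with 5% CV and an
absolute floor of 0.5% of the grid-maximum rate. The 5% CV is our
reading of typical replicate scatter in bulk-absorbance
depolymerization assays (exact magnitudes are not published); the
floor keeps weights finite near zero rates; truncation at zero rather
than lognormal noise is the simplest model consistent with
replicate-SD reporting. At `cv = 0` every generator returns the exact
model surface, which makes noiseless fits fixed-point tests of the
estimators.

What the generators deliberately do not emulate: substrate depletion
over time (initial rates only; $N_0$ constant), per-enzyme rate
heterogeneity beyond the two-state lump, non-random adsorbate
placement (attractive/exclusionary interactions), surface roughness,
and detection artifacts of real localization microscopy (finite
resolution, photobleaching). Passing recovery tests therefore show
that the estimation machinery is correct and well-conditioned under
the stated noise model — not that the SC model is true of any
particular real system.

## Numerical choices and degenerate inputs

* Adsorption root: stable two-root evaluation (above); tiny negative
  round-off (> −10⁻¹² · N_T) clamps to zero; `E_T = 0` returns 0
  exactly.
* `partition_adsorbed()` computes the crowded pool by difference:
  conservation exact; $\theta$ outside [0, 1] is an error, not a
  clamp.
* Weighted SSR refuses zero variances and points to the floor
  configuration instead of silently producing Inf.
* Gauss–Newton covariance falls back to a truncated-SVD pseudo-inverse
  when the Hessian is numerically singular (plateau-only designs), so
  weak identifiability surfaces as wide intervals and a flag rather
  than an error.
* All stochastic routines (generators, multi-start, bootstrap, point
  patterns, blank removal) take an explicit seed and restore the
  caller's RNG state; two runs from the same (config, seed) are
  byte-identical.

## Problem sizes used in the shipped checks

The package's own test battery runs parameter recovery at 10 seeds per
temperature regime (5% CV, 3 replicates, full grids; 12 random starts
per fit after verifying that start counts beyond ~10 do not change
the optimum on these problems), model discrimination at 20 seeds, and
Monte Carlo geometry at ~1.2 × 10⁴ points per pattern. These sizes
give medians and proportions stable enough for the tolerances asserted
while keeping a full run in a few minutes on one core; the acceptance
script (`scripts/acceptance.R`) uses the same 10⁴-point scale.

## Known limitations

* The individual transition rate constants behind $K_a$ and $K_c$ are
  not identifiable from equilibrium data and are deliberately not
  represented.
* No distinction is made between adsorption capacity and catalytic
  site density ($\Gamma_{ads}$ vs $\Gamma_{kin}$); nonspecific
  adsorption would bias $\Gamma$ upward.
* The error model is diagonal Gaussian; correlated or multiplicative
  error structures are out of scope.
* BIC comparison assumes both models are fit to the same weighted
  observations; it is not a goodness-of-fit test in absolute terms.
* The interface is function-first: the pipeline driver
  (`run_pipeline()`) plus the scripts directory is the intended
  command-line surface, rather than a standalone executable.
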