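---
title: "Models and methods behind osteokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osteokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteokin)
```

osteokin describes the kinetics of osteosarcoma cell lines with three
deliberately minimal models — a power law for in vivo tumor volume, a
logistic law for in vitro confluence, and a point-source reaction–diffusion
solution for spatial spread. Each model has one or two parameters, so all of
them can be estimated from the modest time series a cell-line characterization
study produces. This vignette explains the models, their assumptions, the
numerical choices made in the implementation, and what the synthetic-data
generator does and does not emulate.

## Power-law tumor growth

Tumor volume $V(t)$ (mm³) in immunosuppressed mice is modelled by the
allometric law

$$\frac{dV}{dt} = \alpha V^\beta, \qquad V(t_0) = V_0,$$

whose solution for $\beta \neq 1$ is

$$V(t) = \left[V_0^{1-\beta} + \alpha(1-\beta)(t - t_0)\right]^{1/(1-\beta)}.$$

The growth rate $\alpha$ (units mm$^{3(1-\beta)}$/day) ranks lines by how
fast their tumors grow; the scale exponent $\beta$ links growth to the
tumor's metabolic supply geometry. For $\beta < 1$ growth is sublinear and
finite for all time; for $\beta > 1$ the solution blows up at
$T^* = t_0 + V_0^{1-\beta}/(\alpha(\beta-1))$, and `power_law_solution()`
reports that time in its error when asked to step past it.

Fitting conventions, chosen once and applied everywhere:

* $t_0 = 0$, $V_0 = 0$: the tumor is vanishingly small but nonzero at
  injection, so $V(t) = [\alpha(1-\beta)t]^{1/(1-\beta)}$. Because
  $\alpha$'s units depend on $\beta$, fitted $\alpha$ values are comparable
  across lines only under this common (mm³, day) convention.
* Unconstrained Levenberg–Marquardt least squares (via `minpack.lm::nlsLM`)
  started at $(\alpha, \beta) = (0.9, 0.9)$. The $\beta = 1$ singularity of
  the closed form is removable (the exponential limit), but the model domain
  excludes it: iterates entering $|\beta - 1| < 10^{-6}$ are nudged away by
  $10^{-4}$ and the fit continues.
* Fits ending with $\alpha \le 0$ or $\beta \notin (0, 1.5)$ are flagged
  `converged = FALSE` rather than reported silently; $R^2$ uses the standard
  total sum of squares about the mean of the observations.

Lines are ranked into growth tiers by $\alpha$ with inclusive lower bounds —
High $\ge 0.80$, Medium high $\ge 0.30$, Medium $\ge 0.15$, Low below. These
breakpoints are not physical constants: they separate the published tier
groupings of the 17-line reference panel and are exposed in `fit_config()`.
Each fitted $\beta$ is also assigned to the nearest of the classical
allometric exponents $\{2/3, 3/4, 5/6\}$ (ties toward the smaller value),
the clusters the reference panel's exponents gather around.

## Logistic proliferation

Confluence $N(t)$ (percent of culture surface covered) follows

$$\frac{dN}{dt} = \rho N\left(1 - \frac{N}{k}\right), \qquad
N(t) = \frac{k N_0 e^{\rho t}}{k + N_0(e^{\rho t} - 1)},$$

with the carrying capacity fixed at $k = 100$ percent. Confluence is
recorded hourly but $\rho$ is reported per day, so hour grids are divided by
24 at ingest — one convention for both the in vivo and in vitro clocks.

Each (cell line, seeding condition) pair is fit independently; the two
conditions genuinely differ (the reference panel even contains a line whose
5 % rate exceeds its 10 % rate), plausibly through passage-number effects.
Design choices:

* $N_0$ is fixed at the nominal seeding density (5 or 10 percent) by
  default. The alternative of estimating $N_0$ jointly is available via
  `fit_config(fit_N0 = TRUE)`, since observed first points can sit off
  nominal.
* Replicates are pooled into a single residual vector per condition rather
  than fitted separately and averaged: pooling uses every observation, is
  invariant to replicate order, and matches reporting a single rate with a
  replicate count $n$ per condition.
* The two conditions are combined by the replicate-weighted average
  $\bar\rho = (\rho_5 n_5 + \rho_{10} n_{10})/(n_5 + n_{10})$, the rate used
  by the diffusion stage. Proliferation tiers use inclusive bounds
  High $\ge 1.70$, Medium high $\ge 1.49$, Medium $\ge 1.20$ — again
  reverse-engineered from the reference groupings and configurable.

## Point-source diffusion

Spatial spread is modelled by the linearized Fisher–Kolmogorov equation with
a Dirac initial condition of $C_0$ cells at the injection point:

$$u_t = D\,\Delta u + \rho u, \qquad u|_{t=0} = C_0\,\delta(x),$$

whose radial solution is the exponentially growing Gaussian

$$u(r,t) = \frac{C_0}{8(\pi D t)^{3/2}}
\exp\!\left[\rho t - \frac{r^2}{4Dt}\right].$$

A tumor is observed where the density exceeds a detection threshold $u_*$;
the detectable radius satisfies

$$r_*^2 = 4D\rho t^2 - 4Dt\,
\ln\!\left(\frac{8u_*}{C_0}(\pi D t)^{3/2}\right)
\;\approx\; 4 D \rho t^2 \quad \text{for large } t,$$

so the radius grows asymptotically at the Fisher–Kolmogorov front speed
$v = 2\sqrt{D\rho}$, linearly in time. Because $u_*$ and $C_0$ are unknown
in practice, the estimator inverts the asymptotic law at each observation:

$$D_i = \frac{r_i^2}{4 \rho t_i^2},$$

where $r_i$ comes from the observed volume under the spherical-growth
assumption ($r = (3V/4\pi)^{1/3}$) and $\rho$ is the line's
replicate-weighted in vitro rate. The summary $\bar D$ is the mean of the
per-timepoint estimates — not the slope-derived value — because the
accompanying sd and CV only make sense for a collection of per-timepoint
estimates; the slope route ($D = \text{slope}^2/4\rho$ from
`fit_radius_linear()`) is kept as a cross-check. The sd is the sample
(n−1) deviation. Timepoints at $t = 0$ are excluded (the law divides by
$t^2$; experimental windows all start after injection, and time is absolute
from the injection day).

The neglected logarithmic term gives the estimator a known, closed-form
relative error $|\ln(8 (u_*/C_0) (\pi D t)^{3/2})|/(\rho t)$, which decays
in $t$; the test suite verifies the per-timepoint estimates against this
expression exactly. When the radius trajectory really is linear the
per-timepoint estimates are constant, so the coefficient of variation
$\mathrm{CV} = \mathrm{sd}/\bar D$ measures how well the front law holds:
$\mathrm{CV} < 50\%$ is the validity rule, with the cutoff exposed in
`fit_config()`. Diffusivity tiers (High $\ge 8\times10^{-3}$, Medium high
$\ge 10^{-3}$, Medium $\ge 3\times10^{-4}$ mm²/day) mirror the reference
grouping boundaries. The detection ratio $u_*/C_0$ (default $10^{-3}$) is
needed only to synthesize exact-law radii and to analyze the estimator's
error; the estimator itself never uses it.

## Panel association

`build_panel()` joins the fitted $\alpha$, $\beta$, $\bar\rho$ and $\bar D$
with experimental phenotype levels — tumorigenicity (TL), colony-forming
ability (CL), invasion (IL), migration (ML), proliferation (PL) — keeping
only lines with every characteristic available (listwise deletion; dropped
lines are logged). `correlation_matrix()` computes Pearson correlations on
the raw values by default, treating the ordinal levels as numeric scores as
printed; Spearman is available for a rank-based view, which is also the
statistic the test suite uses for generator invariants on the ordinal TL
scale, where rank correlation is the meaningful measure of monotone
association.

## The synthetic-data generator

`simulate_panel()` exists so that every downstream stage can be tested
against known ground truth. Its defaults emulate the reference study's
conditions:

* `reference_ground_truth()` parameterizes the 17 fully characterized lines
  with their published $\alpha \in [0.08, 2.18]$,
  $\beta \in (0.53, 0.88)$, condition-specific rates, replicate counts
  ($n_5 \in 2..8$, $n_{10} \in 2..4$) and diffusivities
  ($5\times10^{-5}$ to $1.2\times10^{-2}$ mm²/day).
* In vivo grids use 12 observations per line starting at each line's first
  experimental day (tumor appearance, 3–23 days across tiers) and extend
  longer for slower lines, up to the study's 172-day horizon; in vitro
  sampling is every 4 h over 5 days.
* Noise: multiplicative lognormal on volumes (default
  $\sigma_V = 0.05$) and additive Gaussian on confluence (default
  $\sigma_N = 2$ percentage points, clipped to $[0.1, 100]$ — the floor
  prevents zero or negative confluence). The source curves publish no noise
  model, so these are the minimal structures respecting positivity and the
  percent bounds; the magnitudes are calibration choices that reproduce the
  published fits' $R^2 > 0.9$ scale, not measured values.
* Phenotype levels are ordinal 1–4 scores assigned by parameter quartile
  (TL from $\alpha$, PL from $\bar\rho$) with a 10 % chance of a ±1 jitter,
  plus count-like CL/IL/ML scores monotone in $\alpha$ — enough structure
  for the association stage to have signal, no more.

Everything is bit-reproducible under a fixed seed, and the generator uses a
private RNG stream so it never disturbs the caller's random state.

What the generator does **not** emulate: digitization error of extracted
curves, inter-animal variability, necrotic cores, immune interaction,
vascularization, or any spatial heterogeneity of $D$. One structural gap is
worth stressing: synthetic radii derived from power-law volumes grow like
$t^{1/(3(1-\beta))}$, which is linear only at $\beta = 2/3$, so a noisy
synthetic panel legitimately fails the CV validity rule for many lines with
$\beta$ near $5/6$. Passing recovery tests on synthetic data therefore shows
the estimators invert their own models correctly — it does not by itself
validate those models against real tumors, which is exactly what the CV rule
is for.

## Numerical choices and degenerate inputs

* Fits run to `ftol` $10^{-10}$ with at most 200 LM iterations; failures
  are caught per line, logged, and excluded — one bad line never aborts a
  pipeline run.
* Growth fits require ≥ 3 points and ≥ 2 distinct positive volumes;
  logistic fits require ≥ 3 points and reject constant series; diffusion
  summaries require ≥ 2 positive-time points (the sd is undefined below
  that).
* Rates are reported at full precision in machine outputs and rounded (4
  decimals for tables, 2 for rates) only in report mode, mirroring the
  published tables' presentation.
* Problem sizes used by the test suite — 200-replicate recovery studies, a
  17-line end-to-end panel, an 800-node Crank–Nicolson PDE oracle — were
  chosen as the smallest sizes at which the medians and discretization
  errors stabilize.

## Known limitations

The diffusion estimator inherits every assumption of the point-source
linearization: constant $D$ and $\rho$, exponential (not saturating) local
growth, spherical symmetry, and an in vitro rate standing in for the in
vivo one. The recomputed arithmetic of the reference tables carries the
rounding of their printed operands (rates at 2 decimals, diffusion values at
3 significant figures), so recomputed weighted averages can differ from the
printed column by up to 0.01 and recomputed CVs by up to one percentage
point — the tolerances the acceptance checks use. Tier breakpoints are
descriptive groupings of one panel, not biological thresholds.
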