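---
title: "Modelling the movement and geometry of newly formed prion foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the movement and geometry of newly formed prion foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionfoci)
```

`prionfoci` analyses 3D time-lapse trajectories of newly formed Sup35NM
prion foci in yeast cells. This vignette explains the models and
procedures it implements, the parameters that matter, what the built-in
simulator does and does not emulate, and the numerical and design choices
behind the implementation.

## The data

The raw material is manual tracking output: for each focus, a table of x,
y, z coordinates (µm) per frame, typically recorded every 10 s over
roughly 16 min (100 frames), plus membrane measurements per cell (edge
coordinates and/or diameters), per-cell aggregate counts, and colony
counts from plating assays. Frames are 0-based; a focus that becomes
visible mid-movie simply has no rows before its first frame, and those
missing frames are treated as explicit gaps — never as zero coordinates.
Every downstream quantity (displacements, rolling averages, model fits)
is computed within gap-free segments only, so a dropout never fabricates
a spurious jump.

When the axial coordinate comes from a z-stack index, the per-movie step
size (commonly 0.28–0.6 µm) must be applied by the caller via the
reader's `z_scale` argument, since it varies between acquisitions.

## Kinematics

Per-interval speed is the 3D Euclidean displacement divided by the time
difference (µm/s). Because single 10 s intervals are noisy, speeds are
smoothed with a simple moving average (SMA) over three successive
intervals — a 30 s rolling window with stride 1 — and the overall trend
of the SMA series is summarised by an ordinary least-squares line of SMA
speed against time. A negative slope describes a slowing (maturing)
focus; a slope near zero a focus at steady mobility. Each SMA value is
stamped with the mid-time of its window, which keeps the trend's slope
units honest (µm/s per s) without shifting the fitted sign.

Run lengths — net distances travelled per frame interval — are pooled
across foci into contiguous histograms from 0 in 200 nm bins. At 10 s
sampling the "distance per frame" and "run length in 10 s" coincide, so
one quantity serves both descriptions; 200 nm matches the resolution at
which run-length ranges for mobile (roughly 200–1000 nm per 10 s) and
impaired (0–600 nm) foci separate.

## The movement model

To ask whether a focus moves randomly or directedly, each trajectory is
fitted with a correlated-random-walk model borrowed from animal-movement
ecology:

$$y_{t+1} = y_t + \gamma\,T(\theta)\,d_{t-1} + \Sigma,$$

with $d_{t-1}$ the previous displacement vector, $\gamma$ the directional
correlation, $T(\theta)$ a rotation by the mean turn angle, and $\Sigma$
the random-walk displacement. The implementation makes three deliberate
simplifications:

1. **The rotation is fixed to the identity.** The source model is 2D; in
   3D a single mean turn angle does not determine a rotation (the axis is
   unspecified), so estimating $T$ is ill-posed. Systematic turning is
   absorbed into the residual, and the mean 3D turn angle
   ($\arccos$ of the normalised dot product of consecutive displacement
   vectors, in $[0, \pi]$) is reported descriptively instead.
2. **A single behavioural state.** No hidden-state switching; the state
   subscript of the ecology model is dropped.
3. **$\Sigma$ is a scalar.** It is reported as the per-axis standard
   deviation of the residual step, µm/step, assuming isotropic residuals:
   the root-mean-square residual norm divided by $\sqrt{3}$.

$\gamma$ is estimated by conditional least squares: stack the x, y, z
components of each displacement $d_t$ against those of $d_{t-1}$ and
regress without intercept, giving the closed form
$\hat\gamma = \sum d_t \cdot d_{t-1} \,/\, \sum |d_{t-1}|^2$. This is
exact, assumption-light, and coincides with maximum likelihood under
isotropic Gaussian residuals. The test suite checks the fit against an
independently coded sum-formula oracle to 1e−9, and checks parameter
recovery on simulated walks (γ ∈ {0, 0.3, 0.6, 0.9}, σ ∈ {0.05, 0.2}
µm, 500 steps, 20 replicates: mean absolute error of γ below 0.05, σ
within 10 % relative).

Two limits pin down the interpretation: a constant-step (ballistic)
trajectory yields exactly γ = 1 and Σ = 0, and a pure random walk yields
γ near 0. Foci with γ below the classification threshold (default 0.5,
strict-below; the value 0.5 itself classifies as directed) are labelled
random movers. Mobile early foci characteristically fit well below 0.4.

Two biases are documented rather than corrected. Confinement: with a
reflecting boundary at a radius comparable to the step length, the fitted
γ is biased negative relative to the generating value, because the wall
anti-correlates successive steps; a direction-only property test
demonstrates this. Axial anisotropy: coarser z-sampling is not corrected,
only flagged when the recorded axial extent exceeds the lateral.

## Cell geometry and periphery mapping

Focus and cell volumes use the ellipsoid formula $V = \frac{4}{3}\pi a b
c$ with $a, b, c$ the semi-axes. Measured lengths are full extents along
x, y, z, so they are halved first — the only dimensionally conventional
reading (a 2 µm-diameter sphere must come out at $4\pi/3$ µm³, not
$32\pi/3$).

Each cell is reduced to a *conceptual sphere*. With at least six membrane
edge points the sphere is fitted algebraically (the containment condition
$|p - c|^2 = R^2$ is linear in the centre and in $R^2 - |c|^2$, so a
least-squares solve gives centre and radius directly; exact spheres are
reproduced to 1e−9 and noisy ones agree with a numerical
residual-minimisation oracle). With only diameters, $R$ is half the mean
diameter and the centre is the centroid of any edge points — the centroid
convention is this package's choice, since the measurement protocol does
not dictate one.

An aggregate at radial distance $r$ from the centre maps to the relative
periphery distance $(R - r)/(2R)$, clipped to $[0, 0.5]$: 0.0 *is* the
periphery and 0.5 *is* the centre, by definition. Manual membrane
coordinates inevitably place some aggregates slightly outside the fitted
sphere ($r > R$); these clip to 0 with a warning rather than triggering a
refit, consistent with "0 = periphery".

## The simulator

The generators produce every input the pipeline reads, with known ground
truth:

- **Trajectories** run the movement model generatively: $d_t =
  \gamma_{\text{true}} d_{t-1} + \varepsilon_t$ with isotropic Gaussian
  innovations (per-axis sd $\sigma_{\text{true}}$), the first step drawn
  from the stationary distribution. $\gamma_{\text{true}} \ge 1$ is
  rejected as nonstationary; ballistic fixtures are built analytically
  instead. Confinement folds positions radially back inside the cell
  sphere ($|p| \to 2R - |p|$), the standard reflecting scheme for
  sphere-confined diffusion; the realised post-fold displacement feeds
  the next step. Focus growth is linear in volume, and mobility may be
  supplied as a function of current volume to emulate the
  small-mobile/large-static dichotomy.
- **Membrane edges** sit at quasi-uniform directions (Fibonacci lattice)
  at the true radius plus Gaussian radial noise.
- **Aggregate positions** draw the radial coordinate with density
  $\propto r^{2+b}$ on $[0, R]$: bias $b = 0$ is uniform in the cell
  volume (mean relative periphery distance exactly $0.125$, since
  $E[r] = 3R/4$ — used as a closed-form test anchor), larger $b$ pushes
  aggregates toward the membrane.
- **Colony counts** are binomial: each of the $\text{CFU} \times
  \text{density factor}$ cells plated selectively forms a colony with the
  true induction probability.

Strain presets fix the study conditions the package is exercised under:
`wildtype` has one focus in each of 5 cells with a free-space mean step
of ~0.75 µm per 10 s; `act1-122` has 11 foci across 6 cells at ~0.55 µm
per 10 s, mixing small mobile, large static, and intermediate foci, with
correspondingly more aggregates per cell (≈88 % vs ≈45 % single-aggregate
cells) and a ~1.7-fold lower induction frequency around a wildtype value
of 0.006. Innovation scales are derived from the target step length via
the mean of a 3D Gaussian step, $E|d| = 2\sqrt{2/\pi}\,\sigma$; inside a
2.6 µm-radius cell the reflecting boundary shortens realised steps
somewhat, so observed mean speeds land below the free-space target — a
property of confinement, not an error. Cell radius defaults to 2.6 µm, a
typical haploid yeast cell.

What the simulator does **not** emulate: localisation error and
photobleaching, anisotropic (z-coarse) sampling, cell shape beyond a
sphere (no buds), multi-state behavioural switching, and any mechanistic
aggregation kinetics. Passing recovery tests therefore show that the
estimators are correct for the model class, not that real microscopy data
satisfy the model.

## Statistics

Result-level computations are thin, conventional layers: OLS regressions
of γ or Σ on focus volume (or focus:cell volume ratio) with two-sided
slope tests; per-strain percent-single-aggregate summaries; Welch's t
(default), paired t, and Kolmogorov–Smirnov two-group comparisons
delegated to `stats`; induction frequency as colonies / (CFU × density
factor) with fold changes as ratios of group means. p-values are reported
unadjusted — matching how pairwise tests are customarily reported for
this kind of small-panel strain comparison — with a Holm helper
(`adjust_p_values()`) available. Because occasional platings can show
frequencies far above their group's typical value, the fold-change helper
exposes mean (default) and median averaging.

## Numerical choices and degenerate inputs

- Model fits require ≥ 4 consecutive frames; all-zero displacement series
  raise an "undefined" error rather than returning γ = 0.
- Exactly collinear/antiparallel steps are clamped into $[-1, 1]$ before
  `acos`, so turn angles are always defined.
- The paired t-test refuses zero within-pair variance; the KS test is
  used when the question is about spread rather than location.
- The problem sizes in the test suite (500-step recovery walks, 20
  replicates per grid cell, 100-frame pipeline trajectories, 20 000-point
  Monte-Carlo checks of closed forms) were chosen so the whole suite
  exercises every estimator at tight tolerances while remaining quick to
  run on a laptop.

## Known limitations

γ and Σ estimates on confined, growing, real foci inherit the biases
described above; absolute per-focus values should be compared only within
matched acquisition conditions. The sphere model ignores budding; the
periphery mapping of aggregates in budded cells is only as good as the
conceptual-sphere approximation of the mother compartment. The CLS
estimator is this package's choice of algorithm for the movement model —
other estimation schemes (e.g. state-space likelihoods) would give
numerically different per-focus values while agreeing in the regimes the
tests pin down.
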