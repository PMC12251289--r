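---
title: "Uncertainty-aware traction force microscopy with tfmuq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware traction force microscopy with tfmuq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Traction force microscopy (TFM) infers the stresses a cell exerts on an
elastic substrate from the displacement of fluorescent beads embedded in
it.  The inversion is ill-posed: high-frequency measurement noise is
amplified, so every practical TFM pipeline regularizes, and the amount of
regularization silently controls both the magnitude and the effective
resolution of the recovered stresses.  `tfmuq` implements an
uncertainty-aware pipeline: the particle image velocimetry (PIV) step
reports a per-window measurement variance obtained by a non-parametric
pixel bootstrap, and a hierarchical Bayesian inversion propagates that
spatially varying variance into pointwise traction magnitude and direction
error maps, choosing its own regularization level from the data.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Deformation measurement and its uncertainty

### PIV

Displacements are measured by single-pass FFT cross-correlation on square
interrogation windows of side `WL` pixels spaced `WS = WL/2` (the usual
Nyquist trade-off).  Windows are mean-subtracted and correlated
circularly; the integer peak is refined per axis with the standard
3-point Gaussian estimator.  The sign convention maps reference
coordinates to session coordinates.  Single-pass correlation carries the
well-known loss-of-pairs bias of order `u/WL` of the shift; the
uncertainty machinery treats the PIV evaluation as a black box, so an
iterative or window-deformation scheme can be substituted without touching
anything else.

### Bootstrap uncertainty (PIV-UQ)

For each window, `n^2` pixel indices are drawn uniformly with
replacement and the unsampled pixels are blacked out, so each bootstrap
replicate asks which pixels the correlation peak actually relies on.
Repeating this `n_B` times yields an
empirical distribution of displacement draws per window.  The draws are
screened with DBSCAN (`eps = WS/5`, `minPts = ceiling(n_B/10)`): points
outside any cluster are outliers, and a window is invalidated when no
cluster exists or when two clusters are separated by at least 20% of the
window spacing (multi-modality, typically caused by motions that are far
from a pure translation or by featureless content).  Valid windows report
the componentwise standard deviation over the largest cluster and the
circular standard deviation `sqrt(-2 ln Rbar)` of the draw directions;
invalidated windows get their displacement from an iterated 3x3 median
fill and a variance of `bad_sigma_factor` (default 5) times the largest
valid sigma.

Two perturbation variants are exposed because the choice matters, and in
both cases the defaults were settled by checking which variant reproduces
the method's validated behaviour on synthetic ensembles (bootstrap sigma
tracking the true ensemble sigma increasingly well as noise grows, with a
finite floor, and RMS sigma decreasing with SNR and window size):

* `weight_mode = "mask"` (default): sampled pixels keep their value,
  unsampled pixels go black.  The `"counts"` variant additionally
  multiplies intensities by the bootstrap multiplicity; when the same
  multiset is applied to both windows this doubles the expected weight of
  aligned (zero-lag) pixel products relative to any other lag, and
  whenever the true displacement is within a few bead widths — the
  typical TFM regime — the spurious zero-lag peak captures every draw.
  We verified this on dense bead windows where nominal PIV finds the
  correct peak while every paired counts-mode draw sits at zero lag.
* `paired = FALSE` (default): each window is resampled independently.
  Applying one shared multiset to both windows (`paired = TRUE`) perturbs
  only the correlation functional, which is conceptually attractive, but
  the shared sparsity pattern self-correlates at zero lag: on windows
  whose content is dominated by a bright background (including heavily
  noise-clipped images) all draws collapse onto the artifact peak and the
  reported uncertainty is suppressed exactly where it should be largest.
  Independent resampling also perturbs the scene, which contributes to
  the uncertainty floor, but it preserves the tracking and monotonicity
  behaviours across noise levels; pairing is kept for sensitivity checks.

The *floor* — a nonzero reported sigma even on effectively noiseless
images — arises because masking beads out of a sparse window genuinely
changes the information available to the subpixel estimator.  Convergence
of sigma with `n_B` is monitored by the coefficient of variation across
repeated bootstrap runs (`cov_convergence()`); noisier images need larger
`n_B`.

## Elastostatic model

The substrate is a flat, inertia-less, linearly elastic layer of Young's
modulus `E`, Poisson ratio `nu` and thickness `h`, bonded at its base and
loaded by in-plane tractions at the free surface where the normal stress
vanishes.  Per wavenumber `k` the surface displacement responds to the
surface traction through a 2x2 block `g1 I + g2 k kT` whose transverse and
longitudinal compliances are

```
gT = tanh(kh) / (mu k),
gL = (1 - nu) [ (3 - 4 nu) sinh(kh) cosh(kh) + kh ] /
     ( mu k [ (kh)^2 + 4 (1 - nu)^2 + (3 - 4 nu) sinh(kh)^2 ] ),
```

with `mu = E / (2 (1 + nu))`.  We re-derived `gL` from the plane-strain
layer boundary-value problem symbolically; the published closed forms of
the longitudinal part are frequently typeset inconsistently, so the
implementation's correctness contract is the two analytic limits, which
the test suite checks to 0.1%: both compliances tend to `h/mu` as
`kh -> 0` (pure shear) and to the Boussinesq half-space kernel
(`g1 = 2(1+nu)/(Ek)`, `g2 = -2 nu (1+nu)/(E k^3)`) for `kh >= 20`.
Hyperbolic terms are evaluated in exponentially rescaled form so no
overflow occurs at large `kh`.  The incompressible limit `nu = 0.5` is
rejected (plane-strain factors degenerate).

The discrete operator uses periodic boundary conditions on the PIV grid.
For even grids the Nyquist line aliases `+k` and `-k`, so the odd coupling
`g2 kx ky` cannot be represented there and is set to zero — this is what
makes the dense real-space operator exactly real and symmetric.  The dense
`2 Nw x 2 Nw` matrix is assembled from the impulse response of each
circulant block and is verified against FFT application to `1e-10`
relative error.  Dense assembly is guarded at about 4000 windows; beyond
that a coarser PIV grid should be used.

## Hierarchical Bayesian inversion

Observed displacements (stacked `ux` then `uy`, micrometres) are modelled
as `uh = M t + e_beta + e_m` with `e_beta ~ N(0, beta^-1 I)` a global
model error and `e_m ~ N(0, Sigma_PIV)` the measured per-window PIV
variances (converted from px^2 with the pixel size).  The smoothness prior
on `t` uses the discrete Laplacian `L` (5-point stencil, mirror
boundaries, applied per component) with precision `alpha L'L`: the
quadratic form is implemented as `|Lt|^2`, which makes the Gamma
conditional for `alpha` exact and the prior proper on the non-constant
subspace; a raw `t'Lt` reading is indefinite and would break the Gamma
update, so `L'L` is the default and the identity regularizer is available
as a variant.  Both hyperparameters carry non-informative Gamma
hyperpriors (shape 1, rate 1e-5).

The posterior is explored with a hybrid Gibbs sampler:

* `t | alpha, beta`: exact Gaussian, precision
  `M' Lambda^-1 M + alpha L'L` with `Lambda = beta^-1 I + Sigma_PIV`
  diagonal; sampled via Cholesky of the precision.
* `alpha | t`: `Gamma(Nw + theta, |Lt|^2/2 + phi)`, exact.
* `beta | t`: no closed form when `Sigma_PIV` varies, so the conditional is
  evaluated on a log-spaced grid (coarse bracket, then 400 points spanning
  4 decades around the maximum, widened once if mass reaches the edges),
  normalised by the trapezoid rule and sampled by inverting the numerical
  CDF.  The `Sigma_PIV = 0` special case reduces to a Gamma and the
  numerical sampler is tested against its analytic moments.

Defaults are 300 draws with a burn-in of 50.  Initial values follow
`beta0 = 1/median(Sigma_PIV)` (or `1/var(uh)` when no variance is
available) and `alpha0 = lambda0 beta0` with `lambda0` the Tikhonov
L-curve corner, so the chain starts near the classical solution.  The
sampler core is compiled (RcppArmadillo) because each draw requires a
dense Cholesky at `2 Nw ~ 2000`; it consumes R's RNG stream, so runs are
reproducible under `set.seed()`.  Summaries are the posterior mean, the
componentwise and total standard deviation `sigma_t`, and the circular
standard deviation of the draw directions per point; hyperparameter chains
are kept for trace/autocorrelation diagnostics
(`effective_sample_size()`).

Clamping both hyperparameters with `Sigma_PIV = 0` reproduces the
Tikhonov solution with `lambda = alpha/beta` to `1e-8` relative — the
bridge between the Bayesian and classical formulations that the test suite
checks.  With `L = U`, `Sigma_PIV = 0` and `kh << 1`, the posterior
variance per point is `1/(beta h^2/mu^2 + alpha)`, interpolating between
the weak-regularization bound `beta^-1 mu^2/h^2` and the
strong-regularization bound `alpha^-1`; this is why the uncertainty map
saturates instead of falling to zero in clean image regions.  A
heteroskedastic prior variant (`heteroskedastic_prior()`) scales the prior
precision by `Sigma_PIV^-1` (symmetrised), making both bounds track the
local measurement noise at the cost of weaker regularization in noisy
areas.

## Tikhonov baseline and the L-curve

The classical baseline solves
`argmin |uh - M t|^2 + lambda |Lt|^2` via the SPD normal equations, with
Laplacian or identity regularizer.  `lambda` is selected at the corner of
the L-curve (log residual vs log seminorm over a 40-point, 8-decade grid):
curvature is computed from a smoothing-spline parameterization in
log-lambda, and among pronounced curvature maxima (at least 30% of the
global maximum) the lowest-lambda one is taken, because curves from data
with visible structure often carry a second bend at the signal scale.
Grid-edge points are excluded.  When the curve is degenerate (no corner)
the grid midpoint is returned with a warning.  On very clean data the
L-curve criterion itself becomes uninformative — the seminorm is
signal-dominated at every lambda and the "corner" no longer tracks the
noise level; this is a known limitation of the criterion, not of the
implementation, and it shapes the synthetic comparison below.
`match_percentile_lambda()` reproduces the protocol of pairing
identity-regularized maps with Laplacian ones by matching the 95th
percentile of the traction magnitude (bisection; the percentile is
monotone in lambda).

A property worth knowing: with the Laplacian prior the area integral of
the recovered traction is invariant to the regularization weight (the
stencil annihilates constants and the elastostatic operator is circulant),
so total force is conserved while patterns spread; identity regularization
does not have this property.

## Synthetic benchmark

`build_benchmark()` reproduces the heteroskedastic validation design:
four Gaussian traction islands (peak 500 Pa, width 15 um, one per
quadrant, pointing at the vertical midline) on a substrate with
`E = 5 kPa`, `nu = 0.45`; the displacement field is forward-solved on a
fine periodic grid (256^2 by default) and beads are displaced by bilinear
interpolation of that field at their positions, rendered as Gaussian
profiles (sigma 1.5 px, saturation 1000 a.u.), with additive Gaussian
pixel noise at SNR = 50 dB (`sigma_px = 1000 * 10^(-SNR/20)`) and a linear
bead-density ramp from 8e-3 (left) to 8e-4 (right) beads/px^2 on a 1024 px
image.  Default analysis uses `WL = 64`, `WS = 32` (a 31x31 window grid)
and `n_B = 50`.

Several quantities in this design are calibrations rather than
predictions: the pixel size 0.3462 um/px is chosen so that the RMS
magnitude of the analytic ground-truth field over the domain is 75 Pa (the
foreground/background threshold); the island centres sit at quadrant
midpoints; the substrate thickness defaults to 50 um, comfortably between
the pure-shear and half-space regimes.  Bead density and bead width are
plausible microscopy values, not published ones.  Metrics follow the
standard layout: RMS vector error, RMS `sigma_t`, foreground/background
mean and max of the recovered magnitude (foreground = true magnitude above
the true RMS), and the scalar `SNR_t` = foreground mean / background mean.

### What the synthetic study shows — and what it does not

The generator produces ideal Gaussian beads with no point-spread blur,
focus gradients, bead aggregates or drift.  At SNR 50 such images give PIV
errors of a few hundredths of a pixel, noticeably cleaner than typical
experimental data.  Three consequences, all reproduced by the acceptance
runs and worth keeping in mind when comparing against published numbers
from equivalent designs:

* the posterior uncertainty is data-dominated rather than
  prior-dominated, so `sigma_t` comes out smaller and with a larger
  max/min ratio than in noisier studies where the regularization floor
  dominates everywhere;
* the Bayesian posterior mean applies little smoothing (foreground means
  close to truth), because little is needed;
* the three L-curve corners (the benchmark's own, and those of
  homoskedastic low/high-density calibration runs) nearly coincide — with
  nearly clean data the corner stops discriminating noise levels, so the
  sharp under/over-regularization contrast between `lambda_L` and
  `lambda_H` baselines largely collapses.

Passing the synthetic suite therefore demonstrates correctness of the
machinery (kernels, samplers, metrics, uncertainty plumbing) and the
qualitative behaviours (uncertainty gradient tracking the bead-density
gradient, invalidation of featureless windows, floor behaviour, error
decreasing with window size), not that every published magnitude from
noisier imagery is matched.

## Problem sizes and runtime

Defaults were chosen so a full benchmark cycle (simulate, PIV-UQ with
`n_B = 50` on a 31x31 grid, 300 Gibbs draws, three L-curves) completes in
a few minutes on a single core: the bootstrap costs about `n_B + 1` PIV
runs per window, and each Gibbs draw is one dense Cholesky at
`2 Nw = 1922`.  The test suite uses scaled-down images (128-512 px) for
everything except the acceptance blocks.

## Known limitations

* Single-pass PIV: loss-of-pairs bias and no window deformation; large
  strains within a window broaden the correlation peak.
* The bootstrap cannot see systematic subpixel bias (peak locking): it
  estimates the stability of the estimator, not its accuracy.
* Paired mask resampling locks to zero lag on windows dominated by a
  bright featureless background; use `paired = FALSE` for such imagery.
* Periodic boundary conditions: long-range displacement tails wrap
  around; keep tractions away from the field-of-view edges or pad.
* Out-of-plane displacements, finite bead depth below the surface, and
  substrate-parameter (E, h) uncertainty are not modelled.
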