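---
title: "Measuring the bending mechanics of filamentous cyanobacteria"
author: "cyanomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the bending mechanics of filamentous cyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanomech)
```

## The measurement problem

Filamentous cyanobacteria grow as chains of cells hundreds of micrometres to
millimetres long and a few micrometres across. Mechanically they behave as
slender elastic rods: their resistance to bending is captured by a single
bending stiffness (flexural rigidity) $\beta$, with units of N m$^2$. This
number controls how filaments buckle around obstacles, how they bundle into
biofilms and mats, and what forces their gliding machinery must generate to
hold the curved shapes that actively moving filaments adopt.

`cyanomech` implements a complete, testable pipeline for estimating $\beta$
from microfluidic flow-cell experiments, in which a single filament anchored
to a channel wall is deflected by a slow water flow, together with the
surrounding analyses: channel hydrodynamics, skeleton geometry, population
shape statistics (curvature distributions and persistence length), and the
cell-wall mechanics that can be derived once $\beta$, the wall modulus and
the filament geometry are known.

## The forward model

### Channel flow

The flow cell is a shallow rectangular duct (width $W$, height $H$, flow
along $y$). For steady pressure-driven laminar flow the axial velocity is
the classical rectangular-duct series solution

$$u_y(x,z) = \frac{4W^2 U_0}{\pi^3 k}\sum_{n\,\mathrm{odd}}
\frac{(-1)^{(n-1)/2}}{n^3}
\left[1-\frac{\cosh(n\pi z/W)}{\cosh(n\pi H/2W)}\right]
\cos\frac{n\pi x}{W},$$

normalized through the effective permeability

$$k = \frac{W^2}{12}\left(1-\frac{192W}{\pi^5 H}
\sum_{n\,\mathrm{odd}}\frac{\tanh(n\pi H/2W)}{n^5}\right)$$

so that the cross-sectional mean of $u_y$ equals the pump-set speed $U_0$.
Ten series terms give a mean-flow normalization error below 0.1% for the
channel aspect ratios used here ($300\times134$ and $300\times72$ μm); the
truncation is configurable. As a safety net, `flow_environment()` checks the
normalization by quadrature at construction and rescales the field if the
mean ever deviates by more than 0.1% — with the implemented series this
rescale is inactive for all tested geometries. The test suite additionally
validates both $k$ and $u_y$ against an independent finite-difference
solution of the cross-sectional Poisson problem to better than 0.5%.

One physical subtlety, confirmed against the finite-difference oracle: even
for a wide channel ($W = 10H$) the midwidth velocity profile has the
plane-Poiseuille *shape* to within a few parts in $10^5$, but its amplitude
sits about 6% above $\tfrac32 U_0$, because the side-wall boundary layers
depress the cross-sectional mean that defines $U_0$. Tests therefore compare
the profile shape, not the raw amplitude, against the two-plate limit.

### Drag on the filament

At the filament scale the Reynolds number $Re = 2\rho r u_n/\mu$ is of order
$10^{-2}$, and the drag per unit length on a thin cylinder in cross-flow is
$w = \xi u_n$ with the Lamb–Oseen friction coefficient

$$\xi = \frac{4\pi\mu}{\ln(7.4/Re)}.$$

The logarithm is natural: with $r = 2.2$ μm and $u_n = 2.6$ mm/s this gives
$Re = 0.0114$, matching the magnitudes the drag law is used at. The
implementation refuses $Re \ge 7.4$ (where the logarithm changes sign) and
warns above $Re = 0.1$. A sample with zero normal speed carries zero load;
$\xi$ itself is never evaluated there.

### Beam response

For small deflections of an inextensible filament clamped at the wall
($\delta(0)=\delta'(0)=0$) and free at the tip ($M(L)=M'(L)=0$), the
deflection profile obeys $\beta\,\delta''''(s) = w(s)$. `forward_deflection()`
integrates this four times by cumulative trapezoids, applying the free-end
conditions first and the clamp conditions last. On 500-point grids the
uniform- and triangular-load solutions match their closed forms to better
than $10^{-3}$ relative error (trapezoid error is $O(h^2)$).

## The inverse procedure

A deflection experiment supplies a rest path $x_0(s)$, a deflected path
$x(s)$, the flow condition, the filament radius and its height $z$ in the
channel. Both paths are interpolated onto a common arclength grid at
one-pixel spacing. The load is evaluated *on the deflected shape*: the
far-field velocity at each sample's cross-channel position and height is
projected on the local normal (tangents from total-least-squares line fits
over a 5-pixel window), and $\xi$ is evaluated locally from $u_n$. A single
evaluation on the observed deflected shape is used, not a self-consistent
iteration — the observed shape already is the loaded configuration.

Because the deflection equation is linear, the predicted profile at
stiffness $\beta$ is $c(s)/\beta$, where $c(s)$ is the unit-stiffness
integral of the load. The fit minimizes

$$\sum_s \left(c(s)/\beta - \left|x(s) - R(\alpha)\,x_0(s)\right|\right)^2$$

where $R(\alpha)$ is a small solid-body rotation of the rest shape about the
anchor, absorbing any rigid pivoting of the filament in its holder. For
fixed $\alpha$ the optimal stiffness is the closed form
$\hat\beta = \sum c^2 / \sum c\,\delta_{\mathrm{corr}}$, so the
two-parameter fit reduces to a bounded one-dimensional search over $\alpha$
(Brent search on $\pm5°$ by default, tolerance $10^{-8}$ rad). Fitting with
the rotation disabled attributes all motion to bending and therefore yields
a lower bound on $\beta$; the profiled residual with rotation can never
exceed the rotation-free residual. If the rotation mode absorbs the entire
signal ($\sum c\,\delta_{\mathrm{corr}} \le 0$), the stiffness is unbounded
and `Inf` is returned with a warning rather than a spurious number.

A per-point profile $\beta(s) = c(s)/\delta_{\mathrm{corr}}(s)$ — the
stiffness that would reproduce the observed bending of each sample — is the
per-test diagnostic; its mean and standard deviation summarize each test.
The ratio degenerates where the denominator is small, so samples with
$\delta_{\mathrm{corr}}$ below a noise floor (default 2 px) and within the
first 10% of the contour next to the clamp are excluded. Tests on one strand
are combined by an inverse-variance weighted mean (weights $1/\mathrm{sd}^2$,
falling back to an unweighted mean with a warning if any test reports zero
variance), and species values are unweighted means over strands with a
population standard deviation and count.

## Shape statistics

Actively gliding filaments hold nearly constant curvature, so their shapes
are summarized by circle fits: the algebraic Pratt fit (exact on noiseless
circles, graceful on near-collinear data) with the sign taken from the net
turning direction, so ensembles without a preferred handedness centre on
zero. Disordered (inactive) filaments are summarized by the persistence
length $P$, defined through the surface-confined tangent-correlation decay

$$\langle\cos\phi\rangle(\Delta s) = e^{-\Delta s/2P},
\qquad \phi = \theta(s+\Delta s)-\theta(s).$$

`angular_correlation()` averages over all sample pairs of all filaments
(each pair weighted equally; per-filament weighting is a documented
alternative the implementation could adopt, but equal pair weights match
the estimator's definition as a contour-and-ensemble average), binned at
90 μm — the same 30-pixel window used for the tangent fits — up to half the
longest contour, beyond which bins are noise-dominated. The exponential is
fitted in linear space with equal bin weights, because near-zero correlation
values make log-space fitting unstable; the single parameter is found by
bounded one-dimensional minimization, which inverts exact exponential data
to numerical precision.

Two energy scales connect stiffness to shape: the incoherent bending energy
density $U \simeq \beta/P^2$ implied by shape disorder, and the thermal
persistence length $\beta/k_BT$ ($k_B = 1.380649\times10^{-23}$ J/K,
$T = 293$ K by default, the culture temperature). For the measured stiffness
range the latter is kilometres — conclusive evidence that filament shapes
are actively generated, not thermal.

## Derived cell-wall mechanics

Treating the filament as a thin-walled hollow cylinder (wall thickness
$\Delta r \ll r$) of Young's modulus $E$ gives $\beta = \pi E r^3 \Delta r$.
Three derived quantities follow from measured $(\beta, E, \kappa, r)$:

* effective wall thickness $\Delta r = \beta/(\pi E r^3)$,
* maximum wall stress under bending $\sigma_s = \kappa E r$
  (identically $\kappa\beta/(\pi r^2\Delta r)$ for thin-wall-consistent
  inputs),
* bending energy density $U = \tfrac12\beta\tilde\kappa^2$, with
  $\tilde\kappa$ the curvature change from the stress-free shape
  (taken as straight, $\kappa_0 = 0$, since inactive filaments show median
  curvature near zero).

Indentation instruments report the reduced modulus $E^* = E/(1-\nu^2)$;
conversion assumes $\nu = 0.5$, appropriate for soft biological material.
`derive_summary()` propagates uncertainties to the derived quantities by the
first-order delta method, treating inputs as independent and using standard
errors $\mathrm{sd}/\sqrt{n}$. This reproduces the published uncertainty
magnitudes for the wall thickness and energy density; for the wall stress it
gives noticeably smaller uncertainties than published, and since the exact
published propagation convention is not recoverable, the delta-method values
are reported as such and comparisons focus on central values.

## The synthetic-data generator

Every input of the pipeline can be generated with known ground truth:

* **Arc ensembles** (`gen_arc_filaments()`): circular arcs with curvature
  drawn from a folded normal $|N(\mu_\kappa, \sigma_\kappa)|$ — a negative
  draw is a handedness flip — with defaults $\mu_\kappa = 470$ /m,
  $\sigma_\kappa = 304$ /m, contour 1.2 mm, emulating actively gliding
  filaments.
* **Worm-like chains** (`gen_wlc_filaments()`): tangent angles performing a
  Gaussian random walk with variance $\mathrm{step}/P$ per step, so the
  correlation target holds by construction; defaults $P = 7$ mm (the middle
  of the observed 5–10 mm inactive range), 3 mm contour, 10 μm step.
* **Flow-cell experiments** (`gen_deflection_experiment()`): a straight
  filament anchored at the wall (default $L = 250$ μm, $r = 2.2$ μm,
  midheight, 0.5 μm/px), loaded by the package's own flow and beam model.
  The load–deflection pair is iterated to a fixed point, so the generated
  shape is exactly self-consistent with the load evaluated on the deflected
  path — the same quantity the fit uses; a single evaluation (as applied to
  real data) is the first iterate of this map. The deflected configuration
  is then rotated by the ground-truth $\alpha$ about the anchor, and both
  configurations receive isotropic Gaussian pixel noise (default 0.5 px).
* **Rasters** (`rasterize_filament()`): constant-width ribbons (default
  4.4 μm, twice the typical radius) for exercising the tracer.

All generators use R's default Mersenne-Twister RNG through locally applied
seeds, so a fixed seed reproduces outputs exactly without disturbing the
caller's RNG state.

What the generators deliberately do **not** emulate: confocal point-spread
functions and fluorescence texture, multi-filament crossings, out-of-plane
bending, axial extension, or viscoelastic relaxation. Recovery tests on
synthetic data therefore validate the estimators' correctness and noise
robustness, not the segmentation of difficult real images.

## Numerical choices and degenerate inputs

* **Skeletons**: binary images are thinned with the Zhang–Suen algorithm and
  walked from endpoint to endpoint; spur branches up to 10 px are pruned,
  and genuinely branched skeletons raise an error naming the endpoint
  count. The traced pixel chain is smoothed with a 5-px boxcar before
  arclength accumulation: an unsmoothed 8-connected digital line
  overestimates its own length by up to ~8% near 22.5°, which would exceed
  the tracer's 5% length-accuracy contract. No spline smoothing is applied.
* **Tangents** come from principal-axis (total-least-squares) line fits, so
  vertical tangents are handled; the axis direction is oriented along the
  local secant and the angle sequence unwrapped before differentiation.
  Window defaults: 5 px for flow-cell loads, 30 px (90 μm) for shape
  statistics.
* **Curvature** is the centred finite difference of the unwrapped
  orientation, one-sided at the ends; reported counter-clockwise positive.
* **Circle fits** solve the Pratt-normalized generalized eigenproblem on
  centred, scaled coordinates; collinear input returns curvature 0 and
  infinite radius instead of failing.
* **Flow evaluation** uses the series directly at the filament sample
  positions rather than a pre-tabulated fine grid — the series is cheap and
  exact where evaluated. Samples pushed marginally outside the cross-section
  by digitization noise (up to 5 px) are clamped to the wall for evaluation;
  anything further out is an error.

## Problem sizes

The validation suite runs entirely on synthetic data at modest sizes chosen
to make Monte-Carlo statements stable: 50-seed recovery studies for the
stiffness fit (500-sample filaments), 150 worm-like chains of 3 mm for
persistence recovery, 119-arc ensembles for curvature statistics, and
201×201 finite-difference grids for the flow oracle. The complete suite
runs in well under a minute.

## Known limitations

* The beam model is linear; tip deflections beyond ~30% of the filament
  length strain the small-deflection assumption and trigger a generator
  warning. Large-deflection elastica fitting is out of scope.
* The inverse procedure assumes one-way coupling (the filament does not
  perturb the flow) and a filament at a single, known height.
* Species-level experimental values (stiffness, moduli, curvature) are
  inputs, not outputs: reproducing them requires the original image data.
* The wall-stress uncertainty convention differs from the published one, as
  discussed above; central values agree.

## A worked example

```{r example, eval = FALSE}
env <- flow_environment(channel_geometry(width = 300e-6, height = 134e-6),
                        mean_speed = 1e-3)
syn <- gen_deflection_experiment(5e-17, rotation = 0.3 * pi / 180, env,
                                 noise = 0.5, seed = 42)
fit <- fit_filament_stiffness(syn$experiment)
summary(fit)
plot(fit)

# population shape statistics
chains <- gen_wlc_filaments(150, persistence = 7e-3, seed = 1)
fit_persistence_length(angular_correlation(chains))

# derived wall mechanics for the bundled species-level measurements
derive_summary(species_table())[, c("species", "dr", "sigma_s", "U")]
```
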