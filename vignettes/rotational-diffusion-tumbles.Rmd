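---
title: "Modeling bacterial tumbles as active rotational diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bacterial tumbles as active rotational diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotumble)
```

## The model

A swimming *E. coli* alternates straight **runs** (flagellar bundle formed,
speed $V_{run} \sim 20\ \mu m/s$, exponentially distributed durations with
mean $\langle\tau_{run}\rangle \sim 1\ s$) with brief **tumbles** (bundle
unraveled, no net translation, mean duration
$\langle\tau_{tum}\rangle \sim 0.1\ s$). `rotumble` treats the reorientation
accumulated during a tumble as **active rotational diffusion**: the body
axis $\mathbf{n}$ performs a Brownian walk on the unit sphere with a single
coefficient $D_r$ (rad$^2$/s), orders of magnitude larger than the thermal
Stokes--Einstein--Debye value
$D_r^{thermal} = k_B T / (8\pi\eta a^3) \approx 0.16$ rad$^2$/s for a
micron-sized sphere (`stokes_einstein_rotational()`).

Starting from a delta-function orientation, the polar angle $\theta$ after
time $t$ has density

$$p(\theta, t) = \sin\theta \sum_{l \ge 0}
  \left(l + \tfrac12\right) e^{-l(l+1) D_r t} P_l(\cos\theta),$$

implemented in `legendre_propagator()` with adaptive truncation (mode weight
$< 10^{-12}$, hard cap $l = 500$; below $D_r t \approx 1.1\times10^{-4}$ the
capped series has not converged and the function directs callers to the
$t = 0$ delta convention or the Monte-Carlo sampler). The directional
autocorrelation is the first Legendre moment,
$\langle\cos\theta\rangle(t) = e^{-2 D_r t}$
(`direction_autocorrelation()`).

Because tumble durations $\tau$ are themselves random, the distribution of
reorientation angles *between successive runs* is the mixture
$\sum_k w_k\, p(\theta, \tau_k)$ over the duration law
(`reorientation_distribution()`). Frame-quantized tracking reports durations
on a grid, which the **discrete exponential** model captures: a geometric
law on $\{s, 2s, \dots\}$ with the success probability chosen so the mean is
exact. For mean 0.14 s and step 0.1 s this gives
$q = 1 - s/\bar\tau = 2/7$, and the persistence factor has the closed form
$\alpha = E[e^{-2 D_r \tau}] = (1-q) e^{-2 D_r s} / (1 - q e^{-2 D_r s})$
(`persistence_from_rotdiff()`).

## The observation plane

Tracking microscopy measures angles in 2D: the planar angle $\psi$ between
the projections of successive run directions, or the in-plane angle of the
fitted ellipse axis for tumbler mutants. How $\psi$ relates to the 3D model
is the central modeling choice of this package, and we state it openly.

**The planar (near-plane) observation model — the default.** Tracked cells
stay close to the focal plane: chambers are shallow relative to the track
length, cells that dive out of the plane leave the depth of field and are
not tracked, and the ellipse-axis measurement is apolar (defined modulo
$\pi$), which suppresses the apparent angle swings that occur when an axis
passes near the optical axis. In this regime the observed planar angle
accumulates the component of the angular displacement about the optical
axis; for isotropic rotational diffusion that component is Brownian with
variance $2 D_r t$, so the exact projected correlation is

$$\langle\cos\psi\rangle(t) = e^{-D_r t}:$$

projection *halves* the decay rate relative to
$\langle\cos\theta\rangle = e^{-2 D_r t}$. This is the law implemented by
`projected_autocorrelation(reference = "planar")`, the observation model of
the trajectory generator, and the `"projected"` rate convention of
`fit_exponential()` ($\hat D_r$ = fitted rate). Geometric corrections from
out-of-plane excursions are *neglected*; we explored them quantitatively
(a Feynman--Kac treatment of the azimuthal component attenuated by
$\sin^2$ of the polar angle slows the decay by 5--15% over one decay time)
and discuss the consequences under *Limitations*.

**The isotropic 3D reference.** For data with no near-plane selection —
both directions of a pair oriented uniformly relative to the plane — the
conditional kernel $K(\theta) = E[\cos\psi \mid \theta]$ is computed by 2D
numerical quadrature over the pair orientation (`projection_kernel()`) and
expanded in Legendre coefficients, so the marginal
$\langle\cos\psi\rangle(t) = \sum_l c_l e^{-l(l+1) D_r t}$ is a fast
spectral sum (`reference = "isotropic3d"`). Its leading coefficient is
$c_1 \approx 0.93$: such data decay essentially at the *full* 3D rate
$2 D_r$, not the halved one. The two references therefore differ by almost
a factor of two in the fitted coefficient, which is why the package makes
the observation model an explicit argument rather than a hidden assumption.
The `"3d"` simulator mode plus `reference = "isotropic3d"` fits form a
self-consistent pair, cross-checked against a uniform-pair Monte-Carlo
oracle in the test suite.

A consequence of the planar model worth stating plainly: the exact planar
projected correlation *is* a single exponential, so
`fit_exact_projection()` (which fits the exact law) and
`fit_exponential(rate_convention = "projected")` coincide analytically on
planar-reference data; their reported agreement is a consistency check of
two independent implementations, not a comparison of two physical models.
With `reference = "isotropic3d"` the two genuinely differ.

## The synthetic-data generator

`run_tumble_scenario()` + `simulate_run_tumble()` generate everything the
tracking experiments produce, with full ground truth:

* runs: straight, constant speed, exponential durations (no rotational
  diffusion during runs — reorientation is attributed entirely to tumbles);
* tumbles: durations from the discrete (default) or continuous exponential
  model; the latent 3D reorientation $\theta$ is drawn from the exact
  propagator (inverse-CDF tables cached per $D_r\tau$; the law is identical
  to the sphere walk, verified by chi-square cross-checks), and the observed
  planar turn is $\psi \sim N(0, 2 D_r \tau)$, wrapped;
* chemotaxis: cosine-linear modulation of the mean run duration,
  $\bar\tau_{run}(1 + \chi_{run}\cos\varphi)$, and of the mean tumble
  duration, $\bar\tau_{tum}(1 - \chi_{tum}\cos\varphi)$, where $\varphi$ is
  the angle between the swimming direction and the gradient axis. The
  functional form of real chemoreceptor modulation is not specified by the
  analyses this package supports (they condition only on direction
  quadrants); cosine-linear is the minimal smooth odd choice and makes
  quadrant averages analytic;
* wave regime: direction-dependent coefficients `d_r_by_class`
  (up / perpendicular / down relative to the propagation axis) applied per
  tumble according to the class of the preceding run, modeled as stationary
  statistics inside the front rather than as a self-consistent traveling
  wave;
* camera: positions sampled at `frame_rate` (default 10 Hz for swimming
  tracks, 50 Hz for tumblers).

The default mode is **quasi-planar** (positions and headings in the
observation plane, $z \equiv 0$), matching the planar observation model
end to end; `mode = "3d"` produces fully 3D headings for properties that
need isotropy (e.g. the translational-diffusion closure). The generator
does **not** emulate localization noise, cell-to-cell variability of speed
or of $D_r$, out-of-plane excursions, or nutrient consumption — so passing
recovery tests demonstrate correctness of the estimators under the model's
own assumptions, not robustness to every artifact of real microscopy data.

Reference scenarios encode the study conditions used throughout:
`scenario_homogeneous()` ($D_r = 2.1$), `scenario_gradient()` ($D_r = 2.3$,
$\chi_{run} = \chi_{tum} = 0.25$), and `scenario_wave()`
($D_r$ = 2.3 / 3.2 / 4.4 for up / perp / down, $\chi_{tum} = 0.13$, chosen
so the up-to-down spread of mean tumble durations is $\approx 22\%$ under
the cone-averaged cosine).

`simulate_tumbler()` generates the orientation series of constantly
tumbling (CheZ-deleted) mutants under the same planar observation model:
unwrapped $\psi$ with Gaussian frame increments of variance $2 D_r \Delta t$
at 50 fps.

## Trajectory analysis

`segment_track()` labels each frame interval a tumble when its speed drops
below `speed_factor` (default 0.5) times the track's median speed **or**
the turn rate at a frame boundary exceeds `turn_rate_thresh` (default
5 rad/s). The turning boundary is attributed to the *slower* of the two
intervals sharing it, since reorientation happens while the cell is
(partly) paused; without this rule, large-angle short tumbles
systematically spill into the following duration bin and bias the fitted
coefficient low by ~25%.

The published detection criteria for run/tumble decomposition are not
available, so the defaults were tuned on the generator at the homogeneous
study conditions and are documented here (10 Hz, mean run 1 s, discrete
tumbles 0.14/0.1 s; 200 tracks):

| `min_run_frames` | tumbles recovered | boundaries within 1 frame | mean duration error | $\hat D_r$ (truth 2.1) |
|---|---|---|---|---|
| 1 | 100% | 90% | +7% | 2.13 |
| 2 | 100% | 76% | +21% | 2.08 |
| 3 | 100% | 61% | +50% | 1.95 |

Merging short runs (values 2--3) fuses the tumbles on either side of any
run shorter than the threshold (26% of runs at these conditions), inflating
durations and biasing the fit; since every detected run in low-noise data
carries a reliable direction, the default is `min_run_frames = 1` (no
merging). For noisy real tracking data, where one-frame "runs" can be
localization artifacts, raising it to 2--3 is the appropriate trade-off.

`reorientation_events()` measures $\psi$ between the displacement-weighted
mean directions of the flanking runs and classifies the preceding run into
quadrants: half-open cones of 45 degrees about the gradient axis (`up` /
`down`; a direction at exactly 45 degrees belongs to `perp`; the two
perpendicular quadrants are merged). `correlation_curve()` bins events by
duration (bins centered on multiples of 0.1 s, the duration quantum;
bins with fewer than 10 events suppressed).

## Fitting and uncertainties

Both fitters are one-parameter weighted least squares (weights $1/SE^2$)
with **no intercept or amplitude**: correlation curves are anchored at 1 by
construction, and the decay rate is the only adjustable parameter.
Identifiability degenerates for flat curves (rate $\to 0$, or fully
randomized long-tumble data); these are flagged rather than silently
reported. Reported uncertainties are nonparametric event-level bootstrap
standard errors (default 200 resamples, rebuilding the curve each time);
the curve-covariance (Gauss--Newton) standard error is retained in the fit
details. A coverage test in the suite checks that the $\pm 1$ SE interval
covers the generating coefficient at the nominal 60--80% rate. The "$\pm$"
reported by this package is therefore a bootstrap SE; published
"$\pm$" values of this kind rarely state their convention, so compare with
care.

`fit_reorientation_histogram()` estimates $D_r$ from 3D reorientation
angles by binned multinomial maximum likelihood (default; robust for
low-count tails) or least squares on bin frequencies, with 18 bins of 10
degrees by default; bin probabilities use exact Legendre antiderivatives,
not grid sums. Replicate SD at $n = 1200$ events grows roughly linearly
with the coefficient (0.05 at 1.5, 0.13 at 3.5, 0.20 at 5 rad$^2$/s).

`fit_by_class()` fits each quadrant class and the pooled curve, and runs
Cochran's Q across the class estimates (precision-weighted) at the 1%
level: the gradient scenario is homogeneous (one $D_r$, only durations
modulated), the wave scenario decisively is not.

## Drift arithmetic

`drift_velocity()` is the per-track net displacement along the axis over
the track duration, averaged with across-track SE.
`translational_diffusion()` implements the persistent-random-walk closure
$D_t = v^2 \bar\tau_{run} / (d(1 - \alpha))$ with the spatial dimension
exposed; it neglects the run/tumble duty cycle (a ~12% effect at the
canonical durations), which is why the simulation cross-check in the test
suite uses a short tumble mean (0.05 s) to isolate the closure itself.
`modulation_summary()` reports the down-vs-up modulation of $D_r$ and of
mean tumble duration under all three candidate baselines (class mean,
perpendicular class, grand mean), because percentage-modulation conventions
are ambiguous; for coefficients 4.4 vs 2.3 the class-mean baseline gives
63%.

## Numerical choices

* Propagator truncation at mode weight $10^{-12}$, cap $l = 500$; the
  convergence floor $D_r t \approx 1.1\times 10^{-4}$ is enforced with an
  explicit error. Duration-mixture quadrature nodes below the floor are
  evaluated at the floor (misplacement below any realistic grid
  resolution).
* The stationary density is approached as $\sim 1.5 e^{-2 D_r t}$ (the
  $l = 1$ mode): sup-norm $10^{-6}$ agreement with $\sin\theta/2$ holds
  from $D_r t \approx 7.5$ on.
* Sphere-walk steps rotate *exactly* through the sampled Gaussian angle
  about a random tangent axis (per-step variance capped at 0.1 rad$^2$ by
  sub-stepping). Displacing and renormalizing instead shortens steps and
  biases $\langle\cos\theta\rangle$ upward by $O(\Delta t)$ — measurably so
  at the cap.
* The isotropic3d kernel uses 192-node Gauss--Legendre $\times$ 384-node
  periodic quadrature and 40 Legendre coefficients, accurate to a few
  $10^{-5}$ (anchored to the Monte-Carlo oracle in the tests).
* Inverse-CDF reorientation sampling uses 2048-point tables cached per
  $D_r\tau$; below the series floor a Rayleigh small-angle draw is exact to
  the same order.
* The $t = 0$ propagator is a documented discrete delta: all mass in the
  first grid cell with trapezoid weighting.

## Problem sizes

The packaged recovery experiments (`reproduce_experiments()`, also run by
`scripts/acceptance.R`) use 1200 events for the histogram fit (matching the
classic tumble-statistics sample size), 500 tracks of 20 s at 10 Hz for the
homogeneous pipeline (~8000 events), 600 tracks for the gradient scenario
(~10000 events) and 2400 tracks for the wave scenario (~7500 events in each
of the up/down classes), with 200 bootstrap resamples throughout. These
sizes put every recovery comfortably inside the targeted $\pm 0.3$--$0.4$
rad$^2$/s windows while keeping a full run in the minutes range on one CPU.

## Limitations

* The planar observation model is an idealization: out-of-plane excursions
  during long tumbles slow the observed planar decorrelation below
  $e^{-D_r t}$, and fully isotropic unselected data behave like the
  `"isotropic3d"` reference instead (decay $\approx 2 D_r$). Estimates from
  real data therefore carry a model-dependence that the observation-model
  argument makes explicit but does not remove.
* Runs are perfectly straight; wobble and rotational diffusion during runs
  would add a floor to measured reorientations at short durations.
* The wave regime is a stationary caricature of a traveling front; no
  nutrient field or consumption is modeled.
* The discrete tumble-duration grid and the 10 Hz camera share the same
  0.1 s quantum by construction; segmentation duration errors are
  therefore at most one frame in the dominant bins, but systematic at
  higher frame-rate/step mismatches.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_run_tumble(scenario_homogeneous(n_tracks = 150, seed = 7))
an  <- analyze_tracks(project_to_plane(sim))
fit <- fit_exponential(an$curve, events = an$events, seed = 8)
tidy(fit)
autoplot(an$curve, fit = fit)
```
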