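# rotumble

Rotational-diffusion analysis of bacterial run-and-tumble motility.

Swimming *Escherichia coli* alternates straight **runs** (~20 µm/s, mean
~1 s) with brief **tumbles** (~0.1 s) during which the cell reorients
without advancing. Tumbles do not fully randomize the heading: successive
runs keep a directional persistence (⟨cos θ⟩ ≈ 0.3–0.4). `rotumble` models
the reorientation accumulated during a tumble as **active rotational
diffusion** of the body axis on the unit sphere, characterized by a single
coefficient D_r (rad²/s), and provides everything needed to estimate D_r
from tracking data and to study its chemotactic consequences:

* the Legendre-polynomial **orientation propagator**
  p(θ, t) = sin θ Σ_l (l + ½) e^(−l(l+1)·D_r·t) P_l(cos θ), its 3D
  autocorrelation ⟨cos θ⟩(t) = e^(−2·D_r·t), and the thermal
  Stokes–Einstein–Debye reference D_r = k_B·T / (8π·η·a³);
* the **tumble-time-marginalized reorientation distribution** (mixture of
  propagators over a continuous- or discrete-exponential duration law) and
  its maximum-likelihood histogram fit for D_r;
* projection to the **microscope observation plane**: under the near-plane
  observation model the projected correlation is ⟨cos ψ⟩(t) = e^(−D_r·t)
  (projection halves the decay rate); an isotropic-3D quadrature kernel is
  provided for selection-free data;
* a Monte-Carlo **random walk on the sphere** (the brute-force oracle for
  all of the above);
* a **synthetic run-and-tumble generator** with full ground truth —
  homogeneous media, shallow chemoattractant gradients (cosine-linear
  modulation of run and tumble durations), and propagating-wave regimes
  with direction-dependent D_r — plus tumbler-mutant orientation series;
* the **trajectory analysis pipeline**: segmentation of 2D tracks into runs
  and tumbles, reorientation events with quadrant classification relative
  to a gradient axis, binned ⟨cos ψ⟩-vs-τ correlation curves, exponential
  and exact-projection fits with event-bootstrap uncertainties, per-class
  fits with a Cochran-Q homogeneity check;
* **chemotactic drift metrics**: drift velocity along a gradient,
  persistence factors, the persistent-random-walk translational diffusion
  closure D_t = v²·τ_run / (d·(1 − α)), and up/down modulation summaries.

Everything is tidyverse-shaped: functions take and return tibbles, fits
have `tidy()`/`glance()` methods, result types have `autoplot()` methods.

## Worked example

Simulate tracking data at the homogeneous reference conditions
(D_r = 2.1 rad²/s, 20 µm/s, 10 Hz camera), run the analysis pipeline, and
re-estimate the coefficient:

```r
library(rotumble)

stokes_einstein_rotational(1e-6, 1e-3, 295) # thermal reference, rad^2/s
#> [1] 0.1620561

sim <- simulate_run_tumble(scenario_homogeneous(n_tracks = 150, seed = 7))
an  <- analyze_tracks(project_to_plane(sim))
an$curve
#> # A tibble: 5 × 4
#>     tau mean_cos     n      se
#>   <dbl>    <dbl> <int>   <dbl>
#> 1   0.1    0.820  1652 0.00575
#> 2   0.2    0.668   541 0.0168
#> 3   0.3    0.504   195 0.0374
#> # i 2 more rows

fit <- fit_exponential(an$curve, events = an$events, seed = 8)
tidy(fit)
#> # A tibble: 1 × 4
#>   term  estimate std.error method
#>   <chr>    <dbl>     <dbl> <chr>
#> 1 d_r       2.02    0.0574 exponential
```

The curve is the mean cosine of the planar reorientation angle ψ between
successive runs, binned by tumble duration: 0.82 after a single-frame
(0.1 s) tumble, decaying toward 0 as tumbles lengthen and the heading
randomizes. The one-parameter exponential fit e^(−D_r·τ) recovers
D_r = 2.02 ± 0.06 rad²/s against the generating value 2.1 (the ± is an
event-bootstrap standard error over 200 resamples). The implied persistence
across a tumble,
`persistence_from_rotdiff(2.02, tumble_time_model("discrete_exponential", 0.14, 0.1))`,
is 0.59: tumbles at these kinetics erase only about 40% of the directional
memory, which is what makes their duration modulation an effective steering
channel during chemotaxis.

A thin command-line pipeline over the same functions is installed at
`system.file("cli", "rotumble", package = "rotumble")` with subcommands
`simulate`, `analyze`, `fit`, `drift` and `reproduce` (see the header of
that script and `inst/extdata/example-scenario.yaml`).

## Package layout

* `R/propagator.R`, `R/projection.R`, `R/sphere-walk.R` — the model core
* `R/tumble-kinetics.R` — duration laws, marginalized distribution, histogram fit
* `R/scenario.R`, `R/simulate.R` — synthetic-data generator
* `R/track-analysis.R`, `R/fit.R` — the tracking pipeline and estimators
* `R/drift.R` — drift and persistence arithmetic
* `R/io.R`, `R/pipeline.R`, `inst/cli/rotumble` — formats, config, CLI
* `vignettes/rotational-diffusion-tumbles.Rmd` — the methods vignette
  (model, observation plane, generator assumptions, numerical choices,
  limitations)
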