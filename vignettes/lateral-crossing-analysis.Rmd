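---
title: "Lateral obstacle-crossing analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateral obstacle-crossing analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latstep)
```

## The problem

Falls to the side are a leading cause of hip fracture in older adults, and a
safe recovery often demands a quick, accurate lateral step over whatever is in
the way — more so when the body is already leaning. `latstep` implements a
complete analysis of repeated lateral obstacle-crossing trials recorded by
optical motion capture: it segments each trial into its swing phase, scores
how repeatable the swing trajectory and landing position are across trials,
summarises per-trial kinematics, and compares an older and a young adult group
with a Bayesian Gaussian model.

The study design the package targets is: two groups of 20 subjects, each
crossing an obstacle set at 15% of body height, placed 0.10 m lateral to the
right foot, ten times under each of four conditions — `normal`, `fast`,
`leaning` (starting displaced to 70% of the lateral limit of stability) and
`leaning_fast`. Markers are sampled at 100 Hz and the force plate at 1000 Hz,
with X lateral (right +), Y anterior (+) and Z vertical (up +).

## Event detection

The swing phase is bounded by two events:

* **heel-off** — the first marker sample whose displacement from a static
  baseline reference *strictly exceeds* 2 mm. The baseline reference is the
  per-axis median over the first `baseline_window` (default 0.3 s) of the
  recording. The displacement is 3-D Euclidean by default; the definition in
  the source protocol ("moved 2 mm") does not say whether it was 3-D or
  vertical-only, so `axes` makes the norm configurable and 3-D is the
  default.
* **landing** — the first force sample *at or above* 10 N that stays at or
  above threshold for a 10 ms debounce window. The debounce is our addition:
  the protocol is silent on noise handling, and a single-sample spike should
  not count as foot contact.

The asymmetry of the inequalities (strict at 2 mm, inclusive at 10 N) mirrors
the phrasing "moved 2 mm" versus "detected 10 N". Both thresholds are exposed
as arguments. Events are detected on each stream's native rate; nothing is
resampled before detection, so heel-off is quantised to 10 ms and landing to
1 ms. Step time is the difference of the two event times.

## Trajectory consistency

Each swing's heel path is mapped onto normalized time $u \in [0,1]$
(amplitudes untouched), interpolated per axis with a cubic spline, and
evaluated on a regular grid of `n_points = 101` points — the conventional
0–100% grid; the source method says only "regular intervals". The spline is
the *natural* interpolating spline (zero second derivative at the ends);
this boundary condition is unstated in the source, and the knot-adjacent
`"fmm"` variant is available as an option.

The **error distance** of a trial block is, per trial, the 3-D gap to the
pointwise average trajectory at every grid point, aggregated as the *mean*
gap per point and then averaged over trials (`mean_point`, the default). A
literal reading of the source — "gaps … were summed" — is available as
`sum_point`. We default to the mean because the tabulated values
(≈ 0.017–0.021 m) are plausible as a mean per-point gap but not as a raw sum
over roughly a thousand point–trial pairs; the statistic is identical up to
the constant factor `n_points × n_trials` and all invariance properties are
shared. The mean-point statistic is translation-invariant, scales linearly
under uniform scaling, and is zero exactly when all paths coincide.

**Landing variability** is the sample SD (denominator $n-1$) of the heel
marker's X and Y coordinates at each trial's landing instant, the landing
coordinate being the nearest marker sample at or before the force-defined
landing time.

## Scalar outcomes and the tenth-trial rule

Step time, the per-axis maxima of absolute COG displacement during the swing
(displacement relative to the heel-off instant; a relative-to-start variant
is available), and the maxima of the hip extension, knee extension and ankle
plantar-flexion moments (body-mass-normalized, extension/plantar-flexion
positive) are computed per trial. Following the source protocol, only the
*tenth* trial of each condition block contributes these scalars to the group
analysis, while the consistency statistics use all ten trials. The rule is
implemented as stated; no justification for it is offered by the protocol
and none is invented here.

## The Bayesian comparison

Each (parameter, condition, group) cell of 20 per-subject values is modelled
as Gaussian with a noninformative prior, read concretely as
$p(\mu, \sigma) \propto 1/\sigma$ — flat on $(\mu, \log\sigma)$. The
posterior is explored by a self-implemented Hamiltonian Monte Carlo sampler
on $(\mu, \log\sigma)$:

* leapfrog integration with a per-iteration trajectory length jittered
  uniformly on 1…`leapfrog_steps` (default 20) — fixed-length trajectories
  loop back on themselves for this near-Gaussian target and mix poorly;
* a global step size adapted by dual averaging toward 0.8 acceptance during
  burn-in only, then frozen;
* diagonal preconditioning with the exact posterior scales of the
  standardized problem, $1/\sqrt{n}$ for $\mu$ and $1/\sqrt{2n}$ for
  $\log\sigma$.

Internally the sampler runs on standardized data, whose sufficient
statistics are exactly $(\sum z = 0, \sum z^2 = n-1)$, and maps the draws
back affinely. The flat prior is affine-invariant, so the target is
identical — and posterior draws become *exactly* location/scale
equivariant, which the test suite asserts to machine precision. A
random-walk Metropolis fallback (`sampler = "rw_metropolis"`) guarantees
the same statistical contract if HMC tuning ever fails.

Sampling runs 4 chains of 2000 iterations with 500 burn-in and thin 1, so
6000 draws are retained. Convergence is judged by the *split-chain*
Gelman–Rubin factor (each chain halved before the between/within variance
ratio), accepted below 1.05. Split-Rhat is the modern form of the
diagnostic; the classic whole-chain estimator is available via
`split = FALSE`.

The group contrast is the draw-wise difference $\mu_{young} - \mu_{old}$
across equal-length retained chains; the direction is fixed so that larger
older-adult values give negative intervals, matching the sign pattern of the
published table. The central 95% interval uses empirical type-7 quantiles,
and significance means the interval excludes zero. If any of the four
parameters' Rhat reaches 1.05 the comparison is flagged non-converged and
the significance decision withheld. Because groups are sampled
independently, the pairing order of draws is immaterial; retained order is
used for reproducibility.

Correctness is checked against the closed-form conjugate marginal: under the
flat prior, $\mu \mid y$ is a location-scale Student-t with location
$\bar y$, scale $s/\sqrt{n}$ and $n-1$ degrees of freedom
(`conjugate_oracle()`), and the difference interval is checked by
Monte-Carlo over two independent t variates. The suite requires MCMC
interval endpoints to agree with the oracle within three Monte-Carlo
standard errors across randomized cells.

## The synthetic generator: what it emulates, and what it does not

No recordings accompany the published study, so the package ships a
generator that emulates the *design* and the *statistical structure* the
analysis assumes:

* The heel swing is a smooth C² arc — quintic-smoothstep travel in X/Y and a
  $\sin^2$ bump in Z — through a start point, an apex `clearance` (default
  0.05 m) above the obstacle, and a landing point. The source gives no
  trajectory model; any C¹ arc clearing the obstacle satisfies the analysis,
  and this one is exactly static before heel-off and after landing, which
  makes event ground truth well defined.
* The vertical force is zero until foot contact, then ramps linearly to body
  weight over 50 ms; the protocol specifies only the 10 N threshold. With a
  typical body weight the 10 N crossing lags contact by about 1 ms.
* COG and joint-moment series are smooth unimodal curves whose extrema equal
  programmed per-subject targets, because whole-body COG estimation and
  inverse dynamics are explicitly out of scope — those streams are *inputs*
  to the analysis, not outputs of a musculoskeletal model.
* Trial-to-trial inconsistency is injected by perturbing arc control points
  and the landing point (`trajectory_sd`, `landing_sd_x/y`, `timing_sd`);
  larger perturbations emulate the less consistent older-adult motion. A
  noisy arc that would intersect the obstacle box is redrawn with a derived
  seed, mirroring the protocol's exclusion of tripped trials.
* Per-subject outcome targets are drawn from a calibration table of group
  means and SDs per (parameter, condition) cell — the published group
  statistics. The `exact = TRUE` scalar mode (`simulate_scalar_cohort()`,
  built on `exact_moment_sample()`) reproduces each cell's sample mean and
  SD *exactly*, which is what lets the package re-derive the published
  posterior intervals from scratch.
* The lateral limit of stability defaults to a 0.10 m COP excursion
  (configurable); the protocol measures it per subject but publishes no
  values. Leaning trials start the COG at 70% of it.

A green test on synthetic data therefore establishes that the *pipeline*
does what it claims — events recovered within one sample, consistency
statistics with the right invariances, posterior intervals matching the
conjugate oracle — not that the generator reproduces real human kinematics.
Real swing paths are not C² splines, real force onsets are not linear ramps,
and real trial-to-trial variation is structured rather than independent
Gaussian jitter.

Two tabulated irregularities are handled explicitly and excluded from
numeric acceptance: the published moment rows duplicate the COG rows
verbatim (kept as printed in the calibration so every cell can be
exercised), and cells whose printed SD is 0.00 have zero sample variance in
exact-moment mode, under which the flat-prior posterior is improper —
`sample_posterior()` rejects them, and `compare_cells()` reports such cells
with NA intervals.

## Numerical choices

* Exact-moment sampling draws standard normals, centres, and rescales; the
  moments are exact to floating-point round-off (tested at 1e-10).
* Degenerate inputs are errors, not warnings: fewer than 4 swing samples
  (no cubic spline), a single path (error distance undefined), fewer than 2
  trials (landing SD undefined), marker gaps inside the swing (never
  interpolated), zero-variance cells (improper posterior).
* All randomness flows from integer seeds through a deterministic
  seed-derivation hash, so cohorts, chains and whole pipeline runs are
  bit-reproducible; equal seeds give byte-identical results tables.
* Results are printed at the table's own precision: two decimals for scalar
  rows, three for error distance.

## Limitations

* The generator's realism is bounded by published summary statistics; it
  cannot validate claims about real kinematic waveforms.
* Only one swing per trial is segmented; multi-step or gait-cycle
  segmentation is out of scope.
* Cells are fitted independently; there is no hierarchical sharing across
  conditions or parameters, no model comparison and no posterior predictive
  checking, matching the published analysis.
* TRC and CSV are the supported input formats; C3D ingest would be an
  adapter on top of `load_trial()`, not a change to the analysis.
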