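---
title: "Ensemble Kalman enhancement of voxel-based flow data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble Kalman enhancement of voxel-based flow data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `senkflow`, the
assumptions behind it, the tunable parameters, the numerical choices, and
the limits of what the bundled synthetic cases can demonstrate.

## The statistical model

Turbulent and pulsatile flows are not reproducible realization by
realization; what a filter can meaningfully estimate is the *statistics*
of the flow. `senkflow` therefore treats the phase-averaged mean velocity
as the true state of the system and the turbulent fluctuations as the
noise process. Under a Reynolds decomposition
`u = <u> + u'`, the forecast covariance of the ensemble Kalman filter is
exactly the Reynolds-stress tensor of the forecast, and the observation
noise covariance is the measured per-voxel velocity covariance. This
identification is what lets a *stochastic* ensemble Kalman filter (the
perturbed-observation variant, in which the observation error covariance
is itself a sample covariance) operate on single-run flow data.

The ensemble is built from pulses rather than from parallel perturbed
model runs. With pulse period `T` divided into `N_phi` phases at times
`t_phi`, the realization `r` of phase `phi` is the model state at
`t = t_phi + (r - 1) T`. A statistically steady flow is the degenerate
single-phase case: samples taken every `Delta tau` form the time-average
ensemble. Consequences of this choice:

* the ensemble grows by one member per pulse — it starts at size 1;
* the forecast never needs restarting or ensemble inflation machinery:
  the forward model runs once, continuously, chained through the analysis
  states;
* every analysis step nudges the *current realization*, so the filter is
  also a physics-respecting regularizer of the trajectory.

### D regularization

At pulse `s = 1` the sample covariance is identically zero and the filter
would ignore the data. The forecast covariance is therefore regularized
as `p^f = (D + sum of deviation outer products) / s` with a diagonal `D`
(variance units, per velocity component). `p^f` equals `D` exactly at
`s = 1`, and the `D` contribution decays exactly as `1/s` (both are
asserted in the tests). `D` should be one to two orders of magnitude
larger than the expected velocity covariance: large `D` makes the filter
trust the data early (fast pull toward the observations, slower
convergence of covariance estimates), small `D` makes the filter trust an
essentially meaningless early forecast. The bundled defaults follow the
study configurations: `D = diag(1000)` for the cylinder twin experiment
and `D = diag(10)` for the channel.

### The voxel observation operator

Observed data live on cubic voxels whose edge is a multiple of the grid
spacing. The discrete operator `H` is node-counting: voxel `v` averages
its `g_v` member cell-center nodes with equal weights `phi_{v,g} = 1/g_v`
(each row of `H` sums to one). Membership uses *closed* intervals with a
relative tolerance of `1e-9 h`: a node exactly on a shared voxel border
belongs to all `v_g` adjacent voxels, and corrections coming from several
voxels are combined with interpolation weights `Psi_{g,v} = 1/v_g`.
Equal node weights (not volume weights) are a deliberate choice: voxel
data are modeled as plain node averages, and the tests pin this down with
arithmetic-mean oracles. A voxel containing no nodes raises an error
rather than being skipped — in practice it means a misconfigured window.

Two further design choices:

* **Collocation.** Velocities are interpolated from the staggered faces
  to cell centers before voxel averaging, so all three components are
  collocated the way measured voxel data are. The filter state is this
  center-collocated field; the analysis `u^a = u^f + k` is exact at the
  centers (and the analysis phase statistics are accumulated there),
  while the correction is transferred back to the staggered faces by the
  adjoint of the center interpolation. That transfer is a smoothing
  operator — on an even-sized periodic axis the center interpolation
  annihilates the Nyquist mode, so no face transfer can reproduce an
  arbitrary center correction exactly. Corrections produced by voxel
  averaging are smooth at the voxel scale, so the loss is immaterial in
  practice, but it is the reason exactness statements in the tests are
  made at the center level.
* **Per-voxel independence.** Cross-voxel observation covariance and
  cross-node forecast covariance are set to zero, so the gain collapses
  into independent 3×3 solves per voxel (`S_v` is symmetric positive
  definite whenever `D > 0`; a singular `S_v` raises instead of falling
  back to a pseudo-inverse, surfacing misconfiguration early). On
  disjoint voxels this block computation is *algebraically identical* to
  the dense state-space gain with block-diagonal covariance — a test
  asserts equality to 1e-10 against a dense oracle on 100 random
  instances. When nodes are shared between voxels the dense innovation
  covariance is no longer block diagonal and the `Psi` combination is an
  interpolation, not an identity; the shared-node behavior is covered by
  dedicated weight tests instead.

### The analysis update and incompressibility

The algebraic update `u^a = u^f + k` does not respect the discrete
divergence constraint, which the forward model assumes as a
precondition. By default the analysis state is re-projected onto the
divergence-free subspace after each update (`reproject = TRUE` in
`kalman_config()`); the projection is a small correction of the same
order as the update's divergence. It can be disabled to study the raw
update.

### Observation sampling modes

The per-update observation sample can be (a) the stored per-pulse sample
of the corresponding pulse, cycled modulo the recorded pulse count
(`"cycle"`, the default when samples are retained), (b) a Gaussian
perturbation `d ~ N(d_bar, r_v)` drawn per voxel (`"perturb"`, the
classical perturbed-observations form; the matrix square root is an
eigendecomposition with negative numerical eigenvalues clipped), or (c)
the phase mean itself (`"mean"`). All stochastic draws consume the seed
recorded in the run manifest; two runs with equal configuration and seed
are bit-identical (asserted in the tests).

## The forward model

The incompressible Navier–Stokes equations are discretized on a uniform
staggered Cartesian (MAC) grid — pressure at cell centers, velocity
components on their face families — with second-order central
differences in conservative form. Time integration is a three-stage
low-storage Runge–Kutta scheme (coefficients `gamma = (8/15, 5/12,
3/4)`, `zeta = (0, -17/60, -5/12)`) with a pressure projection per stage;
the Poisson problem is solved spectrally (FFT) on the periodic axes and
by a precomputed tridiagonal factorization across wall-bounded axes.
The x and z axes are always periodic; the y axis is wall-bounded
(no-slip: wall-normal faces pinned to zero, mirror-negated tangential
ghosts) or periodic. A quasi-2D mode collapses the span-wise axis to a
single periodic layer.

This second-order solver intentionally replaces the high-order
finite-difference/multigrid machinery of production DNS codes: the aim
is a forward model that runs validation cases on a single desktop CPU in
minutes while keeping the convergence order testable (the Taylor–Green
error decays with slope ≈ 2, asserted by grid refinement). Resolution is
raised where accuracy demands it; the full-scale cylinder run reproduces
the reference shedding period to better than half a percent.

**Fringe forcing.** Inflows, immersed objects and data-derived walls are
all imposed through the volumetric penalty `f = lambda(x) (U(x, t) - u)`,
active only inside the declared region. The target `U` may be a
constant, a profile, or a time-interpolated provider (used for pulsatile
inflow slices). With the stability-scaled option the rate becomes
`lambda = 1/(alpha_k dt)` at Runge–Kutta stage `k`, where `alpha_k` is
the stage's effective advancement fraction — the largest rate the
explicit scheme tolerates, which drives `u` to `U` in a single stage.
Fringe and bulk forces enter each stage weighted by `alpha_k dt` rather
than through the Adams–Bashforth-like combination of the transport
terms, precisely so that this identity holds. With constant rates
(cylinder: `lambda = 100` in the penalized disc, 50 in the inflow
region) the time step must satisfy `alpha_k lambda dt <= 2`; the bundled
configurations stay well inside that bound.

**Bulk constraint.** A constant bulk velocity (0.667 in the channel
case) is enforced by a uniform stream-wise shift after each projection —
the discrete equivalent of a spatially uniform pressure-gradient force.

**Time stepping.** Fixed `dt` (cylinder: 0.01 full scale, 0.015
reduced) or advective-CFL-derived `dt` (channel), with the final step
before each Kalman update shortened to land exactly on the phase time.

## Synthetic cases: what they emulate and what they do not

* `cylinder_case()` reproduces the confined-cylinder configuration
  (32h×2h channel, diameter-h cylinder at (9h, h), Re = 150, plug inflow
  by fringe with `lambda = 50`, cylinder by fringe with `lambda = 100`,
  N_phi = 20 phases, windows 1–6, D = 1000). The initial condition adds
  a small deterministic asymmetric pulse so the shedding instability
  saturates within a short spin-up instead of growing from rounding
  noise. Twin-experiment observations are extracted after spin-up —
  60 time units at full scale and 40 at reduced scale, scaled-down
  stand-ins for the much longer transients a production study would
  discard. The windows-2/3 split is implemented as equal x-halves at the
  cylinder center line.
* `channel_case()` reproduces the turbulent-channel configuration
  (4πh×2h×2πh, Re = 5000, bulk 0.667, Poiseuille start, windows 1–4,
  D = 10, 65³ nodes at full scale). Transition seeding uses seeded
  random solenoidal perturbations instead of Orr–Sommerfeld/TS modes:
  the assimilation runs never need the deterministic transition
  machinery (the filter itself forces turbulence), so only a generic
  symmetry-breaking perturbation is kept.
* `pulsatile_jet_case()` is a *synthetic* phantom emulating the pipeline
  structure of a measured valve flow: pulsatile jet at 70 beats/min in a
  cylindrical phantom, walls imposed as fringe regions built from
  zero-valued exterior data, inflow from the lowest data slices with
  linear time interpolation, and a 22-interval measurement schedule
  refined ×3 to 66 numerical phases. It is not a geometric or
  hemodynamic model of a real valve.
* `synthetic_channel_observations()` builds statistically steady channel
  observations from a Reichardt law-of-the-wall mean profile (friction
  velocity solved so the bulk matches the case constraint) plus seeded
  Gaussian fluctuations with a near-wall-peaked rms shape. It stands in
  for paper-scale ground-truth statistics in desk-scale runs: passing
  tests built on it demonstrate that the *filter pipeline* reconstructs
  a log-law mean and degrades gracefully with coarser voxels — not that
  the desk-scale forward model sustains real wall turbulence.

Problem sizes were chosen so the complete validation suite runs on one
CPU in well under half an hour: the full cylinder verification uses the
reference 257×33 grid (a few minutes), the twin experiments the 129×17
grid with 50 pulses, and the channel property runs a 24×32×12 grid with
50 assimilation cycles. The paper-scale channel quantities (TKE
stabilization near 0.55 m²/s², ≤ 5% downsampling loss at 65³ over 4000
time units) are long-running targets outside this envelope; the test
suite substitutes the property checks above, and the channel machinery
itself (windows, downsampling, steady-mode statistics) is exercised by
them end to end.

## Numerical details worth knowing

* **Poisson solve.** Eigenvalues of the discrete second difference are
  used (not continuum wavenumbers), so the projection is exact to the
  factorization tolerance; the wall-Neumann zero mode is pinned
  (`phi_1 = 0`), fixing the arbitrary pressure constant. Projection
  residual divergence is at machine precision, and projecting an already
  divergence-free field is the identity to the same precision.
* **Welford accumulation.** Phase moments are one-pass
  (mean/deviation-product updates); they match two-pass batch moments to
  1e-10 on 1e4 poorly conditioned samples, and are permutation
  invariant.
* **3×3 solves.** The per-voxel innovation covariances are inverted by
  an analytic adjugate, vectorized across voxels; `D > 0` guarantees
  positive definiteness, and a vanishing determinant raises.
* **Wall gradient.** The friction velocity uses a one-sided first-order
  difference from the first off-wall center (exact for linear shear);
  with `ny = 32` cells across `2h` the laminar closed form
  `Re_tau = sqrt(2 Re)` is reproduced to under 1%. The printed
  normalization chain of the source formula is typographically
  inconsistent; the implemented form `Re_tau = U_tau L_ref / nu` with
  `U_tau = sqrt(nu |<<du/dy>>| U_ref / L_ref)` is fixed by the laminar
  closed form.
* **Period estimation.** Shedding periods are measured from a wake probe
  by FFT with a Hann window and local parabolic interpolation of the
  log-power peak; on a 60-time-unit record this resolves the period to
  well under 1% despite the ~3% bin spacing.
* **TKE.** By default excludes the `D` term (it measures physical
  fluctuations); the `D`-inclusive variant exists for debugging.

## Known limitations

* Cross-voxel and cross-node covariances are structurally zero; flows
  whose correlation length exceeds the voxel size lose information the
  full-matrix filter would keep.
* Information propagates with the flow: a window that only covers the
  wake cannot reconstruct conditions upstream of an obstacle (the twin
  tests assert this failure mode rather than hiding it).
* The face transfer of the analysis correction smooths at the grid
  scale (see above); enhanced statistics should be read from the
  center-collocated analysis moments.
* No model-error term is carried: the forecast noise is turbulence only,
  so systematic forward-model bias (wrong viscosity, wrong boundary
  conditions) is not budgeted by the filter.
* Uniform Cartesian grids only; no curvilinear geometry, no
  fluid–structure interaction, no MRI noise model.
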