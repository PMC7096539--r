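---
title: "Methods: dynamics and numerics of the Epileptor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics and numerics of the Epileptor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model, the analysis procedures, and the numerical
and design choices behind `epidyn`. Code chunks are illustrative and not
evaluated at build time; every quantitative claim made here is recomputed by
the test suite or by `scripts/acceptance.R`.

## The model and its timescale structure

The Epileptor couples three timescales. Subsystem 1 (`x1`, `y1`) is the fast
population generating ictal fast discharges; subsystem 2 (`x2`, `y2`)
produces sharp-wave events on an intermediate timescale (`tau2 = 10`); the
permittivity variable `z` evolves at rate `r = 0.00035`, three to four
orders of magnitude slower than the fast variables, and carries the system
autonomously between the normal and ictal states. A sixth quantity `g`, the
exponentially filtered history of `x1`, feeds weakly (`0.002 g`) into
subsystem 2. The convolution definition of `g` is equivalent to the ODE
`dg/dt = x1 - gamma * g`, which is how the package integrates it: the
trajectory is identical and no history needs to be stored.

The piecewise nonlinearities create seams at `x1 = 0`, `x2 = -0.25` and
`z = 0`. The vector field is continuous across each seam (both pieces agree
there), but its Jacobian jumps; `model_jacobian()` therefore demands an
explicit side when evaluated exactly on a seam. The seam conditions are
taken exactly as written (`x1 >= 0`, `x2 >= -0.25`, `z >= 0` select the
second branch); because the field is continuous, the choice is
observationally irrelevant for integration.

Two forms of the slow equation are provided. The modified law (default)
adds `-0.1 z^7` inside the bracket for `z < 0`; the original law is linear
in `z` everywhere. Under the original law a trajectory started below the
saddle periodic orbit escapes to infinity — the integrator flags this
divergence (overflow guard at `|state| > 1e6`) rather than erroring, so the
comparison between the two laws is itself testable. Under the modified law
the same initial condition lands on the large-amplitude fast-slow limit
cycle (LC), the analogue of refractory status epilepticus.

## Parameters

All parameters are dimensionless; time is in the model's arbitrary units
(the fast oscillation period is of order one unit).

* `a=1, b=3, c=1, d=5` — subsystem-1 cubic/parabola coefficients; they fix
  the Z-shaped equilibrium curve. Changing them moves every closed form
  below, so they are exposed but rarely touched.
* `Iext1 = 3.1` — subsystem-1 drive; shifts the Z-curve vertically. The
  lower fold sits at `z(SN1) = c + (b-d)x_f^2 - a x_f^3 + Iext1` with
  `x_f = 2(b-d)/(3a)`, i.e. `Iext1 - 5/27` at the defaults.
* `m = 0` — the ictal control parameter: the slope of the linear part of
  the x1-nullcline. It decides how the fast oscillation dies (homoclinic
  for `m > 0`, SNIC or Hopf for `m <= 0` depending on `Iext2`) and, far
  negative, collapses the ictal oscillation into depolarization block.
* `a2=6, tau2=10, Iext2=0.45, gamma=0.01` — subsystem-2 shape, timescale,
  drive, and the `g` filter rate. Subsystem 2 has a SNIC at drive
  `2/(3*sqrt(3)) ≈ 0.385`: below it a stable node (resting state), above it
  a limit cycle (sharp-wave oscillation).
* `r=0.00035, s=4, x0=-1.6` — slow dynamics. `x0` is the excitability: it
  moves the z-nullcline across the bifurcation diagram and thereby selects
  which state (normal, ictal, seizure cycling) the slow flow stabilizes.

## Equilibrium analysis

The piecewise structure makes the frozen-z equilibrium equations polynomial
per branch, so subsystems 1 and 2 and the frozen-z fast equations of the
full model are solved *exactly* by root extraction (`polyroot`), with
branch-validity filtering afterwards. For the five-variable full system the
slow nullcline is inverted first (`z(x1)` is monotone because
`d/dz [z + 0.1 z^7] > 0`), reducing the problem to a bracketed scan over
`x1` (the `x1 < 0` equation is one-dimensional; the `x1 >= 0` equation is
scanned per subsystem-2 root branch), followed by damped-Newton polishing on
the reduced five-variable system. Residuals below `1e-10` are enforced;
duplicates are merged within `1e-8`.

Stability is read from the analytic Jacobian's eigenvalues with tolerances
`real_tol = imag_tol = 1e-7`: saddles have real parts of mixed sign with at
least one real unstable direction; a purely complex unstable set is an
unstable focus (the oscillatory instability of the upper branches); an
eigenvalue with `|Re| < real_tol` yields the class `"marginal"` rather than
a guess.

Two conventions for `g` in the algebraic analysis are exposed, because the
model's printed 5x5 Jacobian omits the `0.002 g` coupling entirely while
the simulated dynamics retain it:

* `g_convention = "omit"` (default): drop `0.002 g` from the equilibrium
  system and Jacobian. This matches the printed matrix and reproduces the
  equilibrium *counts* of the reference regimes (one saddle at
  `m = 0, x0 = -1.6`; three equilibria at `x0 = -0.9`).
* `g_convention = "stationary"`: substitute `g* = x1/gamma`, adding
  `0.2 x1` to the subsystem-2 drive and `0.002/gamma` to the `(x2, x1)`
  Jacobian entry.

The two conventions genuinely disagree in some regions (under "stationary"
the extra drive term can create additional subsystem-2 roots), and neither
reproduces every published classification simultaneously; the package
defaults to the printed convention and documents the difference here. At
strongly negative `x0` (normal state) the omitted `g` feedback is exactly
what stabilizes the subsystem-2 block, so the steady normal state is best
demonstrated dynamically (`classify_behavior()` on the full six-variable
flow) rather than through the reduced algebra.

Equilibria on the outer `x1 >= 0` branch — beyond the fold at
`z = max(X) + 4`, where `X` solves the quartic discriminant condition — are
excluded by default (`include_outer = FALSE`): the Z-curve analysis covers
the principal region only, and the outer branch consists of saddles and
unstable nodes that play no role in the seizure dynamics.

## Continuation and bifurcation identification

Bifurcation diagrams are built by *grid continuation*: the frozen-z (or
frozen-drive, for subsystem 2) equilibria are solved independently at every
grid point (default 801), classified, and linked into branches by
nearest-value matching with equal class. Saddle-nodes are detected as
equilibrium-count changes between neighbouring grid points and refined by
bisection on the exact per-branch solver (~45 steps, i.e. to near machine
precision in the control parameter); Hopf points as stability flips of a
focus, refined by bisection on its leading real part.

Limit-cycle envelopes integrate the fast equations at each frozen z from a
small offset (`+0.01` in `x1`) off the unstable focus, continuing from the
previous attractor where possible; transients are dropped and extrema,
mean and period measured over an integer number of periods (upward
crossings of the mid-range level). The termination of a cycle branch is
tagged:

* `HOPF` when the amplitude collapses (below 20 x the point tolerance
  `amp_tol = 1e-2`);
* `SNIC` when an equilibrium pair is born *on* the cycle across the
  termination: the equilibrium count jumps, the newborn equilibria lie
  inside the cycle's `(x1, x2)` band, and — decisive where a fold and a
  homoclinic share a window — a probe just past the refined fold finds no
  surviving cycle;
* `HOMOCLINIC` otherwise (finite-amplitude death at a pre-existing saddle;
  the period grows logarithmically, so any generous period cap suffices —
  the integration window extends up to 4000 time units before giving up).

`classify_sle()` assembles the seizure class. Onset is always the lower
fold; because the `x1 < 0` equilibrium equations do not involve `x2`, that
fold is exactly the subsystem-1 closed form `z(SN1)` for every `m` and
`Iext2`. The post-onset ictal evolution is emulated by continuing the fast
attractor upward in z from just below `z(SN1)` (120 rungs by default),
starting from the disappeared node's position; the offset type follows from
how the fast oscillation terminates (`HOMOCLINIC` -> fold/homoclinic,
`SNIC` -> fold/circle, `HOPF` -> fold/Hopf, never oscillatory ->
fold/fold), and the fold/fold case is flagged as depolarization block when
the upper plateau's nearest equilibrium is a stable node rather than a
focus. A regime whose full-model equilibrium set is not purely saddles is
reported as "no SLE" with the classes attached.

## Averaging

Periodic orbits of the slow-fast structure are located by the averaging
method: `<x1>(z)` is the cycle average of the frozen-z fast system, and the
slow averaged nullcline
`<z'> = r (s (<x1> - x0) - z - 0.1 z^7 [z<0])` has the periodic orbits as
its zeros, stable where `d<z'>/dz < 0`. The derivative is taken by central
difference over one grid cell, since `<x1>` is itself a numerical estimate.
Zeros are bracketed on the curve grid (default 400 points) and refined by
bisection to `1e-4` in z. Labels follow the orbit geometry: the lowest-z
stable zero is the large cycle LC, stable zeros above a saddle are small
cycles (SLC), unstable zeros are saddle orbits S.

Two numerical points matter here:

* **Step size.** At strongly negative z the frozen-z cycles are giant
  relaxation loops (`x1` excursions approaching 80, period ~17 time
  units) whose local rates reach `~3 a x1^2 ≈ 2e4`; the default simulation
  step 0.01 is outside RK4's stability region there. The averaging module
  therefore integrates at `dt = 0.005`, which is converged (halving the
  step again changes cycle means by under `1e-3`), and the direct
  slow-fast verification runs in the tests use `dt = 2e-4`.
* **z-range.** The averaged curve extends down to `z = -2.5` by default:
  the LC zero sits slightly below `z = -2` at high excitability (direct
  simulation of the fast-slow subsystem at `x0 = 1` settles with z
  oscillating around `-2.03`), so a `-2` cutoff would truncate the root.

The x0-sweep exploits linearity: `<z'>` depends on `x0` only through the
additive `-r s x0`, so one averaged curve serves every `x0`. A
saddle-node-of-periodic-orbits (SNPO) is a root-pair coalescence — the root
count changes by two — and is refined by bisection in `x0` to `1e-3`;
count changes of one are zeros entering or leaving through the ends of the
cycle branch and are not SNPOs.

## Behaviour classification

`classify_behavior()` integrates the full six-variable model (default 2500
time units, step 0.01, recording every 5th step), discards the first half,
and applies rules on the z-plateau and amplitude structure rather than on
phase-space geometry:

1. divergence flag -> `DIVERGENT`;
2. `x1` settled over the final fifth (range < 0.05) -> a fixed point:
   `NORMAL_STATE` if on the lower branch (`x1 < -0.5`), otherwise `DB`
   when the nearest frozen-z equilibrium is a stable node and
   `NONOSCILLATORY` when it is a focus — exactly the node/focus distinction
   between depolarization block and the nonoscillatory state;
3. long quiescent interludes (a 10-time-unit moving window of `x1` range
   below 0.2 sustained for >= 30 units) combined with a wide z excursion
   (> 0.3) -> an episodic regime, sub-typed by `classify_sle()`
   (`SLE_HOMOCLINIC` / `SLE_CIRCLE` / `SLE_HOPF` / `SWITCH_DB_NS` /
   `SWITCH_NONOSC_NS`);
4. otherwise sustained activity: a wide z excursion is the large cycle
   (`LC_RSE`); a narrow one is tonic spiking, `SLC_PERIODIC` when the
   interspike intervals are regular (CV <= 0.2) and `CHAOTIC` when they
   are not — the interspike-interval irregularity is the chaos diagnostic,
   no Lyapunov exponents are computed.

All thresholds are classifier settings exposed as arguments; they were
chosen once from the separation observed between the canonical regimes
(quiet runs in seizure cycling last hundreds of time units versus ~20 for
chaotic spiking; the large cycle's z excursion is ~0.7 versus ~0.01-0.08
for tonic regimes) and are not tuned per case.

## What the simulations do and do not show

Deterministic runs from the catalogued initial conditions demonstrate the
attractor structure: coexistence and basins (the saddle orbit S as
separatrix), the divergence of the original z-law, and the regime labels.
The stochastic mode (Euler-Maruyama, additive white noise of variance
0.0025 on the fast activity variables `x1`, `x2` by default — which
equations carry noise is a modelling choice, configurable) reproduces the
irregular recurrence of seizure-like events, but no noise-driven statistics
(escape times, seizure-duration distributions) are computed. The analyses
here characterize the model itself; nothing is fitted to EEG, and no
multi-node network coupling is included.

## Known limitations

* Grid continuation finds what the grid sees: branches narrower than one
  grid step, or bifurcations outside the default ranges (z in [-2, 6]),
  require a finer or shifted grid.
* The saddle periodic orbit S is established through the averaged slope,
  not Floquet multipliers.
* Near-degenerate regimes (e.g. large `m` at `Iext2 = 0`, where the
  homoclinic death approaches the onset fold) yield formally correct but
  fragile classifications; the seizure-class table is verified on the
  canonical regimes.
* The behaviour classifier assumes the run reached its stationary regime;
  very slow convergence (timescale `1/r`) may need a longer duration, which
  is why the nonoscillatory example is run for 6000 time units in the
  tests.

## Problem sizes used in the checks

The test suite and the acceptance script use deliberately modest problem
sizes — 161-801 continuation points, 120-400 averaging grid points,
simulations of a few thousand time units — chosen so that each analysis
converges well inside its tolerance (doubling any of them does not change a
reported digit at the compared precision).
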