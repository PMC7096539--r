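# epidyn

Simulation and bifurcation analysis of the **Epileptor**, a five-variable
phenomenological neural mass model of seizure dynamics. The package is aimed
at computational neuroscientists and dynamical-systems practitioners who want
to simulate the model, map its equilibria and periodic orbits, and classify
its seizure, refractory-status-epilepticus-like and depolarization-block
regimes over parameter space.

## The model

Two fast variables (x1, y1) generate ictal fast discharges, two intermediate
variables (x2, y2) generate sharp-wave events, and a very slow *permittivity*
variable z carries the system autonomously between normal and ictal states:

    x1' = y1 - f1(x1, x2) - z + Iext1
    y1' = c - d x1^2 - y1
    z'  = r (s (x1 - x0) - z - 0.1 z^7 [z < 0])
    x2' = -y2 + x2 - x2^3 + Iext2 + 0.002 g - 0.3 (z - 3.5)
    y2' = (-y2 + f2(x2)) / tau2
    g'  = x1 - gamma g

with piecewise nonlinearities `f1` (cubic for x1 < 0, linear with slope
`m - x2 + 0.6 (z - 4)^2` for x1 >= 0) and `f2` (threshold-linear at
x2 = -0.25). The `-0.1 z^7` term for z < 0 bounds the large fast-slow limit
cycle; the original linear z-law (selectable via
`epidyn_params(z_law = "original")`) lets trajectories started below the
saddle orbit diverge.

The package provides:

* **Simulation** — fixed-step classical Runge-Kutta and Euler–Maruyama
  integrators (compiled, seeded, with an overflow guard that flags divergence
  instead of crashing), for the full model, its two uncoupled subsystems, and
  the three-variable fast-slow subsystem.
* **Equilibria** — exact per-branch polynomial solutions for the subsystems
  and the frozen-z fast equations, a scan + Newton solver for the full
  five-variable system, eigenvalue stability classes, closed-form fold and
  Hopf points (`z(SN1) = Iext1 - 5/27`, `z(H) = 4 - sqrt((1 - m)/0.6)`,
  `m(H) = 1 - 0.6 (z - 4)^2`, the subsystem-2 SNIC drive `2/(3 sqrt(3))`),
  and sampled verification of the trace/determinant stability tables.
* **Continuation** — (z, x1) bifurcation diagrams by grid continuation with
  branch linking, saddle-node/Hopf detection refined by bisection,
  limit-cycle envelopes with Hopf/SNIC/homoclinic termination tags, and
  `classify_sle()`, which identifies the seizure onset/offset bifurcation
  pair (fold/homoclinic, fold/circle, fold/Hopf, fold/fold).
* **Averaging** — the Pontryagin technique for slow-fast periodic orbits:
  cycle averages `<x1>(z)`, the slow averaged nullcline `<z'>`, its zeros
  (the orbits LC, S, SLC) with stability from `d<z'>/dz`, x0 sweeps and
  saddle-node-of-periodic-orbits (SNPO) location.
* **Atlas** — per-point classification over the (m, x0) plane: equilibrium
  multisets, orbit sets, a rule-based behaviour classifier
  (seizure-like events, limit-cycle status-epilepticus analogue,
  depolarization block, normal state, chaotic spiking via the interspike-
  interval CV), and a figure-preset registry of caption-faithful run
  configurations.

## Worked example

Classify the seizure regime at the standard ictal parameters
(`m = 0.5`, `Iext2 = 0.45`, `x0 = -1.6`):

```r
library(epidyn)
p <- epidyn_params(m = 0.5)
find_equilibria("full", p)
#> <1 equilibria>
#> <equilibrium> saddle  residual=1.42e-13
#>   state: x1=-0.751163 y1=-1.82123 z=3.39535 x2=-0.202071 y2=0.287576

r <- classify_sle(p)
#> onset: SN at z = 2.9148
#> offset: HOMOCLINIC at z = 3.6054
#> bistable on [2.9148, 3.6054]
```

The unique equilibrium is a saddle, so the model cycles autonomously between
the normal and ictal states: onset through the lower-branch fold at
`z(SN1) = Iext1 - 5/27 = 2.9148`, offset through a homoclinic bifurcation at
`z = 3.605` — the fold/homoclinic seizure class. Lowering `m` to 0 changes
the offset to a saddle-node on invariant circle (`"CIRCLE"`, the fold/circle
class), and at `m = -8` with `Iext2 = 0` the ictal oscillation collapses into
a depolarization-block plateau (`classify_sle()$db` is `TRUE`).

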