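---
title: "Modelling TGF-β driven chondrogenesis in layered scaffolds"
author: "chondrosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TGF-β driven chondrogenesis in layered scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chondrosim)
```

## The biological problem

Cartilage implants are engineered by seeding mesenchymal stem cells
(MSCs) in a hydrogel scaffold and inducing them to differentiate into
chondrocytes. The inducing signal is transforming growth factor-β
(TGF-β), which reaches the MSCs from two sources: constitutive secretion
by chondrocytes co-seeded in an upper scaffold layer, and an exogenous
dose added to the culture medium above the scaffold. Both sources are
expensive — harvested chondrocytes are scarce and recombinant TGF-β
costly — so the design question is which combinations of seeding density
`n0`, layer depth `d` and dose `a0` actually trigger differentiation of
the whole MSC layer, and at what speed.

`chondrosim` answers this with a deterministic reaction–diffusion model
in one spatial dimension (the scaffold depth; lateral variation is
neglected, which describes the central region of a wide construct).

## Model structure and assumptions

Cell densities `m(x, t)` (MSCs) and `n(x, t)` (chondrocytes) do not
move, proliferate or die on the 1–10 day timescale of interest;
differentiation is the only cell process. TGF-β is tracked through a
simplified life cycle: unbound latent `c` (secreted by chondrocytes,
diffusing), matrix-bound latent `b` (stored in the hydrogel), and active
`a` (released by chemical activation of `b`, diffusing, short-lived).
Active ligand binds to a fixed number of identical receptors per cell;
the occupied fractions are `f` (MSCs) and `g` (chondrocytes). An MSC
commits to chondrogenesis when `f` exceeds the threshold `f_d`; the
committed cell carries its bound ligand into the chondrocyte pool, which
is why the state evolves the products `p = f m` and `q = g n` rather
than the fractions themselves.

Differentiation is a hard switch `H(f - f_d)` with `H(0) = 0`. A hard
switch is a deliberate idealisation of the graded dose–response of real
cells; it produces the sharp critical thresholds (`ncrit`, `acrit`) that
make the model useful for protocol design, at the cost of a
discontinuous right-hand side (see *Numerical choices*).

Reaction terms are applied over the whole domain, including the
cell-free medium `1 < x < 2`. For the cell-dependent terms this is
vacuous (they vanish where `m = n = 0`), but matrix binding (`λ̃₄`) and
activation (`λ̃₆`) formally operate in the medium too, where there is no
hydrogel. The governing equations are stated without spatial
restriction, and we implement them as stated rather than silently
masking the medium; the effect is small because latent TGF-β is secreted
only inside the scaffold and decays while diffusing.

## Parameters

All defaults are literature-derived representative values, stored
dimensionally (`default_parameters()`, units of minutes, ng and millions
of cells) and non-dimensionalised once at scenario construction
(`nondimensionalise()`); the solver never sees dimensional quantities.
The key dimensionless groups, on the differentiation timescale
`1/Λ₁ ≈ 2.78 h`:

* `λ̃₈ = 43` — active TGF-β decays 43× faster than cells differentiate
  (dimensionless half-life `ln 2 / 43 ≈ 0.016`). This separation of
  timescales is what makes depth penetration the limiting factor:
  the diffusion–decay length of active ligand is `√(D̃ₐ/λ̃₈) ≈ 0.03`,
  a few percent of the scaffold depth.
* `λ̃₃ ≈ 18.2` — chondrocyte secretion, the endogenous source strength.
* `λ̂m9 = 10`, `λ̃m10 ≈ 41.7` — receptor binding vs internalisation;
  occupancy equilibrates at `f ≈ 10a/(10a + 41.7)`, so the threshold
  `f_d = 0.01` corresponds to a sustained local active concentration of
  about 0.04 ng/mL.
* `f_d = 0.01` — the differentiation threshold; with the switch, the
  single most influential parameter for the critical curves.

The scales (`default_scales()`) are `A0 = 1 ng/mL`, `M0 = 1 Mio/mL`,
`L = 2.4 mm`; time in hours is recovered with `dimensional_time()`.

## Scenarios

`scenario_config(case, n0, a0, d, ...)` builds the three strategies:
layered co-culture without dose (case 1, `a0 = 0`), dosed pure-MSC
scaffold (case 2, `n0 = d = 0`) and the combination (case 3). Case 2 is
implemented as the `d → 0` limit of case 3, so one code path constructs
every initial state. Initial layers are indicator functions evaluated at
the grid nodes with the `H(0) = 0` convention, i.e. interfaces snap to
the nearest enclosed node; at the default `N = 200` the snapping error
is below half a grid cell (≈ 0.005 of the scaffold depth). Exogenous
TGF-β enters as a single initial dose of the active form only; periodic
replenishment, used in some experimental protocols, is out of scope.

## Numerical choices

* **Discretisation.** Vertex-centred uniform grid on `[0, 2]`,
  second-order central differences, ghost-node reflection for the
  no-flux boundaries. The discrete diffusion operator telescopes to zero
  under the trapezoidal quadrature, so mass budgets close at round-off
  on the discrete level.
* **Stiff integration.** `deSolve::lsoda` with a banded Jacobian: fields
  are interleaved per node, so all coupling lies within a half-bandwidth
  of 7. Tolerances default to `rtol = 1e-6`, `atol = 1e-9`; tightening
  them tenfold moves the final yield by less than `1e-4` (asserted in
  the test suite).
* **The switch.** The discontinuous `H` is integrated directly, as the
  model intends; `hmax = 0.05` caps the step so ignition of the switch
  cannot be stepped over. An optional ramp of half-width `eps_H`
  replaces the jump for robustness studies (and for smooth convergence
  tests); it defaults to off.
* **Degenerate states.** Fractions are recovered as `f = p/m` only where
  `m` exceeds an emptiness guard (`1e-9`), else 0 — division by a
  vanishing cell density is the model's only singularity. An adaptive
  integrator legitimately undershoots zero by an amount of the order of
  its permitted local error, so negatives within
  `max(1e-10, 100 atol + rtol · max(field))` of zero are clipped;
  anything beyond that bound signals genuine instability and aborts the
  run with a diagnostic rather than being masked. The bound is
  per-field because dose fields can be many orders of magnitude larger
  than cell densities.
* **t90 detection.** The yield `N(t)` is monotone, so the stopping time
  is located by the integrator's root finder on
  `N(t) - 0.9 N(0⁻)`; runs without a crossing terminate at `t_end = 20`,
  by which the system is typically close to steady state (the terminal
  `max |rhs|` is reported, not enforced).

## Outcome classification and critical searches

`classify_outcome()` labels a run `full` if `t90` was reached *or* if
the terminal receptor occupancy satisfies `f ≥ f_d` wherever MSCs
remain — such cells are already committed and differentiate beyond the
simulated horizon, and counting them mirrors how long-term outcomes are
read off in practice. `none` means the final yield is below a floor of
`1e-4` of the seeded MSC number; this floor is this package's
convention, since the boundary between "no" and "negligible"
differentiation is not otherwise defined. Everything between is
`partial` (typically a thin chondrocyte crust at the top of the
scaffold).

`find_critical()` brackets and bisects the full/not-full boundary:
linearly in `n0` (default tolerance 0.005 absolute) and in `log10 a0`
(default 2% relative), because the dose boundary spans orders of
magnitude. The monotonicity of outcome in `n0` and `a0` is validated
from the evaluation log, not assumed; a non-monotone log attaches a
warning. `phase_sweep()` classifies a grid of `(a0, n0)` pairs and
`synergy_region()` extracts the cells that achieve full differentiation
below both single-strategy critical values.

## Problem sizes used in tests

The shipped test-suite and the acceptance script reproduce, at the
model's native resolution `N = 200`: the critical seeding density at
equal layer heights (bisection to ±0.005), the critical dose and the
partial-regime yield ceiling for the dosed scaffold (log-bisection to
2%), the `t90` spot values of the thin-layer combined strategy, and the
diminishing returns of over-seeding and over-dosing in dimensional
hours. Property tests (conservation, budget closure, monotone outcome,
grid-refinement order) use smaller grids (41–161 nodes) and shorter
horizons where the property is resolution-independent; the smooth
convergence test uses grids whose refinement keeps the yield-support
edge on a node, since otherwise the moving quadrature endpoint
contributes a first-order error that masks the second-order stencil.

## What the simulations do and do not show

The model is deterministic and one-dimensional, with constant hydrogel
density and chemically driven activation only. It does not represent
cell proliferation or death, mechanically mediated TGF-β activation,
ECM deposition and remodelling, lateral transport, or replenished
dosing; quantitative predictions near the critical curves are also
sensitive to the literature-derived parameter values, for which no
uncertainty ranges are available. One documented consequence of the
hard switch and node-snapped layers: very close to the
full-differentiation boundary, a run's label can change with grid
refinement (the shipped example is the sparse thin-layer strategy at
`a0 = 2000`, which is full at `N = 200` but partial at `N = 400`).
Boundary-proximal classifications should therefore be checked at more
than one resolution, which `find_critical()`'s grid-independence test
does for the shipped critical values.
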