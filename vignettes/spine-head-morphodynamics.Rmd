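---
title: "Modeling dendritic spine head morphodynamics with a stochastic graph grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dendritic spine head morphodynamics with a stochastic graph grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedgg)
```

## The model

`spinedgg` simulates the growth of a dendritic spine head in two dimensions
as the interplay of three coupled subsystems:

1. **An actin filament network**, represented as a labelled directed graph.
   Each node is a coarse-grained object standing for `N_CG = 12` actin
   monomers (one object per 32.4 nm of filament, at the standard 2.7 nm rise
   per monomer). A node carries a position, a pointer toward the barbed end,
   a stored bend angle, and an occupancy record: how many of its monomers
   are in the ATP, ADP+Pi or ADP state, how many carry cofilin, whether an
   Aip1 or a CaMKII-beta is bound, and (for filament ends) a membrane
   attachment. Junction nodes additionally point to the first node of an
   Arp2/3-nucleated daughter filament.
2. **An enclosing membrane**, a counterclockwise simple polygon whose
   vertices evolve under a discretized squared-mean-curvature (Helfrich)
   energy and under reaction forces from attached filament ends.
3. **Well-mixed protein pools** (free actin in ATP and ADP form, Arp2/3,
   cofilin, CaMKII-beta, capping protein, Aip1) following linear
   synthesis/degradation dynamics, `dM/dt = I_M (+ I_S,M) - k_M M`,
   solved in closed form between events.

All change happens through *stochastic rewrite rules*: each rule matches a
small local motif of the graph (one to four nodes, a membrane vertex, or a
node pair), carries a propensity, and rewrites the matched subgraph when it
fires. An exact Gillespie direct-method scheduler draws the waiting time
from the total propensity and selects one concrete embedding per event; the
biochemical rules (polymerization, nucleotide turnover, binding reactions,
severing) and the biophysical rules (gradient-descent position updates,
thermal moves, membrane updates) all compete on a single shared clock.

### Units

Internally, length is measured in coarse-grained rest lengths
(`l0 = 32.4 nm`), energy in `kT` at 310 K, and time in seconds.
`resolve_params()` converts every laboratory-unit parameter once, up front.
Two tabulated mechanical constants required a unit interpretation: the drag
coefficients ("500 N s/m") are treated as SI drags, which makes the
explicit gradient-descent updates stable (the displacement per firing is
about 7% of the elastic deviation), and the membrane curvature modulus is
read as 5e-22 J per unit internal length (0.117 kT l0), which leaves the
membrane compliant relative to filament pushing.

### Mechanics

Adjacent objects interact through a 12-6 Lennard-Jones separation potential
with its minimum at the rest length and well depth `eps_LJ` (7.36e-16 J per
coarse-grained bond, about 1.7e5 kT; the alternative calibration from the
actin spring constant, `eps = k_s r_min^2 / 18`, gives the same order).
Below 0.75 of the rest length the repulsive core is replaced by its tangent
line so forces stay bounded (the clipped potential). Bending is a harmonic
angular energy `k_bend/2 (theta - theta_target)^2` per connected triple,
with target 0 along a filament and 70 degrees from parent to Arp2/3
daughter; cofilin occupancy divides the stiffness by up to five. The
membrane energy is `2 kappa sum_i g_i / z_i`, the polygonal quadrature of
the squared mean curvature built from unit-tangent differences.

Position updates are overdamped: a kinetic rule fires at `k_kinetic`
(0.35 per second) per eligible node and displaces it by
`-grad U / (zeta k_kinetic)` - a stochastic forward-Euler scheme whose
`k_kinetic -> infinity` limit is the deterministic force-balance ODE. The
buckling (radial) rules come in three mutually exclusive variants keyed by
filament degree (end, interior, branch); bending rules move either the
centre or an end of each triple. All analytic gradients and the
positive-semidefinite diagonal Hessian blocks are verified against central
finite differences in the test suite.

Thermal noise is a Metropolis-Hastings heat-bath chain: a Gaussian
displacement with covariance `2 kT / (zeta k_kinetic) H^{-1}` is drawn from
the node's diagonal buckling Hessian `H` and accepted with
`z/(1+z)`, `z = exp(-(dU - dUq)/kT) |H(x)|/|H(x')|`, where `dU` is the
local separation-energy change and `dUq` the difference of the quadratic
Taylor parts of the forward and reverse proposals. For a locally harmonic
energy this acceptance is exactly detailed-balanced; the test suite
verifies the stationary histogram against the Boltzmann density in that
regime and checks bond-length equipartition (`Var(r) U'' = kT` within 10%)
in an anharmonic well. Because the scheme is a local quadratic
approximation, its stationary law deviates from Boltzmann in *soft*
strongly anharmonic wells; at the model's own bond stiffness (~1e5 kT) the
well is harmonic to about 1% over the thermal range, where the
approximation is excellent. Proposals are suspended for nodes whose local
curvature is non-positive (beyond the potential's inflection), where a
Gaussian with the Hessian as precision is undefined.

### Membrane coupling

A barbed end whose segment, pseudo-extended by the overgrowth length
(0.5 l0), crosses a membrane edge is attached: a new vertex is inserted at
the crossing point (a collinear insertion, so the enclosed area is
untouched) and an attachment edge with the separation potential links end
and vertex. Each kinetic firing displaces one endpoint; summed over paired
firings the attachment imparts equal and opposite impulse - the filament
pushes the membrane outward, the membrane presses the filament back.
Elongation of an attached end is multiplied by the Brownian ratchet factor
`exp(-f delta / kT)` (load `f` = compressive attachment force projected on
the filament axis, `delta` = required insertion length), and steps
adaptively shorten when the membrane gap is sub-unit, with partial objects
carrying proportionally fewer monomers. Attachments whose end drifts beyond
twice the rest length are dropped; the inserted vertex is retained.

### Remodeling chemistry

The biochemical rules follow the tabulated per-monomer rate constants:
elongation propensity is the composition-weighted mixture of the ATP and
ADP on-rates divided by `N_CG` (one object added per firing), retraction is
the occupancy-weighted mean of the per-monomer off-rates, hydrolysis and Pi
release advance single monomers (Pi release is accelerated ~6x by adjacent
cofilin), Arp2/3 branches from cofilin-free interior nodes at ~70 degrees
with the side drawn uniformly, capping blocks barbed-end dynamics, cofilin
binds bare ADP segments slowly and cooperatively next to bound cofilin
(x2 when flanked on both sides), CaMKII-beta bundles non-adjacent node
pairs within 0.0175 um and 15 degrees, filaments break where the stored
bend angle exceeds the occupancy-dependent threshold (57/73/31 degrees for
bare/cofilactin/boundary sites), and Aip1 binds cofilactin and severs at
1.43 per second, leaving an Aip1-capped barbed end and a new pointed end.

Free monomers returned by depolymerization keep their nucleotide state, so
the ADP sub-pool is fed by turnover and newly polymerized objects sample
their state from the pool composition. The initial two-object seed filament
is taken to be aged (ADP) material, as a pre-existing filament would be.

## Design choices where the design was open

- **Scheduler**: full vectorised re-enumeration of all rule propensities at
  every step, rather than dependency-tracked partial updates. With
  struct-of-arrays state and vectorised enumerations the whole-population
  recomputation costs about a millisecond per event in R and eliminates an
  entire class of stale-cache bugs; instance validity is still re-checked
  at fire time.
- **Unprinted constants**: `k_comp = 45` (so that full cofilin occupancy
  multiplies debranching by the stated factor of 50 together with
  `sigma_comp = 4`); the ambiguous capping-protein off rate read as
  0.95 per second; breaking propensity of an angle-eligible site set to
  `k_kinetic`; Hessian regularizers `eps_sep = eps_ang = 1e-6`.
- **Aip1 turnover**: not tabulated. The default gives a 0.5 uM basal steady
  state - in the compartment's ~0.012 fL effective volume this is ~4
  discrete molecules; a smaller, seemingly innocuous choice (10-100 nM)
  rounds to *zero* molecules and silently deletes the mechanism. The
  capping-protein pool, whose synthesis rates *are* tabulated, sits below
  one molecule in this volume, so capping is essentially inert at this
  compartment size; the tabulated values are kept as printed.
- **Minimal filament**: retraction is disabled when a filament would drop
  below two objects, so the seed dimer persists; daughters must grow to two
  objects before they can debranch into a free filament.
- **Pool conversion**: effective volume = membrane area x 0.25 um slab
  thickness; binding propensities are `k_on N / (N_A V_eff)`.
- **Aspect ratio**: square root of the principal-moment ratio of the
  polygon's second central area-moment tensor (1 for a circle, 2 for a 2:1
  rectangle); a bounding-box definition would be orientation-dependent.
- **Elongation angle spread**: the semiflexible-polymer value
  `sigma_theta = sqrt(2 l0 / L_p)` = 0.0605 rad (3.5 degrees); a printed
  form without the segment length is dimensionally inconsistent.
- **Membrane energy**: the curvature term only; optional area/length terms
  are omitted (coefficient zero) to match the model's stated total energy.

## What the generator emulates, and what it does not

The synthetic initial condition - a 64-vertex circle of radius 0.125 um
(enclosed area 0.049 um^2, a realistic spine-head cross-section) with a
two-object seed filament and pools at the basal synthesis/degradation
steady state - reproduces the study conditions. Simulations here run at
desk scale (seconds of biological time, a few hundred objects); the full
study design measures at 20-25 s with 60 s horizons.

Two practical consequences are worth stating plainly. First, membrane
growth is ratchet-limited: an attached tip can only elongate after its
vertex has been pushed outward, which happens at the membrane kinetic rate,
so area growth is slow and local - a few percent over five seconds -
matching the ~20% over sixty seconds scale of the full model. Second, the
cofilin/Aip1 axis is gated by nucleotide aging: with Pi release at
0.006-0.035 per second, ADP-actin (the only cofilin substrate) is scarce on
short horizons, so cofilin and Aip1 barely engage within 5 s even at
tenfold synthesis. Short directional sweeps therefore resolve the Arp2/3
dose-response (branching acts immediately) but not reliably the
cofilin/Aip1 responses, which in the full-length design accumulate through
minutes of turnover. Passing short-horizon tests demonstrates the
machinery, not the long-run biology.

## Statistics

Parameter sweeps scale one species' synthesis rate over a log-spaced grid
centred on (or truncated at) the basal value, run replicate stochastic
simulations per dose, and measure the membrane phenotypes (enclosed area,
perimeter, aspect ratio) at the final snapshot. Trends are summarized by
the Pearson correlation against log dose and a one-sided
Jonckheere-Terpstra trend test whose sidedness follows the sign of the
correlation, mirroring the study's summary tables; the JT p-value uses the
tie-corrected normal approximation and is cross-checked against an
exhaustive permutation oracle on small fixtures. Double sweeps apply
`eta^k` to one species and `eta^(-qk)` to the other; the epistasis algebra
(`q` from the ratio of single-sweep slopes, the `mu/nu` change of variables
and its inverse) is provided as plain functions.

## Numerical choices and degenerate inputs

Waiting times and all samplers consume one RNG stream seeded from the
configuration, so trajectories are bit-reproducible. Stored bend angles are
updated incrementally when a firing moves or rewrites a neighborhood and
are read (not recomputed) by the breaking rule. The bending gradient's
`a -> 1` limit is evaluated by its finite l'Hopital value for a zero target
angle; at an exactly colinear triple with a nonzero target the direction of
steepest descent is undefined by symmetry and the zero vector is returned.
Coincident points raise a degenerate-geometry error. Membrane moves that
would self-intersect the polygon and position updates that would carry a
node beyond the membrane (plus the overgrowth tolerance) are rejected
without state change. Simulation sizes used in the tests - 5 s sweeps with
three doses and eight replicates, 1e4-sample distributional checks, 1e5
thermal proposals - were chosen to give three-standard-error resolution on
every asserted quantity.

## Known limitations

- Purely 2D; no spatial protein gradients (pools are well-mixed).
- The thermal chain is approximate in soft anharmonic wells (see above) and
  silent for nodes at non-convex local curvature.
- The squared-curvature membrane flow expands while it rounds (its energy
  scales inversely with size); containment of the area comes from the
  physical coupling, not from the membrane energy itself.
- Capping is inert at the default compartment volume (sub-molecule pool).
- Only the four modeled binding proteins plus capping protein; no
  profilin, formin or myosin.

## A worked example

```{r example, eval = FALSE}
params <- resolve_params()
res <- simulate_spine(params, seed = 1, t_end = 5, snapshot_every = 1)
res$morpho
check_state(res$state)
render_state(res$state, "spine.png")

sw <- run_sweep(params, species = "arp23", multipliers = c(0.1, 0.316, 1),
                replicates = 4, measure_time = 5, seed_base = 2026L)
sweep_stats(sw)
```
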