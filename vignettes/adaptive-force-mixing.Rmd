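---
title: "Adaptive buffered force mixing: model, thermostats, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive buffered force mixing: model, thermostats, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AdaptiveQMMM)
```

## The method

Hybrid QM/MM simulations describe a small reactive region with an expensive,
accurate model and the surroundings with a cheap force field. When molecules
are allowed to diffuse between the two descriptions (adaptive QM/MM), the
force errors at the QM-MM interface act like a spurious chemical-potential
gradient: molecules are systematically pumped from one region to the other,
and the local density around the reaction site drifts to unphysical values.

Adaptive buffered force mixing (AdBF) addresses this by running **two** force
evaluations per step and discarding the unreliable forces from each:

1. The system is partitioned into a **core** region, a **dynamical QM**
   region (core plus its surroundings), a **buffer** layer, and the **MM**
   remainder. Membership is re-evaluated every step from interatomic
   distances.
2. The **extended** evaluation treats dynamical QM + buffer as "QM"; only
   the forces on dynamical QM atoms are kept, so the QM-MM boundary error
   lives entirely inside the buffer and never touches the propagated QM
   forces.
3. The **reduced** evaluation treats only the core as "QM" (with an empty
   core it is a pure MM calculation); its forces propagate the buffer and MM
   atoms, so the MM region never feels the extended boundary either.
4. Forces switch **abruptly** per atom between the two evaluations -- no
   interpolation region. Abruptness costs energy conservation (see
   thermostats below) but avoids the bookkeeping and cost of transition
   regions, and does not measurably harm average structure or free-energy
   profiles.

Setting region radii appropriately recovers the other standard variants:
conventional QM/MM (`Conv`, fixed QM set, one evaluation), adaptive
conventional (`AdConv`, adaptive QM set, one evaluation, an energy-mixing
scheme), and unbuffered force mixing (`AdUF`, two evaluations, no buffer).
`runVariantStep()` and `runMD()` implement all four.

### Hysteresis

Each adaptive region uses an inner and an outer radius: an atom (or molecule)
must approach closer than `r_in` to join a region and retreat beyond `r_out`
to leave it. With `r_in = r_out` this degenerates to a plain cutoff. The
hysteresis suppresses rapid flicker of atoms sitting near a boundary, which
otherwise causes large fluctuations in the number of QM atoms (and hence
cost) and extra force discontinuities. `qmCountTrace()` re-labels a stored
trajectory under any radii, which is how the package quantifies the effect:
with radii (4.0, 4.5) A the per-molecule membership switch count on a
diffusive trajectory is far below the count at the midpoint cutoff
(4.25, 4.25) A.

One semantic point the construction leaves open is whether the "previously a
member" test of the hysteresis uses membership in the exact region or in any
enclosing region, and whether it is evaluated before or after whole-molecule
promotion. This package uses **post-promotion labels**, and counts membership
in the region **or any region nested inside it** (core counts as previous
membership for the dynamical QM test, and so on). Both choices keep the
region nesting `CORE` &sube; `DYN_QM` &sube; `DYN_QM` &cup; `BUFFER`
self-consistent under the per-molecule bookkeeping.

### Region construction order

Regions are built sequentially against the *current* step's geometry: core
from the fixed core list, dynamical QM around the core (plus the fixed QM
list; with an empty core the fixed QM list seeds the selection), buffer
around the dynamical QM region. A species filter (e.g. heavy-atom distances
only) restricts which distances are tested; whole-molecule promotion then
pulls each selected molecule wholly into the innermost region any of its
atoms reached. Only entire molecules switch description -- bond cutting
across the boundary is out of scope.

### Momentum correction

Mixed forces do not sum to zero. The correction subtracts the net force from
a configurable region, either uniformly or mass-weighted
(`momentumCorrectionSpec()`). The default is mass-weighted over all atoms:
the correction is then a rigid center-of-mass acceleration and does not bias
light atoms. A compensated final subtraction keeps `|sum F|` at machine
precision (below 1e-10 kcal/mol/A on every step in the validation runs).
Restraint and bias forces are added after mixing and *before* the
correction, so the correction sees the total dynamical force; this ordering
is a documented config behavior rather than a claim about other
implementations.

## The two toy force models

All electronic structure is out of scope; the "QM" and "MM" engines are two
deliberately mismatched classical models of a water-like liquid
(`defaultWaterLikeModel()`, `makeModelPair()`):

* molecules of one heavy (16 amu) and two light (1 amu) atoms, harmonic
  bonds (450 kcal/mol/A^2, 1.0 A) and angle (55 kcal/mol/rad^2, 104.52 deg);
* shifted-force Lennard-Jones between heavy atoms (well depth 0.20 kcal/mol,
  minimum at 3.2 A, cutoff 7.0 A), so both energy and force go continuously
  to zero at the cutoff;
* a short-range Gaussian heavy-light attraction between molecules
  (0.25 kcal/mol at 2.0 A, width 0.3 A) with a weak repulsive core, giving
  the liquid a structured first neighbor shell for the RDF-based checks.

The mismatch parameter `delta` scales model A's intermolecular well depths,
equilibrium distances, and cutoffs by `(1 + delta)`. This is a controlled
analogue of the chemical-potential difference between a QM and an MM
description of the same species: at `delta = 0` the models are bitwise
identical (every mixing pathway must then be exactly inert), while at
`delta = 0.5` the A-liquid wants to be substantially larger-grained than the
B-liquid it is embedded in, which drives the boundary instability the
buffer is designed to contain. The model has no fidelity to real water
thermodynamics and no charges; it exists to give the adaptive machinery a
liquid with realistic error structure at the mixing boundary.

In a composite evaluation, an intermolecular pair uses model A iff **both**
atoms are in the QM set; intramolecular terms use A iff the whole molecule
is inside. There is no cross-boundary combining rule -- the resulting force
mismatch at the boundary is exactly the error the buffer must bury.

## Adaptive thermostats

Force mixing makes the dynamics nonconservative: heat is generated near the
boundary and must be removed locally. The package implements two adaptive
thermostats, both coupled **per Cartesian degree of freedom** (massive
mode), since the heat generation is spatially localized.

**Adaptive Langevin** (`adLangevinThermostat()`): per DOF,

$$dq = (p/m)\,dt, \qquad
  dp = F\,dt - (\chi + \gamma)\,p\,dt + \sqrt{2\gamma m k_B T}\,dW, \qquad
  d\chi = \left(p^2/m - k_B T\right)/Q\,dt,$$

with $\gamma = 1/\tau_L$ and $Q = k_B T\,\tau_{NH}^2$. The Langevin part
guarantees ergodicity; the Nose-Hoover variable $\chi$ adapts the total
friction to absorb whatever net heat the mixed forces inject. In steady
state under heating, $\langle\chi\rangle > 0$ measures the absorbed heating
rate; with $\chi$ frozen the same run overheats. With $\gamma = 0$ the
scheme reduces to per-DOF Nose-Hoover; with the $\chi$ coupling removed it
is plain Langevin. The SDEs follow the standard adaptive-Langevin
construction -- a Langevin thermostat in parallel with a Nose-Hoover one --
with $Q$ fixed from the Nose-Hoover time constant by dimensional analysis,
and are validated against the construction's limiting cases.

**Adaptive Nose-Hoover-chains-Langevin** (`adNHCLThermostat()`): the
Langevin part is replaced by a chain $\xi_1 \dots \xi_r$ with optional
Langevin thermalization (friction $\gamma_l$) of the last variable;
$r = 1$ gives the adaptive Nose-Hoover-Langevin thermostat and
$\gamma_l = 0$, $r > 1$ the plain adaptive chain. Chain masses are
$Q_i = k_B T\,\tau_{NH}^2$. Equivalence with other implementations is
claimed only at the level of stationary statistics, not per-step
trajectories.

### Discretization

Each MD step is the palindromic splitting
$$B(h)\;[\chi\text{-}O\text{-}\chi](h)\;A(dt)\;[\chi\text{-}O\text{-}\chi](h)\;B(h),
\qquad h = dt/2,$$
where $B$ is the force half-kick, $A$ the drift, $O$ the exact
Ornstein-Uhlenbeck update with total friction $\chi + \gamma$ (so there is
no dt-dependent temperature bias from the noise integration; the formula
remains valid when $\chi + \gamma \le 0$), and the $\chi$ updates are
midpoint halves. An asymmetric variant with the full $[\chi,O]$ phase on one
side of the drift was measured to carry an $O(\gamma\,dt)$ configurational
bias (about 1.4% in $\langle q^2\rangle$ at $\gamma = 0.5\,\mathrm{fs}^{-1}$,
$\omega\,dt = 0.05$, growing linearly with $\gamma$); the palindromic
ordering restores second-order weak accuracy, and the package's harmonic
oscillator checks hold $\langle q^2 \rangle$ and $\langle p^2 \rangle$
within 2% at $\omega\,dt = 0.05$ over $10^6$ steps. Without a thermostat the
step reduces to velocity Verlet, which is how the conservative limit (total
energy drift below 1e-4 kcal/mol per atom) is checked.

A zero-velocity state is invariant under a pure Nose-Hoover chain (noise
enters only through the last chain variable, which acts on velocities
multiplicatively), so NHC runs start from Maxwell-Boltzmann velocities.

Randomness comes from R's RNG (also inside the C++ kernels, via R's own
generator), with a draw order fixed per step and independent of the method
variant. That makes runs bit-reproducible under `set.seed()` and makes
the delta = 0 identity across variants exact rather than statistical.
Counter-based per-DOF streams would decouple the noise from the number of
thermostatted DOFs; they were not needed for any property checked here.

### Defaults

`dt = 0.5` fs; thermostat presets `tauLangevin = tauNH = 200` fs (the
proton-transfer protocol) and `tauLangevin = 300`, `tauNH = 74` fs (the
hydrolysis protocol). The harmonic-oscillator validation runs use stiffer
couplings (`tau` of a few fs) purely for statistical efficiency at $10^6$
steps; they are sampling checks, not production settings.

## Collective variables and restraints

Two reaction coordinates with analytic gradients:

* **DRCN** (`drcn()`): difference of rational coordination numbers of an
  acceptor and a donor oxygen over an explicit hydrogen list, with the
  switching function $n(r) = (1-(r/r_0)^\alpha)/(1-(r/r_0)^\beta)$,
  $\alpha = 6$, $\beta = 18$, $r_0 = 1.6$ A. The removable singularity at
  $r = r_0$ (value $\alpha/\beta = 1/3$) is evaluated by series expansion
  within $|r/r_0 - 1| < 10^{-4}$. Which hydrogens enter the sums is not
  fully determined by the coordinate's published description; the package
  requires an explicit list and recommends the reactant-molecule hydrogens
  (four for a proton transfer between two waters), matching the
  proton-transfer picture. The list is configurable.
* **DD** (`distanceDifference()`): leaving-minus-attacking distance
  difference to a central atom, minimum-image, zero at the symmetric
  placement.

Restraints (`restraintForces()`): the umbrella bias
$U = (k/2)(x(\mathbf r)-x_0)^2$ on any CV, and one-sided harmonic distance
restraints that activate only beyond (or below) a threshold with forces
continuous there -- the construction used to keep reactants together
(25.0 kcal/mol/A^2 beyond 3.0 A between reactant oxygens, etc.).

## Umbrella integration

`windowGradient()` uses the first-order umbrella-integration estimator: the
mean bias gradient in a window equals minus the PMF gradient at the window's
mean CV value, $dF/dx(\bar x) = -k(\bar x - x_0)$. `assemblePMF()` sorts
windows by $\bar x$, integrates by trapezoid, anchors $F = 0$ at a chosen CV
value, and propagates window variances (block-averaged, independent-window
assumption) into pointwise 95% bands. `uiConfidenceIntervals()` offers a
block bootstrap instead; the analytic propagation is the default in
`assemblePMF()` and the bootstrap is the default for published-style error
bars, with outputs labelling the method. The full Gaussian (variance-based)
umbrella-integration refinement is deliberately not the default: the
first-order estimator is the documented protocol, and for the stiff biases
used here ($k = 400$ kcal/mol per CV unit$^2$) the window variance term is
negligible against the restraint curvature.

Window defaults mirror the validation protocol: 18% of each window is
discarded as equilibration (e.g. 1 ps of a 5.5 ps window), block size 1/20
of the kept samples.

The end-to-end check runs the whole pipeline -- MD with the bias, window
collection by `steeredSchedule()` (linear moves between centers, holds for
sampling), gradient estimation, assembly -- for one particle in the quartic
double well $U(x) = a(x^2-1)^2$, $a = 5$ kcal/mol, 13 windows on
$[-1.5, 1.5]$, and compares the recovered barrier against the same
umbrella-integration estimate computed by exact quadrature of each window's
biased Boltzmann density. Agreement is required within 0.25 kcal/mol. The
problem sizes used (120 ps per window at dt = 1 fs, samples every 10 steps,
Langevin tau = 10 fs) were chosen so the statistical error of the barrier
(~0.09 kcal/mol) sits well inside that band; dt = 1 fs is appropriate here
because the stiffest mode under the k = 400 bias has a period near 53 fs.

## Structural diagnostics

`rdf()` computes g(r) around a designated center atom -- the heavy atom of
the central dynamical-QM molecule, since the structure *inside* the QM
region is the quantity under test -- normalized by the partner species'
ideal-gas shell density. The cumulative neighbor count is computed by
direct counting per frame and then averaged, not by integrating g(r),
because sparse bins make the integral noisy at short simulation times.
`bufferConvergenceScan()` implements the protocol for choosing the buffer
radius: forces on tagged dynamical-QM atoms versus buffer radius, against a
large-radius reference evaluation, aggregated over independent
configurations. Two identities pin the scan down exactly: zero error at the
reference radius, and zero error at every radius when the two models are
identical.

## The synthetic test system

`buildWaterBox()` generates the study conditions: molecules on a jittered
cubic lattice with random orientations, Maxwell-Boltzmann velocities, and a
short capped steepest-descent relaxation under the MM model. The default
number density 0.0237 molecules/A^3 is the 93-molecule, 13.8 A reference
water box rescaled by the ratio of the toy model's heavy-atom equilibrium
distance (3.2 A) to the real water O-O peak (~2.8 A); a 93-molecule box then
has an edge of 15.8 A. What the generator does **not** emulate: hydrogen
bonding and its orientational structure, charges and long-range
electrostatics, real water's density and diffusion constants. Passing tests
therefore demonstrate the correctness and stability of the adaptive
machinery on a liquid with realistic short-range structure, not the
accuracy of any QM/MM electronic-structure model on real water.

The boundary-instability validation uses `delta = 0.5` on a 150-molecule
box: a reference run fully under model A, an unbuffered force-mixing run,
and a buffered one, all from the same MM-equilibrated start (1 ps), each
4 ps long with the cumulative neighbor count of the central molecule
averaged over the second half. Unbuffered mixing lets the compressed
A-description blow the dynamical QM region open (neighbor count below half
the reference); buffered mixing keeps the dynamical QM molecules in a
consistent A environment out to the buffer edge and preserves the count
within 20%. These thresholds characterize a qualitative instability and its
cure, on runs long enough (4 ps) that the depletion has visibly saturated.

## Numerical choices and degenerate inputs

* Orthorhombic cells only; minimum-image distances everywhere a selection
  or CV needs a distance. The distance API is vectorized C++ so a faster
  neighbor-list backend could replace it without touching callers.
* Units: A, fs, amu, kcal/mol; `kBoltzmann()` and `accelUnit()` are the only
  unit constants.
* Empty core region is allowed: the reduced evaluation is then a pure MM
  call (also the cheap path). An empty reference set simply yields an empty
  adaptive selection; the exported `hystereticSelect()` itself requires a
  nonempty reference.
* An empty momentum-correction region with a non-"none" mode is an error,
  as is a tagged scan atom outside the dynamical QM region, a region
  exceeding `maxExtendedAtoms`, and non-finite positions (reported with the
  failing step index).
* Ties and coincidences: coincident atoms make pair forces and CV gradients
  undefined and raise errors rather than returning NaN.

## Known limitations

* No electrostatics, Ewald summation, electrostatic embedding, or link
  atoms; whole molecules are the only switching unit.
* The energy of a mixed-force step is undefined by construction; only
  PMF-style free-energy methods (umbrella integration here) apply.
* O(N^2) pair evaluation: fine at the few-hundred-molecule validation
  scale, not tuned for large boxes.
* The NHC-Langevin integrator targets correct stationary statistics; its
  extended-system invariant in the conservative limit drifts at second
  order but is not exactly preserved.
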