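---
title: "A coarse-grained model of the axon plasma membrane and its skeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of the axon plasma membrane and its skeleton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmem)
```

## The model

The axon plasma membrane is organised by a distinctive submembrane
skeleton: actin rings wrap the axon circumferentially with a ~185 nm
axial period and are joined longitudinally by spectrin tetramers held
near full extension. `axonmem` implements a particle-based, implicit-solvent
coarse-grained model of this system — skeleton, two-leaflet lipid bilayer,
and membrane proteins — together with the diffusion analysis needed to ask
how the skeleton shapes lateral transport.

All computation uses reduced units: the length unit is fixed by the
spectrin bead spacing (`sigma = 5 nm / (2 * 2^(1/6)) = 2.227 nm`), the
energy unit by the reduced simulation temperature `kB*T/eps = 0.22` at
300 K (`eps ~ 0.118 eV`), and the time unit `t_s = sqrt(m sigma^2/eps)`
is calibrated a posteriori by matching the simulated lipid diffusivity to
an experimental value (`calibrate_timescale()`).

### Skeleton

* **Spectrin tetramer** — a chain of 41 beads joined by harmonic springs
  (`k0 = 6.5 eps/sigma^2`, rest length 5 nm, contour length 200 nm). All
  spectrin beads repel through a truncated Lennard-Jones potential of
  scale `2 sigma` cut at its minimum, so only the steric branch acts.
  `eps1 = 0.46 eps` makes the repulsion's curvature at contact
  approximately equal to `k0` (exactly matching `k0` would require
  `eps1 = 0.455`; the conventional rounded value is kept, leaving the
  curvature 1.1% above `k0`).
* **Actin ring** — a regular polygon of 39 beads of 35 nm diameter
  (ring diameter ~434 nm) with stiff springs (`kA = 69.35 eps/sigma^2`),
  the same truncated-LJ steric repulsion between all bead pairs, and a
  FENE bending potential about the interior angle `theta0 = 170.77 deg`
  (`kb = 3500 kB*T`, maximum deviation `0.3 theta0`) that diverges if the
  ring over-bends; an over-bent angle aborts the run with a diagnostic.
* **Actin–spectrin association** — a breakable shifted Lennard-Jones bond
  of depth `eps2 = 7.3 eps` (~0.86 eV) and scale `8 sigma`, minimum near
  20 nm. Beyond the capture distance `2.5 * 8 sigma` both energy and force
  are zero: associations break, and a free chain end re-associates with
  the nearest unoccupied actin bead that re-enters the capture radius
  (one chain end per actin bead).
* **Ring spacing** — microtubules and neurofilaments are not represented
  explicitly; their role in holding consecutive rings at 185 nm is played
  by a FENE potential on the difference of mean axial ring coordinates
  (`kmt = 239 kB*T/sigma`, maximum deviation 30%).

### Membrane

Each lipid particle is a ~2.5 nm cluster of lipids carrying a position
and a unit orientation vector. Same-leaflet pairs interact through an
orientation-dependent potential

    u = uR(r) + A(a) uA(r),      a = ni.nj - (ni.xhat)(nj.xhat),
    A = 1 + alpha (a - 1),       alpha = 1.55,

with `uR = k eps z^8`, `uA = -2 k eps z^4`,
`z = (Rcut - r)/(Rcut - req)`, `Rcut = 2.6 sigma`. With aligned normals
perpendicular to the pair axis (`a = 1`) the pair has a minimum of depth
`k eps` at `req`; anti-aligned normals turn the attraction repulsive,
which keeps each leaflet's orientation field coherent and the sheet
fluid. `k = 1.2` for lipid–lipid pairs; pairs involving a membrane
protein use `k = 2.8`. The printed parameter set specifies `k` only for
lipid–lipid and lipid–protein pairs; this package applies the
protein-class value 2.8 to every pair with at least one protein
(protein–protein and anchor–protein included), the simplest consistent
completion.

The two leaflets cohere through a short-range potential in the style of
solvent-free bilayer models: a repulsive Lennard-Jones core shifted by
`(1-k_layer) eps` joined at `2^(1/6) sigma` to a compliant `cos^2`
attraction of depth `k_layer eps = 0.01 eps` and width `wc = 1.3775
sigma`. The inner cutoff is not printed with the parameter set; the
value `2^(1/6) sigma` is the unique choice that makes the two branches
join continuously with zero slope, and is adopted here.

Monotopic proteins (IMPs) live in one leaflet; transmembrane proteins
(TMPs) sit at the mid-surface and interact with both leaflets. Towards
the skeleton, cytosolic domains give inner-leaflet IMPs and TMPs
effective sizes of 20 and 25 nm; these sterics use the same
truncated-LJ form with the contact distance equal to the sum of
effective radii (e.g. 30 nm between a TMP and an actin bead) and
strength `eps1` (the printed set names no strength for these terms).
Anchoring is by harmonic springs: ankyrin-linked TMPs to the 20th bead
of a spectrin chain (rest length 15 nm), actin-anchored proteins to an
actin bead (rest length 20 nm), and immobilised TMPs to fixed points
(`k0`, rest length 0).

The spectrin–lipid association (strength `n = 0, 0.02, 0.05`) is a
shifted Lennard-Jones of scale `1.5 sigma` truncated at `3.75 sigma`,
implemented exactly as specified including the `+n eps` shift — which
leaves a ~`0.98 n eps` step at the cutoff — and identically zero at
`n = 0`. Fidelity to the printed form was preferred over smoothing.

## Dynamics

Translations follow `m x'' = -dV/dx`; orientations follow the
constrained equation `m~ n'' = -(I - n n^T) dV/dn - m~ |n'|^2 n`, which
keeps `|n| = 1`. Internally the integrator carries the angular velocity
`omega = n x n'` (equation of motion `m~ domega/dt = n x (-dV/dn)`,
mathematically equivalent) and advances `n` by exact rotations, so unit
norm holds to machine precision without renormalisation. Both equations
are integrated by the velocity form of the Beeman algorithm with
`dt = 0.01 t_s`; all masses and pseudo-masses are 1 in reduced units
(the pseudo-mass `m sigma^2` equals 1 when expressed in the reduced
units themselves).

Temperature is controlled by a Nosé–Hoover chain of length two with
masses `Q1 = Nf T tau^2`, `Q2 = T tau^2` and a default time constant
`tau = 1 t_s`. Two choices here deserve comment, both made because the
plain single thermostat misbehaved on this system:

* A single Nosé–Hoover thermostat is weakly ergodic for quasi-harmonic
  systems. On the flat bilayer patch it steadily pumped kinetic energy
  into soft collective modes — most visibly the relative leaflet
  separation, whose restoring force comes only from the weak
  (`0.01 eps`) inter-leaflet coupling — until the leaflets unbound. The
  two-link chain suppresses this and holds the kinetic temperature
  within ~1% of target on every fixture tested.
* Rigid-body zero modes (centre-of-mass drift; whole-body rotation in
  free geometry; rotation about the axis on a cylinder) receive no
  restoring force and are therefore also vulnerable to thermostat
  pumping — a free chain otherwise spins up until centrifugal stretching
  dominates. While thermostatting, these modes are reset every 100 steps
  and excluded from the thermostat's degree-of-freedom count.

Rotational degrees of freedom are thermostatted by default (switchable),
and the thermostat is driven by the kinetic energy of the current
velocities rather than the Beeman-predicted ones, whose variance is
biased upward by the force fluctuations.

With the thermostat off (`ensemble = "nve"`) total energy is conserved
to well under `1e-4 eps` per particle per `1e4` steps after the
startup transient, and trajectories are bit-reproducible for a fixed
seed.

Neighbour search uses a cell list over membrane particles (cutoff
`2.6 sigma` plus a `0.4 sigma` skin, Verlet-style deferred rebuilds) and
a direct scan for the small number of skeleton-involving pairs, whose
cutoffs are larger but whose count is tiny in all fixtures.

## Builders and the synthetic systems

`build_spectrin_chain()`, `build_actin_ring()`, `build_apms()` (rings +
helical chains + associations + ring-spacing terms on an axially
periodic cylinder), `build_bilayer()` (flat doubly-periodic patch or
cylinder, near-hexagonal packing at the 2.5 nm lipid spacing, leaflets
separated by the inter-leaflet minimum, ±5% positional jitter to avoid
a crystalline start) and `place_proteins()` (random substitution of
lipids, reproducible under a set seed; optional anchoring) compose the
study systems. Defaults are the literature geometry: 41-bead chains,
39-bead rings, 185 nm ring period, 2.5 nm lipid spacing, reduced
temperature 0.22.

Because the spectrin contour (200 nm) exceeds the 145 nm gap between
association points, `build_apms()` lays chains out as shallow helices at
the ring radius with the 5 nm bead spacing preserved, the twist snapped
to the ring's angular grid so both chain ends start exactly at the
association minimum of a ring bead.

`build_axon()` composes the full system: the skeleton, a cylindrical
bilayer whose inner leaflet clears the rings by the 20 nm anchor bond
length, actin-anchored proteins embedded in the inner leaflet above
their actin beads (`add_actin_anchors()`), one ankyrin-linked channel at
the 20th bead of each spectrin chain (`add_ankyrin_channels()`), and
optional further proteins at a chosen surface density. At the default
full-size geometry this is the production-scale system (hundreds of
thousands of lipids — buildable here, but integration at that size is
cluster work); the test suite exercises a reduced fixture with smaller
rings and period and a correspondingly scaled steric range.

## Diffusion analysis

`unwrap_cylinder()` maps cylindrical trajectories isometrically onto a
plane (`u = r theta`, `v = z`), unwrapping the angle across the seam and
the axial coordinate across the period; radial displacement is
discarded, with a warning if radial fluctuations exceed 5% of the
radius. `msd()` computes time-and-ensemble averaged directional MSDs on
a log-spaced lag grid with overlapping origins, optionally after
removing per-frame collective drift (`drift = "per_type"` subtracts each
leaflet's centre of mass — the standard correction when leaflets can
slide coherently, which otherwise contaminates single-particle MSDs with
a quasi-ballistic collective term).

Four diffusion laws are fitted:

* normal: `MSD = 2 d D t` (least squares through the origin),
* confined: `MSD = L^2/6 (1 - exp(-12 D_micro t / L^2))`,
* confined-hop: the confined form plus `2 D_macro t`, `D_macro >= 0`,
* anomalous: `MSD = C t^alpha` by log-log least squares (by default
  excluding the first decade of lags, where short-time ballistic motion
  would bias the exponent).

The non-linear fits use Levenberg–Marquardt with positivity bounds and
data-driven starts (`D` from the early slope, `L` from the observed
plateau); the optimizer settings are deterministic. `select_model()`
implements residual-squared-norm selection. Because confined is nested
in confined-hop and time-averaged MSD noise is strongly correlated
across lags, the richer nested model is accepted only when it improves
the residual norm more than three-fold (`tie_tol = 2`); the nested
survivor then competes with the non-nested anomalous model on plain
residual norm. On synthetic curves at the noise level used in the test
suite this rule identifies the generating model in >= 90% of replicates
for all three families, while a plain minimum-residual rule mislabels
roughly half of the truly-confined curves as hop diffusion.

The confined saturation constant is `L^2/6` exactly as printed for the
reference analyses, also where the curve is a one-dimensional component;
the package follows that convention so fitted `L` values remain
comparable with the reference geometry reconciliations (e.g. stripe
width `L + 2 x 30 nm`).

`simulate_brownian_walk()`, `simulate_confined_walk()` and
`simulate_hop_walk()` generate planar reference processes with known
parameters; they are used by the test suite to validate estimator and
fitters, and are exported because they are equally useful for power
analyses of real single-particle-tracking setups.

## Problem sizes and what the tests show

The reference production system (~330,000 particles, 1e8 steps) is
cluster-scale. The packaged validations run desk-scale reductions: a
single 41-bead chain sampled for 1e6 steps after 3e5 steps of
equilibration, and a ~1,000-lipid doubly-periodic patch (24 x 24 sigma)
run for 1.2e5–2e5 steps. These sizes were chosen so the full suite
completes in minutes while each observable is sampled well past its
correlation time (the chain's end-to-end autocorrelation decays in
~1e4 steps; the lipid MSD is linear from ~50 t_s on, and its local slope
is flat to ~3% out to 2,500 t_s in a 5e5-step check).

Two quantitative discrepancies against the reference values are known
and deliberate, in the sense that the model is implemented exactly as
printed and the measurements are honest:

* The free spectrin chain equilibrates at an RMS end-to-end distance of
  ~49 nm, not ~75 nm. Two independent routes agree (Beeman/NVT dynamics
  and a pivot Monte Carlo sampler of the same energy function), and the
  freely-jointed limit of the sampler reproduces the closed-form
  `sqrt(N) b`. A chain of springs with contact-ranged repulsion has a
  persistence length of only ~2–3 bead spacings, so reproducing a 14 nm
  persistence length would need an explicit stiffening term that the
  printed parameter set does not contain.
* The patch lipid self-diffusion coefficient measures ~1.6–1.8e-2
  sigma^2/t_s, above the reference 1.14e-2. The value is
  thermostat-insensitive here (NVE continuation gives the same slope),
  stable across seeds once leaflet-sliding drift is removed, and only
  weakly density-sensitive (-15% for an 8% denser packing), so the gap
  most likely reflects unprinted details of the reference dynamics
  (thermostat implementation and masses) to which absolute diffusivities
  in implicit-solvent models are notoriously sensitive. The reduced
  time unit is calibrated against experiment through exactly this
  coefficient, so relative diffusivities (protein vs lipid) are the
  robust quantities.

Passing tests therefore demonstrate internal correctness — energy
conservation, force/gradient consistency, estimator calibration,
parameter recovery — and reproduce the closed-form calibrations; they do
not by themselves certify the two stochastic reference values above, nor
behaviour of the full cylinder at production scale.

## Known limitations

Single lipid species per leaflet, no electrostatics, no explicit
solvent, no rafts, no mechanical stretch, no explicit microtubules (the
ring-spacing term stands in for them). The flat free-standing patch is
marginally bound in the transverse direction (inter-leaflet coupling
0.01 eps), so very long patch runs show slow relative-leaflet motion;
in-plane observables are unaffected, and the cylinder geometry with
anchoring does not exhibit the mode. The unwrap approximation degrades
if radial fluctuations exceed ~5% of the cylinder radius, where the
package warns.
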