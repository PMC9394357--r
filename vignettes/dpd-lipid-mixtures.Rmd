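---
title: "Coarse-grained DPD simulation of two-component lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DPD simulation of two-component lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdmix)
```

## The model

`dpdmix` simulates the self-assembly of a binary mixture of single-tail
lipids in water with dissipative particle dynamics (DPD). Each lipid is a
linear chain of soft beads: a hydrophilic head block (`H1` or `H2`,
default 3 beads) followed by a hydrophobic tail block (`T1` or `T2`, 2-10
beads); water is a single bead `W`. All quantities are in reduced units:
bead mass, the interaction cutoff $r_c$ and the thermal energy $k_BT$ are
1, so the time unit is $\tau = \sqrt{m r_c^2 / k_BT}$. For reporting, the
conventional mapping for lipid-water systems at bead volume 0.03 nm$^3$
is $r_c \approx 0.5$ nm and $\tau \approx 1.88$ ns
(`physical_units()`); the mapping is metadata only and never enters a
computation.

Beads interact through three pairwise forces inside the cutoff. With
$w(r) = 1 - r/r_c$ and $\hat e$ the unit separation vector:

* conservative soft repulsion $F^C = a_{ij}\, w(r)\, \hat e$,
* dissipative friction $F^D = -\gamma w^2(r) (\hat e \cdot v_{ij})\hat e$,
* random kicks $F^R = \sigma w(r) \zeta \Delta t^{-1/2} \hat e$ with
  $\zeta \sim N(0, 1)$ drawn once per pair per force evaluation and
  applied antisymmetrically.

The thermostat pair obeys the fluctuation-dissipation relation
$\sigma^2 = 2\gamma k_BT$ ($\sigma = 3$, $\gamma = 4.5$), which makes the
pair friction and noise act as a momentum-conserving thermostat at
$k_BT = 1$; `interaction_model()` warns when the relation is broken.
Chain connectivity adds a harmonic bond force
$F = k_s (1 - r/r_s)\hat e$ ($k_s = 120$, $r_s = 0.7\,r_c$) and a
bending potential $U = k_\theta (\theta - \theta_0)^2$ ($k_\theta = 6$,
$\theta_0 = \pi$) on every consecutive bead triple, including the triple
spanning the head-tail junction.

The repulsion matrix (`default_interaction_matrix()`) uses $a = 25$
between compatible beads (like-like pairs, head-water, head-head across
types) and $a = 100$ between incompatible ones (tails against anything
unlike). Through the linear Flory-Huggins mapping
$\chi = 0.286\,(a_{ij} - a_{ii})$ the unlike pairs sit at
$\chi \approx 21.45$, deep in the strongly segregated regime - strong
enough that tails expelled from water assemble into bilayers.

## Integration

`dpd_run()` advances the system with the Groot-Warren modified
velocity-Verlet scheme: positions are updated with the current forces, a
predicted velocity $\tilde v = v + \lambda \Delta t f$ enters the force
recomputation (the dissipative force sees $\tilde v$; the random force is
redrawn), and velocities are corrected with the mean of old and new
forces. The scheme's $\lambda$ is not fixed by the model; the package
defaults to the standard $\lambda = 0.5$ and exposes it as a
configuration field. The time step is $\Delta t = 0.01\tau$.

Neighbour search uses a cell list with cell edges $\ge r_c$ under full
periodic boundaries, rebuilt every step; there is no Verlet skin, so no
stale-list hazard exists and the force evaluation is bitwise reproducible
given a seed. The engine is compiled (C++ via Rcpp) with its own seeded
xoshiro256++ / polar-method Gaussian stream, so a `(configuration, seed)`
pair reproduces a trajectory exactly on one worker. Two numerical
safeguards handle degenerate geometry: exactly overlapping pairs (legal
under soft repulsion) receive the $r \to 0$ force magnitude along a
deterministic pseudo-random direction and are counted in the run output,
and the bending force is set to zero when $\sin\theta < 10^{-8}$ (the
gradient of $\cos\theta$ itself vanishes at $\theta = \pi$, so the limit
is exact for straight chains).

Per-bead energies are reported alongside the trajectory: kinetic
$\sum v^2/2N$, pair $\sum (a r_c/2)(1 - r/r_c)^2/N$, bond
$\sum (k_s r_s/2)(1 - r/r_s)^2/N$ and angle
$\sum k_\theta(\theta - \theta_0)^2/N$. The reported total *includes*
the kinetic term: an equilibrated pure-water box at these parameters sits
near 6.05 $k_BT$ per bead (about 1.5 kinetic + 4.55 pair), which is the
scale on which the stable-stage energies of the lipid systems are quoted.
In lipid systems the bonded terms add a further equipartition offset
(about $0.5\,k_BT$ per bond and $1\,k_BT$ per angle, i.e. a few tenths
per bead at the study compositions), so the kinetic + pair part of the
total is the component that stays near the pure-water value across
compositions - the energy breakdown keeps all four parts separate so
either view is available. The kinetic temperature diagnostic removes the
centre-of-mass velocity before averaging.

## Starting configurations

The study conditions begin from an *unmixed layered bilayer*
(`layered_bilayer_init()`): all type-I chains stand in the upper leaflet
(heads up), all type-II chains mirrored below, each leaflet on a jittered
square lattice (jitter at most 0.2 of the spacing - enough to break
symmetry, small enough to stay "layer-like"). Chains are built straight
at bond length $r_s$ with angles at $\theta_0$, so the short initial
relaxation stage emerges from the dynamics rather than from the
construction. Water fills the box outside the lipid slab - never inside
it, to avoid trapped solvent in the unmixed start - and velocities are
Maxwellian at $k_BT = 1$ with the total momentum removed.

Three further builders support the analysis battery: `random_init()`
(persistent random-walk chains dispersed in water),
`perforated_fixture()` (a layered bilayer with a cylindrical hole, the
displaced chains redistributed over the remaining leaflet area, water
filling the pore) and `vesicle_fixture()` (a closed spherical bilayer
with heads facing both water compartments, chain directions on Fibonacci
lattices). The two fixtures are *geometric test beds* for the pore and
classification analytics, not equilibrated structures, and are named
accordingly.

## Observables

* `density_profile()` / `radial_density_profile()` bin beads per species
  with exact count conservation; the default bin width of 0.5 $r_c$
  balances profile smoothness against counting noise.
* `membrane_thickness()` is the distance between the outermost
  half-maximum crossings of the total head-bead density along the
  normal, with linear interpolation between bins. The convention is a
  package choice (the quantity is often quoted without a definition);
  the profile must show the two head peaks of a bilayer, otherwise `NA`
  is returned. Because membranes drift and undulate, a profile averaged
  over a long trajectory window smears and can lose the two-peak shape
  altogether, so the stable-stage summaries measure each frame
  separately and average the per-frame thicknesses
  (`thickness_timeseries()`); a buckled membrane still inflates the
  per-frame apparent thickness, which is flagged in the limitations
  below.
* `order_parameter()` computes $P_2 = (3\cos^2\theta - 1)/2$ of the
  end-to-end vector of the selected sub-chain (head block, tail block or
  whole chain) against the membrane normal, binned by the sub-chain's
  first bead. The end-to-end choice is the simplest vector that recovers
  the analytic limits (1 parallel, $-0.5$ perpendicular, 0 isotropic).
* `gyration_chains()` computes per-chain gyration tensors after
  unwrapping each chain across the periodic boundaries (walking bonds
  with minimum-image displacements - required, or boundary-straddling
  chains acquire spurious spans). `shape_factor()` maps the sorted
  eigenvalues to $\delta \in [0, 1]$ (0 sphere-like, 1 rod). The
  ensemble summary $\langle\delta\rangle$ (`mean_shape_factor()`)
  averages the eigenvalues over chains and frames *before* combining
  them - the literal reading of the ensemble-averaged formula; the mean
  of per-chain $\delta$ is the companion distribution view and sits a
  little lower because the formula is concave in the small eigenvalues.
* `leaflet_mixing_counts()` assigns each chain to a leaflet by the sign
  of (mean head $z$ $-$ mean tail $z$); chains lying flatter than
  `min_tilt` (0.35 $r_c$, half a bond) are reported unassigned rather
  than forced - these are typically pore-rim chains.
* `pore_detect()` projects tail beads on an $x$-$y$ grid (1 $r_c$ cells)
  and flood-fills empty cells with periodic connectivity; empty regions
  under 4 cells are ignored as thermal voids and the pore diameter is
  $2\sqrt{A/\pi}$.
* `classify_structure()` labels a frame membrane / perforated membrane /
  vesicle / other: a tail aggregate that percolates the periodic
  $x$-$y$ plane is a membrane (perforated when a pore is found); a
  non-spanning aggregate enclosing a water pocket disconnected from the
  bulk (coarse 3-d water-occupancy grid, 1.5 $r_c$ cells) is a vesicle.
* `stage_segmentation()` splits an observable series into the three
  regimes seen in self-assembly runs - initial relaxation, adjustment,
  stable - by an exact least-squares two-change-point fit on a
  running-mean smoothed series (window 50 records by default, clamped to
  a third of the series). A series whose best split explains less than
  1% of the variance is flagged degenerate and split at thirds rather
  than returning arbitrary boundaries.

## Interfacial tension

`pressure_tensor()` evaluates the Irving-Kirkwood diagonal components
$p_{\alpha\alpha} = \frac{1}{V}\big[\sum_i m v_{i\alpha}^2 +
\sum_{i<j} F_{ij,\alpha}\, r_{ij,\alpha}\big]$ and the tension
$\sigma_z = p_{zz} - (p_{xx} + p_{yy})/2$ (normal minus mean
tangential). For slab profiles each pair contribution is spread along
the straight minimum-image segment between the two beads in proportion
to the length inside each slab (the Irving-Kirkwood contour), which
makes the slab decomposition sum *exactly* to the whole-box virial - a
tested identity. The kinetic term is binned at the bead.

Which force classes enter the virial was a genuinely open choice. The
default is the non-bonded pair (conservative) force only: that is the
pairwise force of the DPD equation of motion, and its profile shows the
bilayer signature - $\sigma_z$ statistically zero in bulk water,
near-zero inside the membrane, with pronounced extrema at the two
head-water interfaces. Adding the intramolecular bond and angle forces
(`include_bonded = TRUE`; the three-body angle term is decomposed into
its two bond legs before localization) overlays the large axial
chain-elasticity stress of the oriented tails, which fills the membrane
core and swamps the interfacial structure; it is available because the
total mechanical stress needs it. The dissipative and random forces
average to the thermostat's momentum flux and only add noise at
equilibrium; they can be switched on (`include_thermostat = TRUE`) for
diagnostics.

`tension_near_pore()` restricts the virial path fractions and kinetic
terms to a lateral $y$-window (default $7 \le y \le 17\ r_c$), averaging
over $x$ only, for profiles across a pore. `tension_timeseries()`
averages $\sigma_z$ over the "membrane domain" - the z-slabs where total
lipid density exceeds half its plateau, determined on the stable stage
and reported as an attribute - and groups frames by dynamics stage.

## Study conditions and problem sizes

The full-scale conditions are a $30^3\,r_c$ box at bead density 3
($N = 81{,}000$), $n_1 = n_2 = 900$ chains (one chain per $r_c^2$ of
leaflet area), heads fixed at 3 beads, tails varied from 2 to 10, and
300,000 steps; `full_preset()` carries exactly these numbers, and the
phase sweep (`sweep_phase_grid()`) can run them when that compute is
available. Routine work uses `reduced_preset()`: a
$15 \times 15 \times 30\,r_c$ box ($N = 20{,}250$) with chain counts
scaled by the area ratio ($n_1 = n_2 = 225$, preserving the leaflet
packing) and 60,000 steps - local observables (thickness, order, chain
shape, per-bead energy) converge at this patch size because they are set
by the packing, not the patch area. The membrane runs of the test
suite and of `scripts/acceptance.R` use the reduced preset as is; the
short-tail (NT = 5/6) companion runs are trimmed - to a
$12 \times 12 \times 24\,r_c$ patch with 40,000 steps in the suite and
to 50,000 steps in the reproduction script - because their chain-level
observables plateau well before the full preset length.

What the reduced patch does *not* reproduce: outcomes that depend on the
box scale or on very long runs - the full $9 \times 9$ phase diagram,
absolute vesicle diameters, exact leaflet mixing counts, the pore-growth
time course and stage-resolved tension magnitudes. These remain available
through the full-scale configuration; the reduced runs cover their
qualitative signatures (interfacial localization of $|\sigma_z|$, stage
ordering of energies, classifier labels).

Two desk-scale artefacts deserve naming. At the fixed packing of one
chain per $r_c^2$ the bilayers are laterally compressed and buckle in a
small periodic patch, which inflates the laterally averaged apparent
thickness; the effect is mild for the long-tail membrane but pronounced
for the short-tail (NT = 5/6) system, whose apparent thickness at desk
scale overshoots full-scale reference values noticeably. And the
short-tail system is still reorganising at the end of a 60,000-step
(600 $\tau$) run - at full scale its stable stage only begins near
2000 $\tau$ - so its desk-scale geometry should be read as a
mid-assembly snapshot, not an equilibrium structure. Chain-level
observables (shape factor, order parameter, per-bead energy) are
insensitive to both artefacts and transfer across scales.

A note on the synthetic starts: the layered builder emulates the
experiment-like unmixed initial condition, but real preparations vary in
ways the seed parameter only caricatures (the study family of "different
layer-like inputs" is represented by the jitter seed). Passing tests on
these starts demonstrates correctness of the machinery and
reproducibility of the scaled-down phenomenology, not agreement with any
particular experimental preparation.

## Design choices that were genuinely open

* **Energy convention.** Whether quoted per-bead totals include kinetic
  energy is ambiguous in parts of the literature; the package includes
  it, because stable-stage totals near 6 $k_BT$/bead are only consistent
  with a kinetic-inclusive per-bead convention (a pure water box already
  sits at 6.05).
* **Leaflet assignment** uses chain orientation rather than position
  relative to a fitted midplane: it is parameter-free, exact for intact
  bilayers, and degrades gracefully at pore rims (unassigned, reported).
* **Pore noise floor** of 4 grid cells at 1 $r_c$ spacing ignores
  transient thermal voids; with roughly 6 tail beads per projected cell
  at the study packing, a false 4-cell void is vanishingly rare.
* **Stage boundaries** are fitted, never hard-coded; reference boundary
  values from full-scale runs serve as regression context only.
* **Virial force classes.** The stress excludes thermostat forces by
  default (standard equilibrium reading); the switch exists because the
  instantaneous momentum flux is occasionally useful when debugging
  thermostat artefacts.

## Known limitations

Single-tail linear lipids only (no branched/charged species, no
electrostatics); NVT only (no barostat, so membrane area per lipid is set
by the box, not self-adjusted); classification operates on occupancy
grids and can mislabel structures far from the three reference
morphologies (label `other`); tension profiles use the Irving-Kirkwood
contour - other localizations (e.g. Harasima) would distribute the same
total stress differently.
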