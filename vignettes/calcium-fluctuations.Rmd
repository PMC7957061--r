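---
title: "Modeling spontaneous NCX-driven calcium fluctuations in astrocytic leaflets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spontaneous NCX-driven calcium fluctuations in astrocytic leaflets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfluct)
```

## The scientific question

Perisynaptic astrocytic processes (PAPs, "leaflets") are sheets a few tens to
a few hundreds of nanometres thick that wrap synapses. Their surface-to-volume
ratio (SVR) is enormous — 20–25 per micrometre is typical — so a handful of
ions crossing the membrane translates into large relative swings of the
cytosolic concentration. The sodium–calcium exchanger (NCX) sits close to its
thermodynamic equilibrium at resting conditions and therefore flickers between
forward (Ca^2+^ extrusion) and reverse (Ca^2+^ entry) operation. `calfluct`
implements a voxel-resolved stochastic model of this machinery to ask: in
realistic tripartite-synapse geometry, when do spontaneous high-frequency
(100–500 Hz) Ca^2+^ fluctuations emerge, and how do they depend on leaflet
SVR and on the astrocytic Na^+^ set point?

The package has five working parts: voxel morphometrics, a synthetic geometry
generator, Markov transporter kinetics, a discrete-particle engine, and a
spectral/statistical readout layer. Each is described below with the design
decisions that were genuinely open.

## Voxel geometry and morphometrics

A sample is a `label_volume()`: a 3D integer grid with one compartment per
voxel (ECS, astrocyte, bouton, spine, dendrite shaft, other), an anisotropic
pitch — by default 6 × 6 × 30 nm over 201 × 201 × 41 voxels, i.e. a
1.2 μm cube at serial-EM resolution — and voxel-corner-anchored, half-open
physical coordinates.

**ECS fixation correction.** Chemically fixed tissue under-represents the
extracellular space. `apply_ecs_correction()` erodes every cellular segment
by 6 nm and relabels the shell as ECS. Erosion acts in the imaging plane
only: the 30 nm axial pitch exceeds the 6 nm shrink distance, so eroding a
whole z-layer would over-correct. Voxels at the sample boundary are treated
as continuing outside it and are not eroded.

**Surface and SVR.** The astrocytic surface is defined by 6-connectivity:
every astrocyte voxel face exposed to a differently labelled in-sample voxel
contributes its anisotropic face area; faces on the sample boundary are not
counted (the process continues outside the sample). SVR is exposed area over
segment volume, in 1/μm. Two properties of this estimator matter and are
tested:

* an axis-aligned slab of thickness *t* is measured *exactly*, SVR = 2/*t*;
* any curved surface is over-estimated by the Manhattan factor — summing
  axis-aligned projections gives 3/2 of the true area for an isotropically
  oriented surface, independent of pitch. A voxelised sphere of radius *r*
  therefore converges to 1.5 × 3/*r*, not 3/*r*. This is inherent to
  pixel-count surface definitions (including the one this package mirrors)
  and is the reason the generator calibrates geometry against *measured*
  SVR rather than analytic shell formulas.

**Coverage.** Astrocytic coverage of the bouton or spine is the fraction of
its surface voxels that reach an astrocyte voxel within a contact distance
along face-connected paths through the ECS. The literature gives no numeric
definition of "close contact"; the default here is 12 nm (two in-plane ECS
voxels), which is the regime that remains after the ECS correction removes
direct membrane apposition. The distance field is an anisotropic chamfer
relaxation restricted to the ECS mask.

**Synapse selection.** `select_synapses()` applies the five-criterion
filter — excitatory axon, terminal present, not multi-synaptic, spine
target, astrocytic volume fraction ≥ 2% (inclusive) — preserving order.

## Synthetic tripartite synapses

EM-derived segmentations are large external downloads; the generator
(`make_tripartite()`, `make_population()`) provides statistically matched
stand-ins so every downstream stage is testable offline. A synapse is built
from a bouton sphere capped at the cleft plane (default radius 250 nm, cleft
20 nm), a spine head with neck (200 nm), an axon shaft, and an astrocytic
shell at a 12 nm standoff wrapping polar caps of the bouton/spine surfaces
whose cap fractions are the wrap parameters. Remaining space is packed with
random ellipsoids of inert neuropil ("other") until the ECS fraction reaches
its target — 18% by default, the post-correction physiological value — while
a thin protected ECS film around every membrane keeps the extracellular
network connected. The leaflet volume is capped so the ECS target stays
reachable; when a draw asks for more shell than fits, the wrap is narrowed
(preserving thickness, hence SVR).

Population draws: SVR targets are normal (defaults mean 22, sd 5 per μm,
anchored to the leaflet regime), wrap fractions are Beta(1.2, 1.2) marginals
coupled by a Gaussian copula (ρ = 0.4) — the joint coverage distribution in
real tissue is only known graphically, so this is a modelling choice that
produces broad heterogeneity including strongly asymmetric wraps. Because
voxelisation biases analytic shell formulas (the Manhattan factor above),
each leaflet thickness is *calibrated*: the geometry parameters are
realised, measured with
the package's own morphometrics, and thickness iterated (up to 4 times,
starting from t = 3/SVR) until the measured SVR is within 5% of target.
Identical spec + seed reproduces a volume bit-for-bit.

What the generator does *not* emulate: spine-shape taxonomy, multi-synapse
boutons, en-passant geometries, organelles, and the long-range correlation
structure of real neuropil. Passing tests on synthetic populations therefore
validate the machinery and the geometry–dynamics relationships, not any
claim about a specific reconstructed tissue block.

## Transporter kinetics

Transport is modelled per molecule as a Markov ring. The glutamate
transporter (EAAT) cycle has 13 steps with separate binding/unbinding of
3 Na^+^, 1 H^+^ and 1 Glu on the extracellular side, K^+^ countertransport,
and the loaded translocation carrying +3 elementary charges inward (net +2
per cycle including the K^+^ return step). The NCX cycle has 6 steps in a
consecutive (ping-pong) arrangement exchanging 3 Na^+^ for 1 Ca^2+^, with
charge split −2 on the Ca^2+^ limb and +3 on the Na^+^ limb.

Rates live in an editable YAML file (`inst/extdata/kinetics.yaml`), in
1/ms or 1/(mM·ms); each transition may name a ligand (with first- or
third-order concentration dependence), a charge *q* (symmetric Eyring
voltage factor `exp(-q·V/(2·RT/F))`, RT/F = 26.73 mV), and a bookkeeping
action. The shipped numbers are package defaults of literature order for
the Bergles-type EAAT scheme and Chu-type NCX cycle — the published figure
sources for this class of model do not allow exact reconstruction — with
two hard constraints imposed by construction:

* **Thermodynamic consistency (NCX).** The product of forward over backward
  base rates equals one, so the analytic cycle flux vanishes exactly at the
  reversal potential `V_rev = 3·E_Na − 2·E_Ca` (−85.6 mV at baseline). At
  −70 mV the exchanger idles just on the reverse side of equilibrium:
  raising Na^+^~i~ from 10 to 20 mM moves `V_rev` from −53 to −108 mV,
  switching it from net Ca^2+^ extrusion to increasingly strong Ca^2+^
  entry. This single property drives the sodium results.
* **Step-probability bound.** Every state's total exit probability stays
  below 1 at dt = 1 μs across the Na^+^~i~ ∈ [10, 20] mM study range
  (checked at run time; violations abort with the offending transition).

Temperature enters as a Q10 = 3 factor over one 10 °C decade (configurable
via reference/simulation temperatures); pH is fixed at 7.3 because no proton
dynamics are modelled. Analytic steady states solve `Q p = 0, Σp = 1`;
stochastic stepping is fixed-step Bernoulli per transition (matching the
1 μs engine clock) rather than exact Gillespie — a Gillespie sampler exists
in the test suite as an independent oracle only. Molecules are initialised
at the analytic steady state and then settled stochastically for 30 ms with
pinned concentrations before the timed phase; this reaches the same
distribution as random initialisation while honouring the stated protocol.

## Particle engine

Extracellular glutamate and intracellular free Ca^2+^ are explicit
particles; each free particle takes an independent per-axis Gaussian step
with σ = √(2·D·dt) per 1 μs (the standard Euler–Maruyama discretisation; an
MSD regression recovers the configured D = 0.33 μm²/ms for glutamate).
Boundary rules: a step out of the home compartment is rejected (position
restored); a step out of the sample removes the particle unless its species
is at or below its baseline count, in which case it is returned. D for
cytosolic Ca^2+^ is not a sharply defined constant; the default is
0.22 μm²/ms and configurable.

Each EAAT's glutamate-binding rate uses the *local* concentration: the count
of free molecules in the 50 × 50 × 50 nm³ box around the molecule divided by
the box's ECS volume (precomputed exactly per molecule, clipped at the
sample boundary). Binding sequesters a specific particle until reverse
release (restored at the transporter position) or inward translocation
(counted into a cytosolic tally; cytosolic glutamate itself is a 3 mM
constant). NCX binds the nearest free Ca^2+^ within 150 nm of its
cytosolic face; a binding transition that finds no eligible particle is
vetoed — the state does not change — and logged, which is what prevents
negative mass. Reverse NCX cycles create cytosolic Ca^2+^ at the exchanger's
membrane site (whether entry is point-like or distributed is unstated in
the source models; point-like is the conservative choice for a
particle-tracking engine). Sodium is a single well-mixed concentration —
at 15 mM a leaflet holds ~10⁶ ions, so particle noise is negligible —
updated by event stoichiometry and floored at zero.

A strict ledger (free + bound + translocated + boundary-removed − created)
is maintained per species and checked exactly in the tests.

## Protocol and determinism

`run_simulation()` executes: placement (counts = density × total exposed
astrocytic area, rounded; default 10,800 EAAT and 500 NCX per μm²;
positions sampled over ECS-adjacent faces proportional to face area, since
membrane pressed against other cells has no aqueous access), 30 ms kinetic
pre-equilibration, then the timed loop — per step: particle moves →
transition sampling (molecules in a fresh shuffled order; dynamic
concentrations sampled at the step start, where one ion is far below any
rate's sensitivity) → bookkeeping — with 5,000 glutamate molecules released
at 10 ms when enabled, to 30 ms. Release spreads the molecules over the ECS
voxels within 100 nm of the synapse centroid: the set of nearest ECS
voxels, wide enough that the first-step local concentrations stay inside
the Bernoulli bound. Traces ([Ca^2+^]~i~ from the free-ion count over the
astrocytic volume, [Glu]~e~, [Na^+^]~i~) are sampled every 10 μs (100 kHz).

All randomness flows through R's RNG: a run is bit-reproducible from
(geometry, config, seed), and `run_condition_grid()` derives each run's
stream from (seed, geometry id) only, so patched conditions sharing a seed
stay step-for-step comparable until the patch makes them diverge (e.g.
release on/off pairs are identical before the release event).

## Spectral readout and statistics

`band_power_db()` takes the 12–21 ms window, removes the mean, and forms a
single-segment rectangular-window periodogram (one-sided density with
1/(fs·N) scaling, so density summed over bins times the bin width equals
the segment variance — Parseval is a test). Band power is the summed
100–500 Hz density × bin width, in dB re 1 (nM)². With 9 ms of data the
resolution is ~111 Hz and Welch averaging is impossible; the short-window
single periodogram is the only estimator consistent with that window, and
the resolution is carried in the result. The dB reference is arbitrary
relative to published figures whose normalisation is unstated, so all
scientific conclusions here are differences and trends, never absolute dB.
A constant segment has zero band power and is reported as missing.

Downstream statistics use the canonical tools: OLS (`stats::lm`) for power
vs SVR with broom-style `tidy()`/`glance()`, classical equal-variance
one-way ANOVA (`stats::oneway.test`), and per-bin mean ± SEM summaries.

## Problem sizes used by the tests

The shipped test-suite experiment runs 20 synthetic geometries spanning
SVR 3–35 per μm × 3 seeds × Na^+^~i~ ∈ {10, 15, 20} mM (180 NCX-only,
release-free 30 ms runs at 250 NCX/μm², half the physiological density —
the trend readouts scale with density but do not change sign), plus a
50-synapse population calibration check and full-density short runs for
the bookkeeping and control checks. These sizes were chosen so the whole
suite completes comfortably on a single CPU while leaving the trend
statistics unambiguous (the SVR slope p-value is far below 0.05 at n = 60).

## Known limitations

* No Ca^2+^ buffering, ER stores, mitochondria, IP₃ receptors or astrocytic
  NMDA receptors: the model isolates the NCX/EAAT membrane mechanism, so
  absolute fluctuation amplitudes are upper bounds on the free-Ca^2+^
  signal, and downstream amplification is out of scope.
* Membrane potential is static (−70 mV); no electrodiffusive feedback.
* The kinetic rate values are literature-order defaults, not a fit; all
  quantitative conclusions shipped with the package are structural
  (stoichiometry, reversal, trends), which are robust to rate rescaling
  that respects the two constraints above.
* The face-count surface definition carries the Manhattan factor for curved
  surfaces; comparisons to mesh-based surface areas need the 2/3
  correction discussed above.
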