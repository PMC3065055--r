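---
title: "A hybrid cellular automaton of vascular tumour growth and vascular-targeting therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid cellular automaton of vascular tumour growth and vascular-targeting therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vasctum` simulates the growth of a glioblastoma-like tumour in a
well-vascularized two-dimensional tissue, together with three
vascular-targeting treatment protocols: a bevacizumab-like angiogenesis
inhibitor (AI), the AI combined with a temozolomide-like cytotoxic agent,
and a CA4P-like vascular disrupting agent (VDA). This vignette explains the
model, the choices made where the design was genuinely open, the numerical
scheme, and what the package's tests do and do not establish.

## Model overview

The model couples three layers, advanced in a fixed daily order:

1. an eight-species reaction–diffusion system for VEGF, Ang-1, Ang-2 and
   their receptors (VEGFR-2, Tie-2), solved one day forward;
2. vessel evolution — regression of destabilized vessels (with an upstream
   flow cascade) followed by VEGF-gradient sprouting;
3. cell-state transitions and stochastic division on an irregular cellular
   automaton lattice; then any treatment events scheduled for the day.

### The automaton lattice

Automaton cells are the Voronoi regions of a random-sequential-addition
(RSA) hard-disk point process clipped to the tissue rectangle
(`generate_lattice()`). Each cell stands for a cluster of about seven glial
cells: with a 40 µm glial diameter the cluster area is
7·π·(20 µm)² ≈ 8.8·10³ µm², i.e. an equivalent diameter of ≈ 106 µm —
comfortably below the 250 µm oxygen diffusion length, so a cell is either
oxygenated or not as a whole. The RSA disk diameter is 0.8 × the target
cell diameter; at RSA saturation this yields mean realized cell diameters
of ≈ 115 µm, within a few percent of the target. The calibration factor,
the domain extent (default 20 × 20 mm, accommodating the 10 mm maximum
tumour radius) and the rectangle clipping of boundary cells are all
configuration choices; no planar Voronoi implementation was available among
the supported dependencies, so the tessellation (half-plane clipping with a
security-radius stop) is part of the package's compiled core and is checked
in the tests against a brute-force nearest-generator oracle.

### The healthy vasculature

The capillary bed is a randomized Krogh picture: straight vessels placed
sequentially under three constraints — not too close to a roughly parallel
vessel (default 80 µm, parallel meaning within 10°), no more than three
vessels through one cell site, and at least one newly vascularized cell per
accepted vessel (`generate_native_network()`). Placement stops when every
cell is within 250 µm of a vessel. Vessels are discretized into
sub-segments of about one cell diameter — the unit at which regression and
disruption act.

Each trunk carries blood from its first endpoint: sub-segment *k* supplies
sub-segment *k + 1*, and an angiogenic sprout is supplied by the segment it
sprouted from. Destroying a segment therefore destroys its entire
flow-dependency closure (`remove_segments_with_cascade()`). A dual-fed
reading (both trunk ends acting as sources) was tried first and discarded:
with it, a tumour unable to mount an angiogenic response grows exactly as
fast as a vascularized one, because un-coopted vessel remainders always
re-oxygenate the rim; the directed reading is also what makes the
documented insensitivity of the tumour response to the VDA efficacy
parameter emerge.

### The signalling fields

The ligand/receptor system is integrated on a regular mesh (default
100 µm) with an explicit finite-difference scheme: five-point Laplacian for
the two diffusing ligands (VEGF and Ang-2; Ang-1 acts only on the
endothelium that secretes it), zero-flux boundaries, simultaneous sub-step
updates. The sub-step satisfies both the diffusive CFL bound and
dt ≤ 0.5/ρ for the largest linear reaction rate ρ, which also keeps every
field non-negative without clamping. Receptor association/dissociation
terms are written as exact opposites, so the totals rv0 + rv and
ra0 + ra1 + ra2 are conserved pointwise to rounding error — the tests
assert 1e−10 relative per day and compare the homogeneous limit against an
independent stiff-ODE integration (deSolve) and the binding isotherm
closed form.

Receptors exist only on endothelium and have no production term, so
receptor mass is managed by vessel events: a grid site gains fresh unbound
receptor at the endothelial concentration e₀ = 10⁻⁴ µM when a vessel
appears there and loses all receptor species when its last vessel dies.

The hypoxic-cell concentration entering the VEGF and Ang-2 sources is
h = h₀·h_i with h₀ = 10⁻² µM by default — the magnitude is not fixed by
the published system, and the VEGF carrying capacity K_v sets the natural
scale; h₀ is configuration-exposed.

### Cell states and division

Oxygen is not a field: distance to the nearest alive vessel stands in for
it. Daily, (a) viable nonmalignant cells farther than 250 µm from a vessel
undergo apoptosis; (b) hypoxic tumour cells within 250 µm turn
proliferative; (c) hypoxic cells beyond 1500 µm turn necrotic (necrotic
cells are inert); (d) proliferative cells beyond 250 µm turn hypoxic;
(e) each remaining proliferative cell attempts one Bernoulli division with

  p_div = p₀ (1 − r / R_max),  p₀ = (p_min − p_max)/l_prolif · d_vessel + p_max,

with p_min = 0.1, p_max = 0.284 (doubling times of about seven and three
days; the mid value 0.192 corresponds to about four days), r the distance
from the tumour seed and R_max = 10 mm the mechanical confinement radius.

A daughter is placed at the dividing cell's nearest neighbour; if that
site is occupied by a tumour cell, cell labels are pushed outward along
the shortest adjacency path through the tumour to the nearest non-tumour
cell, leaving one new proliferative cell at the periphery. An earlier
variant that pushed along the ray from the seed through the dividing cell
was abandoned: it is dynamically unstable (rays through dividing cells
keep extending the same filament tips, producing dendritic tumours and
runaway drift of the tumour centroid), whereas the nearest-free-cell push
realizes the same "successively pushed outward" picture compactly and
deterministically. Whether apoptotic sites can be re-occupied by pushed
tumour cells is not constrained by the published description; they are
treated as occupiable dead tissue.

### Vessel regression, rescue and sprouting

A vessel sub-segment is destabilized when its local bound Ang-2 exceeds
six times bound Ang-1, and regresses unless bound VEGF reaches the
threshold `rv_crit` (rescue). Two regimes are distinguished:

* **Inside malignant tissue** the pure ratio rule applies. Freshly coopted
  endothelium starts producing Ang-2 eight times faster than Ang-1, so a
  vessel overrun by the tumour is destabilized within a day or two of
  cooption unless VEGF protects it — the cooption → regression →
  hypoxia → angiogenesis cycle.
* **Outside malignant tissue** no Ang-1 is secreted at all, so the ratio
  rule alone would fire on arbitrarily small diffused Ang-2 and destroy
  the entire domain vasculature. Destabilization there additionally
  requires bound Ang-2 above an absolute floor `ra2_floor`, restricting it
  to the Ang-2 plume of nearby hypoxic tissue.

Both thresholds are calibrated against the steady fields of a nascent
hypoxic focus (a 0.25 mm disk): `rv_crit` is the bound VEGF and
`ra2_floor` the bound Ang-2 at twice the oxygen diffusion length from the
focus edge (`calibrate_rv_crit()`, `calibrate_ang2_floor()`; defaults
3.0·10⁻⁵ and 3.8·10⁻⁵ µM, two significant digits). With intact VEGF
signalling the rescue reach therefore matches the destabilization reach
and hypoxia protects the vessels around it; suppressing the VEGF response
(an AI, or an endothelium that cannot respond) leaves the bare Ang-2
destabilization zone, which strips the vasculature around the tumour and
arrests it — this is what produces the microscopic avascular growth cap.

Sprouting: every alive site with bound VEGF at or above `rv_crit` — open
angiogenic tips, and native sub-segments that have not branched yet —
extends one new angiogenic segment per day (one lattice edge, ≈ 106 µm)
along the central-difference VEGF gradient, falling back to the previous
direction (tips) or the trunk perpendicular (initiation) where the
gradient vanishes. A tip landing within half a sub-segment of another
alive vessel anastomoses and stops; a parent whose branch later dies may
sprout again.

### Treatment protocols

Treatment starts on the first day the effective tumour radius
(√(area/π) over proliferative + hypoxic + necrotic cells) reaches the
trigger radius (default 4 mm).

* **AI** — sustained parameter change while active (its 20-day half-life
  keeps levels therapeutic between biweekly doses): dividing the VEGF
  production rate b_v by T1 (default mode), dividing the association rate
  k₀ by T1, or multiplying `rv_crit` by T1. Parameters are rebuilt from
  pristine copies daily, so cessation restores them exactly.
* **Cytotoxic agent** — daily through a 42-day window; each proliferative
  cell is independently killed with probability T2 and becomes necrotic
  (it stays in the tumour area but leaves the active area). The
  fractional-kill arithmetic behind T2 is exposed as
  `fractional_kill_from_log_kill()`: a net 0.4 log₁₀ kill over five daily
  doses against a four-day doubling time implies f ≈ 0.30 per day; the
  published parameter value 0.34 is kept as the default.
* **VDA** — on dose days only (every 21 days): each alive angiogenic
  sub-segment is independently destroyed with probability T3 and the flow
  cascade removes everything it supplied; coopted native vessels are never
  touched. The cascade is what makes the response insensitive to T3 above
  moderate values.

## What the simulations reproduce, and at what size

Everything stochastic in a run derives from one seed through per-module
RNG streams, so module behaviour does not depend on how many draws another
module consumes; replicate batches use consecutive seeds and report
per-day means and standard deviations (`run_replicates()`,
`sensitivity_sweep()`).

The package's tests exercise the full treatment panel at reduced problem
sizes chosen so the whole suite runs on a desk machine: 5–8 mm domains,
treatment triggers at 1.5–2 mm radius, 3–10 replicates, 300–420 simulated
days (the full-size study conditions — 20 mm domain, 4 mm trigger — are
the package defaults). At these sizes the following emerge and are
asserted: the avascular growth cap at millimetre scale; stabilization of
the active tumour area under an AI; the ordering untreated ≥ AI ≥
AI + cytotoxic; the dose-dependent active-area decline during the
cytotoxic window with dose-independent regrowth after it; the VDA
efficacy plateau above T3 = 0.3 with measurably faster growth at
T3 = 0.1; regrowth after treatment cessation; and week-scale post-dose
active-area declines under the VDA.

Two published observations do **not** emerge from this reconstruction and
are deliberately left as failing checks rather than tuned away. First,
under a maximally efficacious AI (T1 = 1000) about 1% of the active
population should remain proliferative; here the same destabilization
plume that produces the avascular cap strips the rim vasculature
completely and the proliferative population reaches zero — the two
published behaviours appear to demand a vascular-network fragility that
the randomized straight-trunk reconstruction lacks. Second, after a VDA
dose the active area should take about two weeks to recover; here
re-sprouting from surviving rescued vessels at one lattice edge per day
restores it within a few days. Both gaps, and the diagnosis, are recorded
alongside the corresponding checks.

## Numerical and degenerate-input choices

* Mesh spacing is guarded to 10–500 µm; runs use 100 µm, below the 250 µm
  diffusion length and near the cell size. Halving it moves the
  homogeneous steady state by well under 1%.
* The explicit sub-step is recomputed daily from current field maxima with
  carrying-capacity caps, so stiffness from the association rates (up to
  ≈ 47 µM⁻¹h⁻¹) is handled without clamping; a negative excursion beyond
  1e−13 aborts with the offending field named.
* Ties in the directed lattice walk are broken toward the lowest cell id;
  division order is reshuffled daily; push paths follow id-ordered
  breadth-first search — every tie-break is deterministic under the seed.
* A domain smaller than one RSA disk yields a single-cell lattice; an
  exhausted vessel attempt budget yields an empty network with a coverage
  warning (uncovered healthy cells then die by the apoptosis rule, which
  is the documented behaviour, not an error).
* `total_days = 0` returns only the day-0 metrics row; metrics tables
  carry one row per day including day 0.

## Known limitations

Blood flow, pressure and hematocrit are not modelled — supply is purely
geometric (the 250 µm rule). Drug exposure is uniform over the reach of
the vasculature. There is a single angiogenic pathway; no chemoresistant
subpopulations, treatment-induced mutations or phenotypic heterogeneity.
The lattice is two-dimensional. Absolute growth-curve magnitudes depend on
the domain size once the tumour approaches the boundary; comparisons
between treatment arms are therefore made at matched days after the
trigger, on identical seeds.
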