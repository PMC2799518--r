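---
title: "The multiscale virtual-epidermis model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multiscale virtual-epidermis model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidermabm)
```

## Overview

`epidermabm` grows a stratified virtual human epidermis inside a walled
column (100 x 100 um of basement membrane, 100-um walls) from a handful of
seeded keratinocyte stem cells, and simulates scratch wounding and
re-epithelialisation. Three layers are coupled on a 30-minute iteration
clock:

1. **Subcellular** -- each cell carries a TGF-beta1 module: promoter
   activity driven by its matrix environment, capped
   transcription/translation of latent TGF-beta1, and a ligand-receptor
   trafficking network (binding, internalization, recycling, degradation)
   whose endosomal complex (LRCE) is the signalling read-out.
2. **Cellular** -- agent rules for division (a probability table modulated
   by contact inhibition and LRCE), a forward-only differentiation cascade
   stem -> transit-amplifying (TA) -> committed -> corneocyte, and active,
   contact-preserving TA migration (1 um/min) biased toward provisional
   matrix.
3. **Tissue/matrix** -- a lattice of 20 x 20 um tiles whose `ECM_value` in
   [0, 1] encodes the remodeling axis provisional matrix (PM, >= 0.5) ->
   secondary matrix (SM, [0.1, 0.5)) -> basement membrane (BM, < 0.1);
   tiles store latent TGF-beta1 as time-stamped parcels, and an
   overlapping-spheres mechanics solver resolves cell overlap, bonds and
   wall constraints after the biology of every iteration.

## The TGF-beta1 layer

**Promoter activity.** For a cell with matrix-class weights (PM, SM, BM)
from the tile it touches, membrane complex LRCP and stratification distance
D (the height of the cell centre; D_w = 1 once D >= 10 um):

$$PRO = (1 - BM)\,\bigl(\delta(\xi\,PM + \eta\,SM) + \phi\,LRCP + D_w\bigr)$$

with delta = 10, phi = 0.4, eta = xi = 1. Contact with basement membrane is
fully suppressive; a detached (stratified) cell keeps the LRCP and
stratification terms. Only stem and TA cells express TGF-beta1. The
original equations are not legible in the source material; this form uses
every published coefficient with its stated role and makes BM suppression
exact, which reproduces the published worked behaviour (PRO = 10 for pure
PM contact, 0 on BM).

**Expression.** `mRNA = Phi * PRO` and `latent = min(Omega * mRNA, 200)`
with Phi = Omega = 5; the 200 mmol/l ceiling is the published per-cell
maximum per 30-minute iteration.

**Deposition and activation.** Newly synthesized latent TGF-beta1 is
split -- there is no free diffusion: the fraction alpha of the tile
underneath (0.90 on PM, 0.01 on SM and BM) is appended to the tile's
latent store as a parcel stamped with the iteration; the remainder is
divided equally among neighbours within bond range as active membrane
ligand, or discarded if there is none. Latent matrix stores are activated
only by direct cell contact: each contacting cell retrieves an equal share
of the whole store, of which kappa = 90% arrives as active membrane ligand
and 10% is destroyed. Both latent and active parcels have a sharp 48-hour
lifetime (96 iterations): the lifetime is published as a span, not a decay
rate, so parcels carry timestamps and are removed exactly at 48 h.

**Trafficking network.** The decided network (the published reaction
listing is not legible; the topology follows the published model's
textual description and its cited receptor-trafficking model) is

* `ligand + R1 + R2 -> LRCP` (trimolecular binding, `k_bind`),
* `LRCP -> LRCE` (complex internalization, `k_int_complex`),
* `R1 <-> R1E`, `R2 <-> R2E` (constitutive cycling, `k_int_receptor`,
  `k_recycle`),
* first-order degradation of LRCP, LRCE (`k_deg_complex`) and of endosomal
  receptors (`k_deg_receptor`), and constitutive production (`prod_r1`,
  `prod_r2`).

Endosomal receptor degradation is included so that the receptor pool is
bounded under constitutive production; without it total receptor material
grows without limit. Rate values are not published; the defaults are chosen
once so that the documented normal-condition receptor distribution
(R = 20 mmol/l membrane, RE = 10 mmol/l endosome) is a rest state of the
constitutive cycle (`prod = 0.5, k_int_receptor = 0.1, k_recycle = 0.15,
k_deg_receptor = 0.05`; check: 0.5 - 0.1*20 + 0.15*10 = 0), with fast
complex internalization (1/3 min^-1) and ligand-induced complex degradation
(0.25 min^-1) in the ranges used by published trafficking models, and
`k_bind = 0.001 (mmol/l)^-2 min^-1` so that binding at normal receptor
levels runs on the tens-of-minutes trafficking timescale. All are
configuration keys.

**Integration.** The deterministic default integrates each cell's network
over the 30-minute iteration with an adaptive embedded Cash-Karp
Runge-Kutta 4(5) scheme (`ode_rtol = 1e-9`), with step rejection on any
negative component so concentrations stay nonnegative without clipping. A
fixed 100-step grid (the reporting grid of the source model's stochastic
task) is not accurate enough to meet the package's own 1e-6
oracle-agreement contract across parameter ranges, so the step size is
error-controlled instead. The optional stochastic mode maps concentrations
to counts through a volume factor and tau-leaps on a fixed grid of 1000
leaps per iteration; its replicate means agree with the deterministic
solution in the large-count limit (tested).

**Bond modulation.** `IN = PR = Pi * LRCE` with Pi = 0.5 (the two are
published jointly with a single coefficient), then `CCB = CCB0 / (1 + PR)`
and `CSB = CSB0 (1 + IN) / (1 + PR)`: defaults are recovered exactly at
LRCE = 0, and cell-cell bonds weaken monotonically with signal (proteases
loosen the sheet for migration).

## Cellular rules

**Division.** Stem and TA cells attempt division once their 24-h cycle
clock matures; an attempt succeeds with probability
`PRR = DP(scenario) / (1 + lambda * LRCE)` (lambda = 0.1 per mmol/l, a
saturating inhibition that recovers the published table at LRCE = 0). The
scenario table: 90% on provisional matrix or in the wound bed, 40%
uninhibited in normal epidermis, 5% for stratified TA over the wound bed,
2%/1% for contact-inhibited TA/stem. Contact inhibition has two channels:
(i) >= 10 neighbours within 12 um -- the caging count of an interior cell
in a compact sphere packing (a threshold of 6 would declare a confluent
basal monolayer, exactly 6 lateral contacts, inhibited and freeze the
tissue at the inhibited rates right at confluence, making the published
growth timeline unreachable; a monolayer cell with a free upper half-space
remains proliferative); and (ii) crowding-induced mechanical arrest: a cell
whose residual post-mechanics pair overlap stays at or above
`overlap_inhibit` (1 um, a fifth of the radius) for `overlap_persist_h`
(3 h) continuously is also classified contact-inhibited. The second channel
is what bounds the tissue: bond adhesion alone holds a cohesive cluster at
sustained overlaps of a few tenths of a micron, while jamming against the
walled column produces micron-scale compression, and the 1-um threshold
separates the regimes. Because zero-overlap close packing of 10-um spheres
in the 100-um column is ~1200-1300 cells, arrest near the compression onset
puts the homeostatic count at the published scale as a consequence of
geometry.

Daughters are placed at one cell diameter from the parent. Suprabasal
parents use a uniformly random 3D direction. Basal parents place the
daughter near-horizontally (random azimuth, 5-25 degree upward pitch) while
the neighbourhood has room, and steeply upward (60-85 degrees, a
delaminating daughter) when crowded: exactly coplanar placement gives the
relaxation solver no vertical symmetry breaking (a crowded monolayer jams
instead of stratifying), and lateral placement in a confluent sheet shoves
random basal neighbours -- including stem cells -- out of the layer, which
slowly destroys the stem compartment.

**Differentiation.** The cascade is strictly forward. Stem -> TA when the
cell has been stratified continuously for `strat_persist_h` (6 h; a
per-cell timer accumulates while D >= 10 um and resets below -- detachment
commitment takes hours, and transient mechanical bumps during crowded
divisions must not convert stem cells), or when it sits on the edge of a
connected stem colony that has reached `colony_size_threshold` (120 -- above
the ~115-stem capacity of the reference 100 x 100 um surface, so the colony
first occupies the whole basement membrane, matching the published growth
sequence). TA -> committed requires both persistent stratification
(commitment is a suprabasal event; without this gate TA wandering beyond
the colony during sub-confluent growth become corneocytes *on the floor*)
and distance >= 20 um from the nearest stem cell (about two cell diameters;
the larger published-model value keeps the proliferative TA band so high
that the claim that proliferation stays close to the basement membrane
fails). Committed -> corneocyte after 48 h, halved while touching a
corneocyte (the ceramide/FAS-L signal passes only between committed cells
and corneocytes). Timed corneocyte desquamation is implemented but
disabled by default (`corneocyte_dwell_h = Inf`): with the published
division probabilities, any timed removal caps the supra-committed
compartment at production x dwell (~50-100 cells) and the tissue at a
quarter of its published size; the source model describes no desquamation,
and its maintained homeostatic structure is a contact-inhibition-bounded
quiescent tissue, which this package reproduces. Setting any finite dwell
enables shedding.

**Migration.** Only TA cells move actively: 1 um/min for the 30-minute
iteration (one 30-um step), toward the nearest provisional-matrix tile
within a 60-um sensing radius with probability 0.8, otherwise in a uniform
random horizontal direction. Two cancellation rules apply: a cell without
any bond-range contact does not migrate (sheet cohesion), and a move whose
destination is already occupied (another centre within one cell diameter)
is cancelled -- contact inhibition of locomotion. The second rule is what
confines crawling to free territory (colony edges, the denuded wound bed);
without it every basal TA ploughs through the confluent monolayer each
iteration and the landings destroy the basal architecture.

## Mechanics

Cells are rigid 10-um-diameter spheres; contact is at 10 um centre
distance. Forces: repulsion `k_rep * overlap` along the centre line;
bond attraction `k_att * CCB * gap/5` for surface gaps in (0, 5] um (pair
CCB is the mean of the two cells'); substrate adhesion scaled by CSB over
the same 5-um gap, multiplied for stem cells by `stem_anchor` (20 -- stem
cells are the most basement-membrane-adherent keratinocytes, and without
the multiplier the basal layer is a neutral drift in which the stem pool
goes extinct); one-sided springs at the floor, four walls and the wall top;
and a weak constant settling force (`k_settle = 0.2`) on cells that have
neither substrate contact nor a supporting neighbour below -- without it a
cell displaced above the 5-um adhesion range simply floats forever. Because
settling is support-gated it adds no compressive load to resting stacks.

The solver is damped relaxation: sweeps of force summation followed by
moves of `mobility * force` (0.5 um per unit force), until the largest
displacement falls below `tol` (0.01 um) or `max_sweeps` (300) is reached
(most iterations converge far earlier; the cap only matters for the most
crowded ones);
non-convergence is a logged warning, never an error. Centres are
hard-projected into the walled column each sweep, so the invariants
z >= 5 um and in-column positions hold even under compressive loads the
one-sided springs cannot balance. Coincident centres separate along a
seeded random axis so replays stay identical.

## The iteration scheduler

Each `step_world()` executes: (1) neighbour/contact indices; (2) ECM and
subcellular phase -- store aging, remodeling (`ECM_value` drops by 0.01 per
contacting living cell per iteration, so a wound-bed tile under confluent
contact remodels PM -> SM -> BM over about two simulated days), then per
cell: weights -> promoter -> expression -> deposition -> activation ->
trafficking -> bonds; (3) biology -- division, differentiation, migration
(in a seeded shuffled order); (4) mechanics. The subcellular phase runs
before biology so that division and migration use the current iteration's
LRCE. The order is isolated in one function.

`run_epidermis()` iterates to a fixed count or to the homeostatic plateau
(total cell count changing by less than 2% over a sliding 200-iteration
window), and records a per-iteration census, the event log and a stable
run-record hash (FNV-1a over the serialized census and final snapshot;
replays with the same seed hash identically). `wound_world()` removes the
cells in an axis-aligned box, resets the tiles under it to provisional
matrix, and puts surviving cells within one cell diameter of the box into
the wound-onset state (LRCP = LRCE = 20, membrane ligand 100 mmol/l) --
the platelet/macrophage burst of active TGF-beta1; the spatial extent of
that initialization is not published, and one diameter is this package's
choice. `heal_experiment()` steps until no tile is PM-class and the cell
count is back to 80% of its pre-wound value, within an iteration budget;
budget exhaustion is recorded as non-closure.

## What the simulations show -- and what they do not

The growth experiment (30 stem cells seeded on the 100 x 100 um surface,
default parameters, plateau stop rule) reproduces the published
morphological sequence: colony formation, confluence, stratification, and
a four-layer tissue with median heights ordered stem < TA < committed <
corneocyte, with division events concentrated near the basement membrane
and a total agent count in the neighbourhood of 1500 (cells + 25 tiles +
the solver agent). Homeostasis here is a *bounded quiescent* state --
contact inhibition plus the filled walled column stop net growth -- rather
than a flux balance between division and shedding; enabling a finite
corneocyte dwell produces turnover at the cost of a much thinner tissue
than published, which is an inconsistency internal to the source
parameterisation (its division table cannot feed a 10-layer conveyor).

Scale note: the published tissue is itself only 100 x 100 um (25 tiles),
so the growth and healing runs here are full-size, typically a few
thousand iterations (a few simulated weeks). Test-suite runs use the same
geometry but shorter horizons where a full plateau is not needed.

The synthetic world is an idealisation: a flat rigid substrate, rigid
spheres, a single growth factor, no dermis, no immune compartment, no
fluid. Passing tests show the implemented rules interact as designed; they
do not validate the parameter values against real epidermis beyond the
qualitative behaviours above.

## Numerical choices

* Adaptive RK45 with positivity-preserving step rejection for the
  trafficking step (oracle agreement to 1e-6 against an independent stiff
  integrator is part of the test suite).
* Sharp-cutoff parcel lifetimes via a ring buffer of per-iteration age
  bins; the ring semantics are pinned to the reference parcel
  implementation by an equivalence test.
* Damped relaxation with fixed gains for mechanics; determinism is part of
  the contract (same seed, same trajectory, byte-identical snapshots).
* The wound margin, the contact-inhibition count, colony and distance
  thresholds, dwell times, settling and anchoring strengths are the open
  design parameters; every one is a configuration key with its default and
  rationale stated here, and the growth experiment is the sensitivity
  surface that fixed them.

## Known limitations

* The source model's exact promoter/bond equations and trafficking rate
  values are not legible in the available material; the decided forms above
  use every printed coefficient and are flagged at their definition sites.
* The nominal post-resolve overlap target of 10x the convergence
  tolerance (0.1 um) holds for adhesion-free configurations but not for a
  cohesive tissue: bond attraction equilibrates interior cells at
  overlaps of a few tenths of a micron even at full convergence, and the
  published homeostatic configuration (~1450 cells of 10-um diameter in
  the 100-um column) is at or above random close packing, so micron-scale
  residual compression at the plateau is geometrically forced. Residuals
  are reported per iteration in `last_resolve`.
* Without desquamation the corneocyte compartment is a sink; wound-healing
  runs on a grown epidermis therefore model re-epithelialisation of the
  wound bed, not long-term turnover.
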