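---
title: "A vertex model of embryonic thyroid morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vertex model of embryonic thyroid morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromorph)
```

## The biological problem

Between embryonic days E13.5 and E17.5 the murine thyroid transforms from
a compact, multi-layered mass of non-polarised epithelial progenitors
into a collection of follicles: single-layered epithelial spheres around
a central lumen, embedded in a dense capillary network. Three coupled
processes drive the transformation: differential epithelial
proliferation (peripheral cells cycle much faster than central ones),
VEGFA-driven invasion of endothelial tip and stalk cells that fragments
the mass into islets, and apico-basal polarisation of epithelial cells
that eventually nucleates follicular lumina. `thyromorph` implements a
two-dimensional vertex model of this sequence and the summary statistics
used to compare it with stained tissue sections.

## The mechanical model

Each cell is a polygon; vertices are the adherens junctions where three
cells meet. Vertex positions evolve by overdamped gradient descent on
the tissue energy

$$E \;=\; \sum_{\text{cells }\alpha} \frac{K_\alpha}{2}\,
  (A_\alpha - A_{0,\alpha})^2
  \;+\; \sum_{\text{edges } j} \Lambda_j L_j
  \;+\; \sum_{\text{cells }\alpha} \frac{\Gamma_\alpha}{2} P_\alpha^2 ,$$

with area elasticity $K$, per-cell target area $A_0$, line tension
$\Lambda$ per edge, and perimeter contractility $\Gamma$. The equation of
motion $\dot{\mathbf r}_k = \mathbf F_k = -\nabla_k E$ uses unit
mobility and is integrated with forward Euler at $\Delta t = 0.001$ h.
Random vertex fluctuations are neglected: adhesion is assumed strong
enough that junctional noise is irrelevant on these time scales.

Units are nondimensional: lengths in units of one nominal cell diameter
(the initial-condition builder rescales so the median epithelial area is
1), time in hours. With unit mobility, forces are in units of
displacement per hour.

Differential adhesion lives entirely in the $\Lambda$ table, keyed by
the unordered pair of cell types flanking each edge (the tissue boundary
acts as a pseudo-type). Lower $\Lambda$ means stronger adhesion. The
defaults (`default_lambda_table()`) encode the regime the biology
requires: weak epithelial-epithelial cohesion (0.12) so that endothelial
cells can invade at all, strongly adhesive endothelial-endothelial
contacts (0.01) so vessels stay coherent, and a higher epithelial-
boundary tension (0.25) acting as a surface tension that keeps the lobe
compact. Endothelial cells get a stiffer area elasticity ($K = 5$ vs 1)
so that thin nascent vessels resist being squeezed flat by the growing
epithelium. These values are a calibration, not a measurement: the
parameters of the original study are not publicly tabulated, so the
defaults were chosen once so that (i) tip cells invade under the default
motile force but stall when epithelial cohesion is increased, and (ii)
the endothelial area fraction stays in the few-percent range observed
across E13.5-E17.5.

## Junctional rearrangements

Five topological operations keep the polygonal tiling valid while cells
move, grow and divide:

* **T1 (edge swap).** An edge shorter than 0.01 is reconnected
  perpendicular to itself at length 0.015, exchanging neighbours.
  Boundary variants are handled explicitly: a short *boundary* edge, or
  a doubled edge between two cells, is collapsed to its midpoint.
  Edges whose two endpoints are both fixed (endothelial anchors) are
  exempt, and a minimum recreated length above the trigger prevents
  swap/collapse cycles — the "too small edges near fixed vertices"
  failure mode is handled rather than fatal.
* **T2 (extrusion).** A cell whose area falls below 0.001 is replaced
  by a single vertex at its centroid. The operation is defined for
  triangles but the simulator applies the same surgery to any cell that
  the surrounding mechanics has squeezed below the threshold (a cell can
  only invert by first passing through it). Lumen cells are exempt:
  follicular cavities must persist.
* **T3 (boundary merge).** A boundary vertex approaching a facing
  boundary edge within 0.005 is snapped onto the edge and inserted into
  the facing ring, so separate tissue lobes touch instead of
  interpenetrating. A merge that would pinch the local boundary into an
  inconsistent state is refused.
* **Rosette resolution.** Vertices shared by more than three cells (or
  boundary vertices by more than two) arise transiently from T1
  cascades, T3 merges and branch insertion. They are tracked explicitly
  and resolved by splitting: the most angularly isolated incident cell
  moves onto a new vertex, its two angular neighbours gain the new short
  edge (a reverse T1). Redundant interior subdivision vertices (exactly
  two cells, same neighbours) are dissolved.
* **Division.** A cell divides along the line through its area centroid
  in the direction of the *shortest axis*, the minor principal axis of
  its second-moment tensor; exact ties (e.g. squares) break to the +x
  direction. The daughters' areas sum exactly to the mother's; each
  daughter's target area is set to half the mother's. For irregular
  polygons the centroid line need not bisect the area exactly, so area
  *conservation* is the guaranteed invariant, not equal split.

Every operation validates its local surgery (orientation, simplicity,
edge-sharing) and reverts rather than corrupt the mesh; unresolvable
configurations remain tracked and are retried after the next mechanical
substeps. Two further guards keep dense remodelling zones (vessel walls
near fixed anchors, freshly created lumina) from thrashing: every
rearrangement, successful or refused, registers a short *site cooldown*
(0.03 length units around the event, 0.05-0.2 h) during which further
rearrangements there are rejected instantly — hysteresis against
swap/collapse oscillation — and the compiled integrator clamps a minimum
edge length (half the T1 trigger) on edges the rearrangement layer has
exempted, so refused sites cannot degenerate into coincident vertex
clusters. Both are deterministic and affect only pathological
configurations the operations would otherwise revisit every step.

## Cell types and proliferation

Five types: central and peripheral epithelial cells, endothelial tip and
stalk cells, and lumen cells. A peripheral epithelial cell has at least
one unshared (tissue-boundary) edge; by default cells in contact with
endothelium also count as peripheral, because in vivo the periphery is
defined by ECM/vessel contact (`endothelial_contact = FALSE` restores
the strict definition). Labels are re-derived whenever the topology
changes.

EdU pulse labelling at E13.5/E15.5 gives the two baseline cycle
durations used here: 11 h 20 min for peripheral and 31 h 52 min for
central cells. Each new generation multiplies its cycle by the
generation factor $g$ (default 1.45, chosen so the proliferating
fraction declines from roughly 45% toward 10% over four simulated days,
mirroring the exponential decline of the EdU-positive fraction). A 10%
lognormal jitter desynchronises sisters. Cell-cycle phases are not
modelled explicitly; a cell divides when its age reaches its duration,
and the "EdU proxy" reported by `compute_summary_stats()` counts cells
within 0.5 h of their next division — an operationalisation for
comparison, not a biochemical claim. A cell's target area grows
linearly from half its mature value at birth to the full value over one
cycle, so division does not cause area jumps.

Tip cells are differentiated and never divide. Stalk cells have no
timed cycle either: they divide when their elongation factor (square
root of the principal second-moment ratio) exceeds 3, which is what
lets them fill the tube opened behind a migrating tip.

## VEGF field and chemotaxis

Every epithelial cell produces VEGF at rate $s$; the field diffuses and
degrades, with concentration pinned to zero on tissue-boundary cells.
The steady state of $0 = D\nabla^2 c + s\,\mathbf 1_{\text{epithelial}} -
k\,c$ is solved on the cell-adjacency graph by a finite-volume scheme
whose edge weights are shared-edge length over centre distance
(quasi-static: diffusion is assumed fast relative to vertex motion, and
the solve is refreshed every 10 steps together with the rest of the
orchestration). On a 1D chain the scheme converges to the classical
cosh profile; `s = 0` is the in-silico VEGFA knockout.

Tip cells feel an additional motile force of magnitude $\mu$ (default
0.5) on each of their vertices, along the local unit gradient. Because
the Dirichlet layer zeroes the field on boundary cells, a tip sitting at
the tissue edge evaluates its gradient with a two-ring least-squares
stencil; interior gradients use the one-ring fit which is exact for
linear fields.

## Endothelial boundary conditions (endo-BC)

A 2D section cannot show the parent vessels the thyroid capillaries
connect to. Each branch therefore anchors its founding stalk cell
(outermost vertices fixed) and registers a corridor: two semi-infinite
rays starting beside the stalk's original position and extending
outward. After every Euler step, purely-epithelial vertices strictly
inside a corridor are projected to the nearer ray. This prevents two
epithelial buds growing past a vessel from fusing over it, which is what
lets the islets stay separate. Corridors keep their registration-time
half-width and never deactivate (no deactivation rule is modelled).
A vertex exactly equidistant from both rays goes to the side of its
cell's centroid.

New branches (one tip + one stalk, extruded outward from the epithelial
boundary edge farthest from existing endothelium) appear as a Poisson
process at 1/6 per hour during the first 24 simulated hours only —
matching the observation that new tip cells could not be added beyond
24 h — and each registers its own corridor.

## Polarity and folliculogenesis

Each epithelial cell carries a polarity vector $\mathbf p$: direction =
basal-to-apical axis, magnitude = polarisation degree. Cues per unit
time:

* away from each endothelial neighbour: $\Delta\mathbf p = \rho\,
  \hat{\mathbf d}\,\Delta t$ with $\hat{\mathbf d}$ the unit vector from
  the neighbour centroid to the cell centroid;
* away from each unshared boundary edge (cue at the edge midpoint);
* toward each well-developed lumen (area above twice the initial lumen
  target) and toward each strongly polarised neighbour
  ($|\mathbf p| > p^\ast$) — the same rule with the sign of $\rho$
  flipped;
* an epithelial-epithelial magnitude adjustment $\mp\,\epsilon
  \cos\theta\,\Delta t$, with $\theta$ the angle between the cell's
  polarity vector and the centre-to-centre direction. The wording of
  this term is ambiguous in the source description; it is read here as a
  magnitude (not direction) modulation, with the minus branch taken when
  the neighbour is strongly polarised toward the cell (apical poles
  repel) and plus otherwise. `eq5_repulsion = FALSE` switches to the
  always-plus reading.

$|\mathbf p|$ is capped at 1; there is no decay term (none is
described), the cap plays that role. Endothelial and lumen cells carry
zero polarity. Defaults $\rho = 0.007\,h^{-1}$ (the boundary cue shares the same
rate but is exposed separately), $\epsilon = 0.004$,
$p^\ast = 0.6$: with a single persistent cue a cell needs roughly
$p^\ast/\rho \approx 75$ h to become competent, cells with two or three
aligned cues (boundary corners, endothelial contacts) a third of that —
which is what places the first lumina after about a day of simulated
development.

A vertex model cannot hold holes, so lumina are cells of a fifth type.
An epithelial cell that is polarised past $p^\ast$, older than 2 h and
not already touching a lumen divides along the line *perpendicular* to
$\mathbf p$ (so the daughters stack along the polarity axis); the distal
daughter — farther along $+\mathbf p$, i.e. at the apical pole — becomes
the lumen, with target area 0.1, lumen adhesion, zero polarity and no
proliferation, while the proximal daughter remains epithelial and keeps
the mother's polarity vector. Cells touching a lumen cannot create
another; instead their polarity feeds the existing one: each lumen's
target area grows by $\lambda_{\text{grow}} \sum |\mathbf p_i|\,\Delta t$
over its epithelial neighbours and never decreases;
$\lambda_{\text{grow}} = 0.004$ is anchored to the measured thirteen-fold
growth of the mean lumen section over the two days after the first
lumina appear. Lumina are exempt from T2 removal and from
the cycle machinery, so the lumen count is non-decreasing by
construction.

## Initial conditions

`build_voronoi_ic()` reproduces the image-based pipeline: cell-centre
tables (rectangle exports of a segmentation platform, midpoints as
seeds) plus a closed boundary annotation give a Voronoi tessellation
clipped by the boundary polygon, which also closes the infinite outer
regions. The tessellation is computed by half-plane clipping per seed
(nearest seeds first, with an early stopping radius) and verified in the
tests against a brute-force nearest-seed rasterisation. Coordinates are
rescaled so the median epithelial area is 1. No public dataset ships
the original sections, so `synthesize_e13_ic()` generates a synthetic
E13.5-like section: Poisson-disc (blue-noise) seeds inside a smooth
random blob (low-order Fourier perturbation of a circle), mimicking the
even nuclear spacing of the real image; four tip+stalk pairs are then
extruded at well-separated boundary sites exactly as in-simulation
branch addition, giving an endothelial area fraction below the 2%
measured at E13.5. Epithelial ages are uniform within each cycle and
the mature target areas are set so the within-cycle growth law continues
smoothly from those ages. No post-relaxation is applied before t = 0.

What the generator does *not* emulate: real section geometry (lobe
asymmetry, the parathyroid contact), endothelial cells lying at a
distance from the mass, segmentation noise, and any correlation between
cell size and position. Tests that pass on synthetic ICs therefore
validate the machinery and the calibrated regime, not the histology.

## Orchestration and numerical choices

`simulate_tissue()` advances chunks of 20 Euler substeps in compiled
code (forces, motile forces, corridor projection, trigger detection);
between chunks the R layer recomputes the VEGF field, updates polarity
and lumen growth (with the elapsed 0.02 h as the step), performs
divisions and branch addition, and re-runs classification and any
needed rearrangement sweep. Trigger detection prioritises degenerate
cells over short edges, and refused operations go on a skip list that is
cleared whenever the topology changes, so the loop always makes
progress. `step_tissue()` is the transparent single-step reference
path; a test checks the two agree. The stats cadence is 0.5 h.

The degenerate-input policy is uniform: every topological operation is
validated locally and reverted on failure; invariant-violating vertices
are tracked (and exempted from checks) until resolution; a run aborts
only on non-finite positions.

Determinism: all randomness (ages, cycle jitter, branch times, blob
shape, seed placement) flows through R's RNG, so a configuration plus
seed reproduces a run bit for bit.

Problem sizes: the reference configuration uses 200 epithelial cells,
dt = 0.001 h and 72 simulated hours (72,000 steps). The reproduction
script and the end-to-end tests run their 72 h replicates at 140
epithelial founders — a size chosen to keep three replicates in the
ten-to-fifteen-minute range on one CPU while preserving the
fragmentation regime and all calibrated outcomes — and the unit tests
exercise the same machinery on still smaller tissues and shorter
horizons.

## Known limitations

* 2D only; out-of-plane endothelial ingression is represented solely by
  the branch-addition process, and is switched off after 24 h.
* Lumina are polygonal cells; they approach but never reach circular
  shapes.
* The epithelial-epithelial polarity term follows one reading of an
  ambiguous description (see above); the alternative is available but
  not the default.
* Parameters not fixed by the published measurements (energy table,
  polarity rates, motile force, branch rate) are calibrated, and the
  calibration targets are the simulated outcomes themselves; they
  should not be read as measured biophysical constants.
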