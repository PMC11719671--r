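---
title: "Quantifying aortic ring vessel networks and the Angiogenic Activity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic ring vessel networks and the Angiogenic Activity Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioring)
```

## The assay and the problem

In the aortic ring assay an arterial explant (here: a ring of roughly
0.5 mm radius, ~3.4 mm outer circumference) is embedded in a gel and
treated with a candidate pro- or anti-angiogenic agent, typically a stem-cell
secretome, against a serum-free control. Microvessels sprout from the ring's
outer edge and are imaged on days 1, 4 and 7. The readout is a *vessel
network*: primary ("initial") vessels attached to the ring, branches
attached to initial vessels or to other branches, junctions where branches
originate, and loops where tips anastomose back onto the network.

Angiogenesis readouts are notoriously heterogeneous across laboratories.
This package implements one standardized quantification: twelve operationally
defined parameters grouped into four subindex categories, a control-normalized
Angiogenic Activity Index (AAI) that condenses them into a single score, and a
radar-style *angiogenic profile* that keeps the per-parameter structure
visible. Around that core it provides a skeleton-image-to-network extractor
(replacing manual tracing of binary masks) and a stochastic outgrowth
simulator, so the entire pipeline can be exercised and tested without any
experimental data.

## The twelve parameters

`parameter_registry()` fixes names, categories and units:

```{r}
parameter_registry()
```

* **Explant** — `migration` (sprouting visible, scored as the percentage of
  rings that migrated). The ring circumference is measured and reported but
  treated as a covariate rather than a scored parameter, since it describes
  the explant, not the response.
* **Pattern** — `vessel_structure_pct` (initial vessels as a share of all
  vessels; 100% means no ramification yet) and `n_loops` (closed circuits of
  three or more interconnected segments).
* **Network properties** — maximum radial outgrowth (shortest distance from
  the farthest tip to the ring boundary, i.e. measured "at a right angle" to
  the ring, not along the vessel), maximum initial vessel length (path length
  along the vessel, branches ignored), total and mean vessel length, and the
  growth speed of the mean initial vessel length between imaging days, using
  the exact elapsed time (µm/h and µm/day).
* **Sprouting** — vessel density (initial vessels per mm circumference),
  branch count, mean branch length, and junctions per initial vessel.

The registry measures a few more quantities than it scores (raw vessel and
junction counts, the per-hour speed variants, the maximum-length speed): the
scored twelve avoid counting any quantity twice in the index. The scored set
is configurable in `aai_config()`.

Two definitions deserve spelling out because manual counting leaves them
implicit:

* **Junctions.** A junction is a distinct point where at least one branch
  originates. Attachment points closer than a merge tolerance (default
  5 µm, configurable) are one junction, since neither a human tracer nor a
  rasterized skeleton can separate them. Anastomosis points, where a tip
  fused onto a vessel, also attach a branch and are counted.
* **Loops.** Segments are subdivided at every attachment node and the
  resulting graph's cycle rank (independent cycles, `m − n + c`) is computed
  after removing self-loop edges and collapsing parallel edges. The removal
  step is exactly what restricts counting to circuits of three or more
  segments: one- and two-segment closures appear as self-loops and parallel
  pairs. This makes the visually motivated definition ("three or more
  branches interconnected, forming a circle") computable and
  orientation-independent.

One relation often assumed — that the maximum initial vessel length bounds
the maximum radial outgrowth — is *not* an identity once branch tips are
included in the radial measurement (a long branch on a short initial vessel
can reach farther than any initial vessel's own path length). The package
therefore tests the provable forms: total length dominates radial outgrowth,
and each initial vessel's path length dominates its own tip's boundary
distance. In practice the two maxima usually do order as expected, which is
why curved growth makes the initial-length maximum "slightly higher".

## The Angiogenic Activity Index

For each parameter, with treatment values $T$ and control values $C$ at an
early and a late treatment day (defaults: days 4 and 7),

$$\mathrm{AAI} \;=\; \frac{(T_{7}-T_{4}) - (C_{7}-C_{4})}{C_{7}-C_{4}},$$

optionally sign-flipped by a per-parameter orientation. Zero means the
parameter changed exactly as in the control; +1 means the change doubled the
control change; −1 means no change at all. Because the index is a ratio of
differences it is invariant under affine unit rescaling (µm vs mm) — another
property the tests pin down.

Per-parameter values are aggregated per category into a subindex

$$\mathrm{SI} = \frac{1}{n}\sum_{i=1}^{n} w_i\,\mathrm{AAI}_i,$$

where the $w_i$ are predictive-importance factors (default 1; parameters
judged especially informative for complex vascular architecture may be given
factor 2 via the config file). Dividing by the parameter count $n$ rather
than by $\sum w_i$ is deliberate: it lets up-weighted parameters push a
subindex — and the final index, the plain mean of the four subindices —
beyond ±1, which is how a strongly pro-angiogenic sample can score above 1.
The weight-normalized variant (`subindex_mode = "normalized"`) is provided
for sensitivity analysis.

Aggregation across rings follows the assay workflow: under
`aggregation = "per_donor"` (the default) the index is computed from each
donor's own group means — every donor carries their own control — and the
per-donor indices are averaged; `"pooled"` uses grand group means, which is
appropriate for single-donor or fully randomized designs.

Decisions the formulae leave open, and how this package resolves them:

* **Zero control change.** Dividing by a tiny ΔC would manufacture huge
  indices, so the default policy is a hard error naming the parameter;
  an explicit `epsilon` fallback can be opted into. When both changes are
  exactly zero the parameter AAI is defined as 0 — the continuous limit of
  the "treatment equals control" anchor. This case occurs routinely for
  migration when every ring in both groups has sprouted by day 4.
* **Orientation of declining parameters.** All orientations default to +1,
  including `vessel_structure_pct`, which *falls* as angiogenesis proceeds.
  No sign flip is needed for a parameter whose control change is negative:
  the ratio of differences already scores "same direction as control but
  stronger" as positive. The orientation map exists for users who prefer an
  explicit convention.
* **Rings that never migrate** contribute `migration = 0` and zero counts,
  but *missing* (not zero) length and speed values: averaging zeros into
  length parameters would conflate absent outgrowth with short vessels.
  Group means drop missing values.

`build_profile()` lays the per-parameter values out on a circle ordered by
category (explant → pattern → network properties → sprouting);
`plot_profile()` renders the radar chart with the zero circle marking
control-level activity.

## From binary masks to networks

`extract_network()` replaces manual tracing for users who segment their
micrographs into binary vessel + ring masks. The vessel mask (ring interior
excluded) is thinned with the Zhang–Suen algorithm; vessel pixels abutting
the ring are anchored against deletion so end erosion cannot detach a vessel
from the explant, and skeleton endpoints are regrown through the original
mask to restore the tip length that thinning erodes from blunt stroke ends.
Skeleton pixels are classified by 8-neighbour count (endpoint = 1, path = 2,
node ≥ 3), node-to-node paths are traced with diagonal steps weighted √2,
and lengths are measured on chord-resampled paths (every 4th pixel), which
removes most of the ~8% digitization overestimate of raw 8-connected chains.

Graph cleanup and vessel individuation then mirror what a careful human
tracer does:

* terminal spurs shorter than `spur_min_length` (default 20 µm) are removed
  as thinning artifacts, pass-through nodes left behind are spliced, and
  very short edges joining two junctions are collapsed — a junction zone
  several pixels wide can thin into a micro-cycle that is one junction, not
  a loop;
* the cleaned graph is rooted at the ring by breadth-first search (where
  several edges meet the ring at one contact, the longest is the initial
  vessel) and cycle-closing arrivals are noted;
* traced edges are reassembled into vessels by pairing, at every junction,
  the two edge stubs whose directions continue each other most straightly
  (within 60° of straight through, directions measured over ~40 µm so the
  junction blob's local distortion averages out). Pairing is globally
  greedy per node, so a vessel passing through a junction is reassembled
  even when its two halves were discovered from opposite ends of a cycle,
  and a fused tip cannot claim another vessel's continuation;
* hierarchy is re-derived from the free chain ends: a ring end makes an
  initial vessel; an attachment end makes a branch; any other end sitting
  at a shared node is recorded as an anastomosis, which is what preserves
  every loop of the skeleton in the output network.

Rasterization has inherent resolution limits, so exact recovery is only
claimed for *well-separated* networks, and `is_well_separated()` makes that
precondition checkable on the true geometry (it knows nothing about the
extraction): distinct vessels keep ≥ 10 µm clearance away from their
connecting nodes (at 2 µm/px the drawn strokes are 3 px wide), junction
events are mutually ≥ 12 µm apart (which also excludes four-way meets such
as two tips fusing at one point), no segment is shorter than 30 µm, nodes
clear segment endpoints by ≥ 30 µm (an attachment just short of a free tip
leaves a stub that spur pruning would remove), branches depart ≥ 45° from
the parent tangent and anastomoses approach ≥ 30° off the target tangent
(nearly parallel arms cannot be told apart in a raster), and vessels stay
clear of the ring except at their own attachment. On simulated networks
satisfying the predicate — sampled at branch angles of 50–90° and 10°/day
direction jitter, comfortably inside the resolvable regime — vessel,
branch, junction and loop counts are recovered exactly and
total/mean/maximum lengths to well within 5%; the tests enforce this on 20
rendered networks at 2 µm/px, and the acceptance script recomputes the
exact-recovery fraction and worst length error for any requested seed.
Individual very short branches still carry pixel-scale absolute error
(junction displacement plus tip erosion, several µm), which is visible in
the mean *branch* length when a network has only a few short branches.

## The outgrowth simulator

`simulate_ring_series()` is a phenomenological generator of the assay's
observable time course, not a model of endothelial signalling. One ring is
simulated in 0.25-day steps:

* initial vessels are recruited on the ring as a Poisson process at constant
  rate over the first 7 days, with expected total `seed_density` per mm of
  circumference (default 12/mm) — so vessel density rises across imaging
  days, as observed;
* tips elongate at `elongation` µm/day (default 100) with small directional
  jitter (default sd 20°/day), starting radially;
* branches spawn along newly grown length at `branching_rate` events per mm
  grown (default 1.5/mm), at 30–90° from the parent, but only after a
  1.5-day onset lag — ramification follows the initial sprouting phase, which
  is what makes day-1 networks 100% primary vessels;
* a tip that comes within `capture_radius` (default 15 µm) of another vessel
  (not itself, its parent or its own children) fuses with probability
  `anastomosis_prob` (default 0.15) per step, redirecting its final growth
  step onto the fusion point and closing a loop.

Treatments multiply elongation and branching by `treatment_multiplier`;
an optional lognormal per-donor factor (sd 0.1) models donor variability.
Each ring draws from a counter-based substream of the experiment seed, so
adding rings never perturbs existing ones, and later-day snapshots contain
earlier ones as sub-geometries (monotone growth).

The control defaults were chosen once for day-7 plausibility against the
assay's reported magnitudes — a ~3.4 mm ring carrying tens of initial
vessels, maximum radial outgrowth around 650 µm, mean branch lengths around
100–150 µm, junctions and loops emerging between days 4 and 7 — while
keeping the whole multiplier range 0.5–2 in a bounded growth regime: because
a multiplier scales elongation *and* branching, the branch cascade rate
grows with its square, and a branching rate high enough to reproduce the
heaviest observed ramification in the *control* would make a doubled
treatment explode combinatorially. The compromise (control ramification at
the lighter end of the observed range, treated groups squarely inside it) is
deliberate and keeps a 5-group, 50-rings-per-group calibration experiment
under a few minutes. What the simulator does not emulate: gel heterogeneity,
vessel regression, diameter/lumen structure, cell-level phenotypes, or
imaging segmentation noise — so green tests demonstrate correctness of the
*quantification and scoring machinery*, not biological validity on real
micrographs.

Under these conditions the package's acceptance suite checks the index
end-to-end: a multiplier-1 "treatment" scores |final AAI| < 0.15 with
50 rings per group, and the final AAI increases strictly across multipliers
0.5 / 1.0 / 1.5 / 2.0.

## Numerical choices and edge cases

* Coordinates are continuous 2-D µm with the origin at the ring centre;
  images use 0-based pixel indices with a stated pixel size (a pixel centre
  sits at (index + 0.5) × pixel size).
* Node merge tolerance (junctions, loop graph): 5 µm default everywhere.
* Degenerate geometry (polylines with < 2 points, zero lengths,
  self-intersecting ring polygons, non-positive sector angles) raises classed
  errors (`angioring_invalid_geometry`, `angioring_invalid_angle`, ...);
  undefined parameters on empty networks raise
  `angioring_undefined_parameter` rather than returning 0.
* The vessel area helper defaults to the plain circular-sector formula
  ((θ/2)·r²) rather than extrapolating an annulus around the whole ring; the
  measured gel areas are far below a full-circle extrapolation, so the
  conservative sector is the default and `annulus_sector` mode is opt-in.
* Ties in skeleton rooting (two segments at one ring contact) resolve to the
  longer segment as the initial vessel; BFS order is deterministic, so
  extraction is reproducible byte-for-byte.
* Report CSVs round to 3 significant figures; JSON keeps full precision.

## Sizes used by the test and acceptance runs

The shipped tests run the oracle-equivalence property on 100 random
networks of up to 20 segments, the rendering round trip on 20 well-separated
simulated rings at 2 µm/px, and the calibration experiment at 50 rings per
group for five groups; the acceptance script uses 3 donors × 5 rings per
group for the scored experiment, mirroring the assay's replicate structure.
These sizes keep full runs in the minutes range on a single core while
leaving the Monte-Carlo checks well-powered.

## Known limitations

* The extractor consumes *binary* masks; segmentation of raw brightfield
  micrographs is upstream and out of scope.
* Exact count recovery is guaranteed only under the well-separated
  precondition; densely entangled day-7 networks rasterized at coarse pixel
  sizes will under-resolve junctions, exactly as manual tracing does.
* A branch attached exactly at its parent's free tip is indistinguishable
  from a continuation in any raster — such networks fail
  `is_well_separated()` by construction.
* The AAI compares two time points; kinetic designs with more imaging days
  are supported by the measurement table but only one early/late pair enters
  the index per report.
* 3-D networks, vessel diameters, perfusion and cell-level readouts are out
  of scope.
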