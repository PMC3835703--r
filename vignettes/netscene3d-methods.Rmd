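---
title: "netscene3d: models, parameters and design choices"
author: "netscene3d authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netscene3d: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscene3d)
```

This vignette is the package's own account of the science it implements:
the force model and its multilevel acceleration, the motion-network and
synchronization algebra, the bubble definition for assembly graphs, what
the synthetic generators do and do not emulate, and the numerical and
design choices made where more than one defensible option existed.

## 1. The force model

Layout is a 3D spring embedder in the Fruchterman–Reingold family. With
`d` the current Euclidean distance between two nodes and `k` the ideal
edge length,

* every node pair repels with magnitude `k²/d`,
* every edge attracts its endpoints with magnitude `d²/k`,
* each node's displacement per iteration is its force sum, capped at a
  temperature that decays geometrically.

An isolated connected pair is stationary exactly at `d = k` (the two
magnitudes coincide there), which gives the model its unit: all lengths are
multiples of the ideal edge length. The ideal length is
`k = C·(volume/n)^(1/3)`; the defaults `C = 1`, `volume = n` allocate one
unit cell per node and make `k = 1`.

Assumptions worth stating: forces ignore edge weights and directions (a
directed assembly view is laid out like its undirected skeleton);
self-loops exert no force; the model knows nothing about node sizes, so
very unequal visual sizes can overlap regardless of layout quality.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `C` | 1 | – | overall scale; rarely worth changing |
| `volume` | `n` | k³ | one unit cell per node keeps density seed-independent |
| `iterations` | 50 | – | enough for graphs of a few hundred nodes to settle |
| `coolingFactor` | 0.95 | – | geometric decay; displacement cap after t iterations is `T₀·0.95^t` |
| `initialTemperature` | `0.1·k·n^(1/3)` | k | a tenth of the initial layout radius: large early moves without teleporting |
| `neighborhood` | `"all-pairs"` | k | exact repulsion for the single-level embedder |
| `maxPartners` | 40 | – | per-node repulsion budget in neighbourhood mode (see §2) |
| `coarsestSize` | 50 | nodes | recursion floor; toy graphs bypass coarsening so tests stay interpretable |
| `jitterRadius` | `k/4` | k | prolongation offset; small enough that siblings start as a tight cluster |
| `seed` | 42 | – | every random draw derives from it; layouts are bit-reproducible |

### Equilibrium versus default schedule

The default schedule (50 iterations, cooling 0.95) is a *drawing* schedule:
it produces a readable layout quickly, but the temperature reaches ~8% of
its initial value by iteration 50 and the layout freezes. Slowly
symmetrizing structures — a 20-ring is the canonical example — freeze
slightly uneven: across seeds we observe edge-length coefficients of
variation between about 0.06 and 0.19 at the default schedule. Statements
about *equilibria* (pair distance `= k`, equal triangle sides, uniform ring
edges) are therefore measured at convergence, with
`layoutParams(iterations = 300, coolingFactor = 0.98)`; under that schedule
the 20-ring CV drops below 0.001 for every seed we probed (1–10). The
package defaults are unchanged; the convergence schedule is an explicit
argument wherever an equilibrium is being measured.

```{r equilibrium}
pair <- readSIF(text = "A pp B")
st <- frLayout(pair, layoutParams(seed = 1, iterations = 300,
                                  coolingFactor = 0.98))
sqrt(sum((st@positions[1, ] - st@positions[2, ])^2))   # ~ 1 = k
```

## 2. The multilevel scheme

Exact all-pairs repulsion is `n²/2` evaluations per iteration. For large
graphs `multilevelLayout()`:

1. **coarsens** by greedy maximal matching over edges in a seeded-random
   order — matched pairs collapse to a supernode named after the smaller
   member, self-loops vanish, parallel coarse edges merge with summed
   weight — repeating until ≤ `coarsestSize` nodes remain or no edge can be
   matched (node count strictly decreases at every productive level, and
   collapsing an edge cannot disconnect anything, so connectivity is
   preserved);
2. **lays out the coarsest graph** with the exact single-level embedder;
3. **prolongs** positions level by level (each fine node at its supernode
   plus a random offset of norm ≤ `jitterRadius`, never exactly coincident)
   and **refines** with neighbourhood-limited repulsion.

Neighbourhood-limited repulsion uses a uniform spatial grid with cell size
equal to the cutoff radius `2k`: each node evaluates repulsion against
candidates from its 27 surrounding cells, nearest cells first, and stops
after `maxPartners` in-range partners. The budget is the load-bearing part
of the design: a grid cutoff alone bounds work only while local density is
bounded, but a dense graph (tens of edges per node) contracts under
attraction until arbitrarily many neighbours sit inside any fixed cutoff,
and the cutoff then degenerates to all-pairs. The deterministic per-node
budget guarantees ≤ `maxPartners·n` repulsive evaluations per iteration —
`40n`, against `n²/2 = 5000n` at `n = 10 000` — regardless of density, at
the cost of approximating the repulsive field in dense regions by its
nearest contributors. Edge attraction is always exact and costs `m`
evaluations; the two counts are logged separately per (level, iteration) in
`LayoutState@evalLog`.

`force_evaluations` in all reported numbers means *repulsive pair
evaluations*, the quantity the multilevel scheme actually bounds.

Problem sizes used in the shipped checks: the capacity run is one seeded
10,000-node / 250,000-edge uniform random graph (the acceptance script
reports its wall time rather than asserting one); equilibria use 2–20
nodes; oracle comparisons use ≤ 12 nodes for forces and ≤ 30 for bubbles.

## 3. Motion networks and scene synchronization

A motion network stores an ordered frame sequence as its union graph plus
per-frame mutation events: edge deletes, node deletes, node inserts, edge
inserts, each class sorted by element id. Replaying events 1..t from the
empty graph reproduces frame t exactly — this replay invariant is the
definition of correctness and is property-tested on random churned frame
sequences.

Animation renders every frame on the fixed union layout: visibility
changes, positions do not. The alternative (re-laying-out each frame) reads
better per frame but destroys object permanence between frames, which is
the point of a motion display. Discrete frames are emitted; interpolated
transitions would be a renderer-side extension.

The same event algebra synchronizes clients. `sceneDiff(x, y)` emits the
minimal ordered event list with server-assigned consecutive sequence
numbers; `applyEvents` enforces contiguity (stale or out-of-order sequence
numbers, double inserts and unknown deletes are errors) and satisfies
`applyEvents(x, sceneDiff(x, y)) = y` exactly — exact, not approximate,
which is why scenes store their element collections in canonical
(C-collation) order and serialize numbers at 17 significant digits. The
wire form is a full-state snapshot followed by newline-delimited JSON
events (`docs/protocol.md`); a late subscriber starts from a snapshot at
its join point, so any two consumers of the same stream prefix hold
byte-identical serialized scenes. Transport is any R connection (file,
pipe, socket); the server object itself is in-process and clients are
read-only mirrors.

## 4. Assembly graphs and bubbles

`readLastGraph()` interprets the Velvet dump conservatively: header, `NODE`
blocks (id, length, remaining numeric columns kept as uninterpreted
coverage values — the column layout varies across Velvet versions) and
signed `ARC` records; short-read tracking records are skipped. Conversion
folds orientation: `±a` is one node, an arc `(±a, ±b)` one undirected edge,
reverse-complement twin arcs merge with summed multiplicity, and the signs
are preserved as 5'/3' end labels on the edge (twins agree on the label
after folding; genuinely different merged junctions get `"mixed"`). The
directed, orientation-signed alternative remains available via
`keepOrientation = TRUE`.

**Bubble definition.** A bubble is a pair of nodes joined by at least two
internally node-disjoint simple paths, each with at least one interior node
and at most `maxPathLen` edges. Two refinements over the bare
"two disjoint paths" phrasing are needed to make counting well-defined:

* *interior requirement* — without it, a direct edge plus any detour counts
  as a bubble, and every cycle of length ≤ 2·`maxPathLen` contributes one
  "bubble" per vertex pair on it;
* *node-set deduplication* — in a plain cycle, every sufficiently separated
  vertex pair sees the same two arcs as "its" disjoint paths. Candidate
  pairs whose maximal disjoint path sets span exactly the same node set are
  one physical structure and are counted once, reported from the
  endpoint pair with the largest degrees (the branching nodes where an
  embedded bubble meets its backbone), ties broken by id order.

Under these rules the minimal diamond is exactly one bubble, a simple path
has none, and implanting b diamonds into a backbone yields exactly b.
Nested structures with distinct node sets count separately per endpoint
pair. The default `maxPathLen = 10` reflects that bubbles from sequencing
errors and small variants are short; the bound also keeps the search (a
bounded depth-first enumeration from every node of degree ≥ 2, followed by
a greedy maximal disjoint-path selection in canonical order) tractable.
Correctness is established against an independent exhaustive oracle that
enumerates *all* simple path pairs per endpoint pair on 250 seeded
instances; the random-graph arm of that comparison uses `maxPathLen = 6`,
because the exhaustive oracle's cost grows exponentially with the bound
while the detector's pruning does not — 6 exercises every code path
(reconvergence, nesting, dedup) at a cost the oracle can afford.

## 5. Synthetic generators: what they emulate, what they don't

* `randomGraph(n, m, seed)` — uniform simple graphs; the null model for
  property tests, not a model of biological topology (no degree
  heterogeneity, no clustering).
* `syntheticAssembly(nNodes, nBubbles, seed)` — a backbone contig path with
  diamond implants and non-reconvergent decoy branches, random orientation
  signs, multiplicities 1–20, lengths 5–60, random DNA sequence lines. It
  emulates the *topology* Velvet emits around short variants; it does not
  model coverage structure, repeats, palindromes, or chimeric joins, so
  passing recovery tests says nothing about those.
* `syntheticTimecourse(graph, nFrames, seed)` — i.i.d. log-normal values
  per node per frame: positive and right-skewed like expression/flux data,
  but with no temporal autocorrelation and no network structure in the
  signal.
* `syntheticFrames(graph, nFrames, churn, seed)` — per-frame random hiding
  of a fixed node fraction, the presence/absence pattern of per-condition
  molecular networks; real condition series are not independent across
  frames.

All generators are pure functions of their parameters and seed, and their
outputs re-parse through the package's own readers without warnings.

## 6. Numerical choices and degenerate inputs

* Exactly coincident nodes are separated by a deterministic index-derived
  offset of order `10⁻⁶k` before force evaluation (division by zero guard;
  no RNG, so layouts stay reproducible).
* Displacement capping happens after force summation, per node.
* Layouts are centred on the origin at the end of every refinement, so a
  single node sits exactly at the origin.
* All identifier ordering uses C-collation radix sorting, making object
  canonicalization locale-independent.
* Coordinates serialize at 17 significant digits (`%.17g` in GraphML, 17
  digits in JSON), the round-trip-exact width for IEEE doubles.
* Constant-value style mapping sends every element to the midpoint of the
  target range (avoids invisible elements); empty graphs and header-only
  tables are valid and round-trip as such.
* Parsers never silently drop malformed lines: every format error names a
  line or row.

## 7. Known limitations

* The per-node repulsion budget trades global repulsive accuracy in dense
  regions for the evaluation bound; aesthetics of very dense graphs are
  accordingly coarse (they are also unreadable at any accuracy).
* Bubble search cost grows with `maxPathLen` and with local branching;
  pathological dense graphs can exceed the path-enumeration guard
  (an explicit error, not silence).
* The synchronization server is single-writer by design; concurrent
  writers would need conflict resolution that the event algebra does not
  attempt.
* No renderer is included: scenes are data. The scene JSON is designed to
  be trivially consumable by WebGL/three.js-style viewers.
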