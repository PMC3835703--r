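# netscene3d

Three-dimensional scenes for biological networks: multilevel force-directed
layout, time-course/condition animation, multi-client scene synchronization,
and de Bruijn assembly-graph conversion with bubble detection.

## What this is for

Large biological networks — protein interaction maps, metabolic
substrate–product networks, MS/MS molecular networks, genome-assembly
contig graphs — quickly become unreadable in two dimensions: hubs overlap,
crossings pile up, and reconvergent structures hide behind other edges. An
extra spatial dimension disperses exactly those regions. `netscene3d` is an
R toolkit for building such 3D views programmatically: it lays networks out
in 3D, maps experimental values (expression, flux, spectral counts) onto
node sizes, edge thicknesses and heat-map colours, animates condition series
as *motion networks*, keeps multiple rendering clients in lockstep through a
mutation-event stream, and converts Velvet `LastGraph` assembly output into
networks in which *bubbles* — the reconvergent path pairs that sequencing
errors and biological variants leave in a de Bruijn graph — are detected
automatically and verified against an exhaustive oracle.

It is aimed at bioinformaticians who need reproducible, scriptable 3D
network scenes (written to a documented JSON/GraphML form and rendered by
whatever viewer they prefer), not at interactive GUI users.

## The models at the core

**Spring embedder.** Layout is force-directed in the Fruchterman–Reingold
family: every node pair repels with magnitude `k²/d`, every edge attracts
with `d²/k`, where `d` is the current distance and `k = C·(volume/n)^{1/3}`
is the ideal edge length (defaults `C = 1`, `volume = n`, so `k = 1` and all
lengths are in ideal-edge-length units). Per-iteration displacements are the
force sums capped at a geometrically cooled temperature. An isolated
connected pair is stationary exactly at `d = k`.

**Multilevel scheme.** Single-level force layout is quadratic per iteration
and impractical beyond a few hundred nodes. `multilevelLayout()` coarsens
the graph by greedy maximal matching (matched pairs collapse to supernodes)
until at most 50 nodes remain, lays out the coarsest graph exactly, then
prolongs positions back level by level (children jittered around their
supernode within `k/4`) while refining with *neighbourhood-limited*
repulsion: a uniform spatial grid of cell size `2k` with a deterministic
per-node partner budget (40 partners, nearest cells first). Per-iteration
repulsive force evaluations are therefore bounded by `40·n` instead of
`n²/2`; a 10,000-node, 250,000-edge random graph lays out in well under a
minute on one core.

**Motion networks.** An ordered frame sequence (time points or conditions)
is stored as its union graph plus per-frame mutation events (deletes before
inserts, sorted); replaying events 1..t from the empty graph reproduces
frame t exactly. Animation renders every frame on the *fixed* union layout,
so elements appear and disappear but never drift. The same event algebra
(`sceneDiff`/`applyEvents`, with `apply(x, diff(x, y)) = y` exactly) drives
client synchronization: a server logs events, clients join on a full-state
snapshot and replay deltas, so all clients that consumed the same stream
hold byte-identical scenes.

**Bubbles.** After orientation folding (an arc `(±a, ±b)` becomes the
undirected edge `a–b`, reverse-complement twins merged with summed
multiplicity), a bubble is a node pair joined by ≥ 2 internally
node-disjoint simple paths, each with at least one interior node and at most
`maxPathLen` (default 10) edges; pairs whose disjoint-path sets span the
same node set are one structure and are reported once, from the
highest-degree (branching) endpoints.

## A worked example

Generate a 30-node synthetic Velvet assembly with three implanted bubbles,
convert it, detect the bubbles, and lay it out:

```r
library(netscene3d)

lg  <- syntheticAssembly(30, 3, seed = 7)     # LastGraph text
asm <- readLastGraph(text = lg)
g   <- assemblyToGraph(asm)
g
#> NetGraph: 30 nodes, 32 edges (undirected)
#>   node attributes: length, cov1, cov2
#>   edge attributes: multiplicity, end_source, end_target

detectBubbles(g, maxPathLen = 10)[, c("source", "sink", "nPaths", "maxPathLen")]
#>   source sink nPaths maxPathLen
#> 1     14    6      2          2
#> 2      2    7      2          2
#> 3     26   29      2          2

st <- multilevelLayout(g, layoutParams(seed = 42))
st
#> LayoutState: 30 nodes, 21750 repulsive force evaluations
str(layoutQuality(g, st))
#> List of 3
#>  $ edgeLengthMean: num 1.86
#>  $ edgeLengthCV  : num 0.154
#>  $ minSeparation : num 0.772

connectionReport(g, "14")        # a contig's connections, by 5'/3' end
#>   neighbor end multiplicity interaction
#> 1       11  3p            2         arc
#> 2        9  3p           20         arc
#> 3       30  5p           11         arc
```

The three detected `(source, sink)` pairs are exactly the three implanted
diamonds. `edgeLengthCV` is the coefficient of variation of laid-out edge
lengths (the layout-uniformity metric); `connectionReport` tabulates a
contig's neighbours with arc multiplicities, grouped by which end (5'/3')
the connection touches — the scaffolding view of a contig.

The same pipeline is available from a shell via the bundled executable:

```sh
netscene3d fixtures --kind assembly --n 30 --bubbles 3 --seed 7 --out toy.LastGraph
netscene3d convert  --lastgraph toy.LastGraph --out toy.sif
netscene3d bubbles  --input toy.sif --maxlen 10 --out bubbles.tsv
netscene3d layout   --input toy.sif --method multilevel --seed 42 --out scene.json
```

Scene JSON and the synchronization event stream are documented in
`docs/scene-format.md` and `docs/protocol.md`.

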