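---
title: "Models and algorithms behind wirefold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms behind wirefold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wirefold)
```

wirefold turns a polygon mesh into a nucleotide-complete DNA or RNA
wireframe nanostructure in four stages — routing, cylinder model,
nucleotide model, sequence design — with validators at the end of the
pipeline. This vignette explains the models, the parameters that matter,
and the numerical and design choices made where the underlying methods
leave freedom.

## Meshes and the rotation system

The input is a surface mesh (`v`/`f` records of an OBJ file); faces are used
as given, never triangulated or repaired. For routing, only the wireframe
graph matters: vertices with 3D positions, edges with Euclidean lengths.
The one additional structure is the *rotation system* — the cyclic order of
edges around each vertex. On a closed orientable 2-manifold it is induced
by face adjacency (walking the fan of faces around the vertex), and it is
what makes "sharp turns" at junctions well defined for A-trail routing. For
wireframes that are not manifolds, wirefold falls back to the angular order
of edge directions projected on the vertex star's least-variance plane;
this keeps the spanning-tree, cycle-cover and Xuong-tree methods available
on any connected wireframe, at the price that the fallback rotation is a
geometric heuristic with no topological guarantees. Vertex welding
(`merge_epsilon`) is off by default because merging near-duplicate vertices
can silently change the topology the user meant to design.

Genus is computed from the Euler characteristic, $V - E + F = 2 - 2g$, and
only reported when the mesh is a closed orientable connected manifold.

## Routing models

**A-trail (`at_dna`).** The scaffold must traverse every edge exactly once,
turning at every junction onto a rotation-adjacent edge. Odd-degree
vertices first get parallel edge copies along a minimum-length T-join: odd
vertices are matched pairwise by shortest-path distance (exact bitmask-DP
matching up to 14 odd vertices, greedy beyond — every bundled fixture has at
most 12) and each edge on a matched path is doubled, the copy sitting next
to its original in the rotation. At an even-degree vertex the sharp-turn
condition admits exactly two pairings of the incident edge slots into
adjacent pairs, so the search is branch-and-bound over one binary choice
per vertex, in decreasing-degree order, pruned by a union-find over edges:
closing a second separate cycle can never extend to a single Eulerian
circuit. On topological spheres a sharp-turn circuit is unknotted; toroidal
meshes are searched too but the package makes no knottedness claim for
them, and manually designed trails can be imported (`import_atrail`), with
non-sharp circuits accepted under a warning.

**Spanning tree (`st_dna`).** Prim's algorithm in its maximally branching
form (the frontier vertex adjacent to the most tree vertices wins; ties go
to the lowest index) gives the tree; the scaffold walks its boundary,
visiting each co-tree edge out-and-back, so every edge is covered exactly
twice in antiparallel directions by the scaffold — each edge is a two-helix
bundle. Helix lengths are rounded to whole turns (half-down, never below
one turn) so the staple pattern lines up. The exact stapling pattern of
two-helix-bundle designs is not reproduced in detail: staples are derived
by complementing the scaffold and nicking at junction helix ends, which is
an approximation the validators treat on an equal footing with the other
methods.

**Cycle cover (`cc_dna`).** Tracing "next edge = rotation successor of the
reversed edge" partitions the directed edges into closed cycles — the face
boundaries when the rotation comes from a mesh — covering every edge once
per direction, with all arms of each junction connected through one cyclic
transition. This is the scaffold-free model: the cycles are the strands.

**RNA spanning tree (`st_rna`) and Xuong tree (`xt_rna`).** A single RNA
strand walks the tree twice; each co-tree edge is realised as two hairpins,
one per endpoint, meeting at the edge midpoint as a 180° kissing-loop pair.
The Xuong variant instead chooses the spanning tree minimising the number
of odd-sized co-tree components, because only odd components force a
kissing loop; the cycle rank's parity is a lower bound, and on fully
triangulated meshes at most one loop remains. Exact Xuong trees are found
by enumerating spanning trees (Kirchhoff count first; refused above a
10^5-tree budget) — chosen over the polynomial matroid-parity algorithm
because at package scale the enumeration doubles as its own correctness
oracle — with a tree-edge swap local search, started from the Prim tree and
never worse than it, for larger graphs. The strand's single 3′-to-5′ nick
goes to the longest wireframe edge, where the open ends strain the
structure least.

All routings are deterministic: ties everywhere break toward the lowest
vertex or edge index.

## Cylinder model

Each duplex becomes a rigid cylinder with a 4×4 transform (local Y = helix
axis). Diameters are fixed at 2.0 nm (B-DNA) and 2.3 nm (A-RNA); rise and
twist default to 0.332 nm/bp at 10.5 bp/turn (DNA) and 0.281 nm/bp at 11.0
bp/turn (RNA) — the standard helical parameters consistent with those
diameters, configurable in `helix_geometry()`. The user's `scale`
(nm per mesh unit) fixes absolute size: a unit edge at scale 1 nm is a 1 nm
cylinder. At each junction a cylinder retreats from the vertex by
$d = r / \tan(\alpha/2)$, where $\alpha$ is the smallest angle to a
neighbouring edge — the distance at which two cylinders of radius $r$
meeting at angle $\alpha$ just stop overlapping — clamped to at most 40 % of
the edge so short edges stay representable; `bp_count` is the floor of the
usable length over the rise, and a scale too small to give every edge
`min_bp` base pairs is rejected with the offending edges listed. The
azimuth reference of each cylinder points toward the lowest-index
neighbouring vertex, a covariant choice that makes the whole nucleotide
model move rigidly with the input mesh (a property the test suite checks).
Strand backbones sit at 0.9 × radius with a minor-groove offset of 120°
(DNA) / 139° (RNA) between paired backbones.

Relaxation treats cylinders as rigid bodies joined by zero-rest-length
springs at their connection points, integrated with damped explicit steps
(defaults: 500 steps, dt 0.01, stiffness 1, damping 0.5) plus a penalty
force when two cylinder axes come closer than the sum of radii
(sphere-swept-segment distance, 0.1 nm tolerance). The integrator returns
the best state seen, so the spring objective never increases; ties go to
the later state so that pure collision resolution, which leaves the spring
objective flat, still takes effect. A diverging integration (non-finite
state) aborts with advice to reduce the step.

## Nucleotide model

A template double helix is generated along Y per cylinder and mapped by the
cylinder transform. Orientation vectors follow the oxDNA convention (`a1`
backbone→base, `a3` along the axis 3′→5′), so export needs no conversion.
Linked strand ends are joined by linker nucleotides placed by spherical
linear interpolation about the junction vertex; the count defaults to
`round(gap / 0.6 nm) − 1`, capped at 5 — 0.6 nm being a comfortable
inter-nucleotide backbone step — with coincident or antipodal ends falling
back to linear interpolation. Kissing-loop cylinders are rewired mid-helix
into two hairpins; the central 7 pairs keep their pairing across hairpins
(that retained pairing *is* the modelled kissing interaction) and 2 bases
per side are unpaired for loop slack — motif dimensions are configurable,
and a flagged cylinder shorter than the motif (13 bp at the defaults) is an
error rather than a silent deformity.

Nicking maximises the strand count subject to the stability rule that
every contiguous binding domain of every resulting strand keeps at least
`min_overlap` (default 8 nt) paired bases: all candidate nicks are
inserted — helix ends at junctions for scaffolded designs, staggered
mid-helix bonds for the cycle cover — and the nicks bounding the shortest
illegal domain are removed greedily until feasible. Cycles shorter than
twice the overlap stay circular with a warning. The scaffold is never
nicked; RNA designs receive exactly the one prescribed nick.

## Sequence design

Scaffolded designs take any user sequence (text or FASTA; M13mp18 is the
conventional choice, not bundled) or an emulated random scaffold, and set
every paired base to the Watson–Crick complement of its partner.
Scaffold-free designs run Focused Metropolis Search: mutate one free base
(with probability 0.9 inside an occurrence of a current longest repeated
substring), propagate the complement, reject hard-constraint violations
(per-strand GC within `gc_bounds`, default 0.30–0.70; forbidden
subsequences; pinned bases), and accept by the Metropolis rule on the
longest-repeated-substring objective at fixed temperature 0.5. The
best-so-far assignment is returned, making the reported objective monotone
in the iteration count; the acceptance schedule of the original local
search is not published, so these Metropolis defaults are package choices,
all configurable. The objective is evaluated by binary search over the
repeat length with vectorised k-mer duplicate scans — same complexity class
as a suffix automaton at these sizes, and checked in the tests against an
independent suffix-sort oracle. Only substrings wholly inside single
strands count, matching the objective's rationale (cross-strand repeats
cannot fold back within one molecule).

Kissing loops draw distinct entries from a bundled table of complementary
7-nt pairs; the table is a synthetic, clearly-labelled fixture
(`inst/extdata/kissing_loops_synthetic.tsv`) to be replaced by an
experimentally validated list for wet-lab work. RNA designs can also export
a NUPACK-style design file (nested dot-paren structure; kissing loops as
fixed-letter domains rather than bracket pairs, since their pairings are
pseudoknotted) and re-import the designed sequences.

## Exports

oxDNA legacy `.top`/`.dat` (nucleotides in strand order 5′→3′, 0-based
indices, circular strands wrapping their neighbour chain, coordinates in
nanometres), a pinned minimal subset of UNF 1.0.0 JSON, CSV strand lists
(RFC 4180), and plain-text route edge lists. The oxDNA writer/reader pair
is exercised as a round-trip identity (bases, connectivity, coordinates to
1e-6) on every fixture × method combination.

## What the fixtures do and do not show

The bundled meshes (Platonic solids at unit circumradius, a triangular
prism, a 2/0.7 quad torus) exercise every code path at desk scale: odd and
even degrees, triangular and quad faces, genus 0 and 1, upper-embeddable
and non-triangulated graphs. Test and acceptance runs use these shapes at
scales of 14–18 nm per mesh unit (edges of roughly 50–90 bp), Metropolis
runs of 10^2–10^4 iterations, and relaxation runs of 80–500 steps — sizes
chosen so the whole suite completes in minutes while still spanning all
branch points. Passing them shows the algorithms implement their contracts
(coverage laws, sharp turns, parity bounds, complementarity, round trips);
it does not show that a designed structure folds in the laboratory —
folding yields, salt dependence, and the real thermodynamics of kissing
loops are outside the model, and meshes with thousands of edges will need
the heuristic (not exact) Xuong mode and longer search budgets.

## Known limitations

- The A-trail search is worst-case exponential in the number of junctions;
  no knot-invariant computation is performed for toroidal meshes.
- Two-helix-bundle stapling uses the generic nicking engine, not the
  method's published crossover pattern.
- Relaxation is a damped explicit integrator, not a physics engine;
  extreme initial strain may need a smaller `relax_dt`.
- PDB export and multi-helix edge reinforcement are out of scope; so is
  running oxDNA or NUPACK themselves.
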