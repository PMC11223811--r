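# wirefold

Scriptable design of DNA and RNA **wireframe nanostructures**: given a 3D
polygon mesh (Wavefront OBJ), wirefold routes nucleic-acid strands along the
mesh edges, models every edge as a rigid double-helix cylinder, expands the
cylinders into an oriented nucleotide-level 3D model, designs the primary
sequences, and exports the result for simulation (oxDNA), interchange (UNF
JSON) and synthesis (CSV strand lists).

Wireframe designs realise only the edges and vertices of a target polyhedron
— one (or two) double helices per edge — which is economical in strand
material and folds well at low salt, at the cost of some rigidity. The hard
part is the routing: which closed path(s) the scaffold or the single RNA
strand should take so that every edge is built, junctions stay connected,
and the strand remains topologically unknotted.

## Design methods

| method   | routing model | output |
|----------|---------------|--------|
| `at_dna` | **A-trail**: an Eulerian circuit over the (reconditioned) wireframe whose turns at every junction are rotation-adjacent ("sharp left or sharp right"); found by branch-and-bound over the two sharp-turn transition configurations per vertex. Unknotted on topological spheres. | scaffold + staples |
| `st_dna` | scaffold routed **twice around a maximally branching spanning tree** (Prim); every edge a two-helix bundle, helix lengths rounded to whole turns. Linear time, any connected wireframe. | scaffold + staples |
| `cc_dna` | **antiparallel double cycle cover**: directed cycles covering each edge once per direction, built from connected junction crossovers; scaffold-free. Sequences by **Focused Metropolis Search** minimising the longest repeated substring. | short cyclic/linear strands |
| `st_rna` | single RNA strand twice around a spanning tree; each co-tree edge bulged out as two hairpins forming a **180° kissing-loop** pair; nick at the longest edge; NUPACK design export. | one RNA strand |
| `xt_rna` | like `st_rna` but routed around a **Xuong tree** — the spanning tree minimising the number of odd co-tree components — so that at most one kissing loop remains on fully triangulated (upper-embeddable) meshes. | one RNA strand |

Downstream of the routing, all methods share the same machinery: a cylinder
per duplex (4×4 transform, diameter 2.0 nm for DNA / 2.3 nm for RNA, length
= mesh edge length × the user's nm-per-unit scale, shortened by junction
clearance), optional damped-spring relaxation of inter-cylinder strain,
template-helix nucleotide generation with slerp-placed linkers, kissing-loop
rerouting, and nicking of the long cyclic strands into staples under a
minimum binding-domain (overlap) constraint.

## Worked example

```r
library(wirefold)
d <- run_design(make_mesh("tetrahedron"), "st_dna", scale = 18, seed = 7)
summary(d)
#> wf_design [st_dna] at 18 nm/unit: 4 vertices, 6 edges
#> wf_cylinder_model [st_dna]: 12 cylinders (0 kissing-loop), 24 links, 876 bp total, diameter 2.0 nm
#> wf_nucleotide_model: 1860 nucleotides (1752 paired, 108 linker, 0 kissing-loop), 13 strand(s)
#>   staple: 12 strand(s), lengths 77-78
#>   scaffold: 1 strand(s), lengths 928-928 (circular)
#> validators: all pass
#>   edge coverage: 2
#>   kissing-loop pairs: 0
#>   staple lengths:
#> 77 78
#>  4  8
```

Reading: the 6 tetrahedron edges (unit circumradius, so edge length 1.63
mesh units ≈ 29 nm at scale 18) each became a two-helix bundle of 12
cylinders carrying 876 bp in total; the scaffold is a single 928-nt circular
strand (helix passes plus linker bases) traversing every edge twice, pinned
by 12 staples of 77–78 nt whose binding domains all respect the default
8-nt minimum overlap. `run_design(..., outdir = "out")` writes the oxDNA
`.top`/`.dat` pair, a UNF JSON, the strand CSV, the route edge list and the
validator report. A command-line front end with `design`, `route`,
`fixtures` and `validate` subcommands is installed at
`system.file("cli", "wirefold.R", package = "wirefold")`.

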