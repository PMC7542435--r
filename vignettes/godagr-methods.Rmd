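---
title: "Methods: hierarchy levels, reduced DAGs and term prioritization"
author: "godagr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchy levels, reduced DAGs and term prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(godagr)
```

## The problem

The Gene Ontology organises tens of thousands of terms per namespace
(biological process, molecular function, cellular component) as a directed
acyclic graph with a unique root. Most downstream tools treat a list of
GO-terms as a flat set, ignoring where each term sits in that graph. godagr
makes the vertical structure explicit: how deep a term is, whether its
children skip levels, how the whole DAG looks when collapsed to a handful of
summary nodes, and which members of a term list are redundant because they
lie on another member's path to the root.

All machinery operates on an `OntologyDAG`: a validated single-namespace
graph with parent-to-child edges, built by `buildDAG()` from `parseOBO()`
records (or from plain id/parents records, as in the examples below).

## Hierarchy levels: the largest-value rule

A child of a term need not sit immediately below it; an edge may "jump"
several levels down. Scanning children lists naively therefore assigns some
terms several provisional levels — one per distinct root-to-term path
length. The convention adopted here (and by the ecosystem this package
interoperates with) is that the *correct* level is the largest of these
values, i.e. the length of the longest directed path from the root:

```{r}
g <- toyDAG()            # 9 terms, 9 edges, one jump edge x2 -> x8
levelSets(g)[["x8"]]     # provisional levels: direct edge vs. long route
termLevels(assignLevels(g))
```

`assignLevels()` computes longest paths by dynamic programming over a
topological order, O(V+E), rather than by re-scanning children lists; the
test suite asserts on hundreds of random DAGs that this equals both the
exhaustive path enumeration and `max()` over the `levelSets()` procedure.
Levels strictly increase along every edge, so the per-level term sets
partition the DAG.

Organism-specific graphs arise by restricting to the terms annotated to an
organism's gene products (`parseGAF()`) plus all their ancestors
(`organismSubDAG()`). Levels inside such a sub-DAG are recomputed by
default: removing nodes can only shorten longest paths, so inherited
full-DAG levels would violate the level invariants. Callers who want the
global levels can simply evaluate the full `LevelMap` on the sub-DAG's
nodes.

## Node categories and the reduced DAG

Every non-root term falls into exactly one of three categories, per level:

* **LN** (leaf node): no children;
* **RN** (regular node): has children, all on the next level;
* **JN** (jump node): has children, at least one not on the next level.

The root is excluded — it has no level above it for the rules to compare
against. Mapping every term to its (category, level) pair collapses a DAG of
thousands of terms to at most three summary nodes per level, each carrying
the count of terms it absorbs; a summary edge appears wherever at least one
original edge connects two pairs' members. That summary is small enough to
draw:

```{r}
lv <- assignLevels(g)
reduceDAG(g, lv)
```

Two design points were genuinely open:

* **Root display.** The root has no category, but dropping it disconnects
  the picture. `reduceDAG()` therefore shows it as a distinguished
  pseudo-node at level 0 (toggle with `includeRoot = FALSE`), with edges to
  the categories of the root's children. `reduceSubDAG()`, which restricts
  the summary to a user's term list, defaults the pseudo-node off — a list
  summary need not be anchored at the root.
* **Edge multiplicity.** Parallel original edges collapse onto one summary
  edge (the adjacency is boolean); the number of collapsed edges is kept in
  the `n` column as metadata. Self-loops cannot occur because levels
  strictly increase along edges; this is asserted, not filtered.

## Ranking a term list by vertical position

Deeper terms are more specific. Two complementary rankings exploit this.
With `level(t)` the term's level, `level_max(t)` the deepest level reachable
along paths through `t` (`maxDepthThrough()`), and `depth` the DAG's maximal
level:

* `distRanking()` orders by `level_max(t) - level(t)` ascending: terms
  closest to the end of their own deepest path first. Terms on shallow
  branches can rank highly even if their absolute level is modest.
* `scoreRanking()` orders by the score
  `s_t = (level/level_max) * (level/depth)` descending. Both factors lie in
  (0, 1], hence `s_t` does too, and `s_t = 1` exactly for leaves on the
  DAG's deepest level. The second factor penalises shallow branches, so the
  two orderings agree often but not always; the test suite constructs a
  two-branch DAG (depths 3 and 6) where they flip.

The root is excluded (level 0 would zero the score). Ties — the rankings
must be deterministic to be testable — break by level descending, then term
id ascending. Unknown ids in a list are dropped with a warning rather than
an error, to tolerate ontology release drift; the same policy applies
throughout the package.

```{r}
scoreRanking(g, lv, c("x2", "x6", "x8"))
```

## Prioritizing a term list

Comparing terms across branches is hard; along one path it is trivial — the
deeper term wins. `prioritizedTerms()` applies that logic iteratively:
retain the deepest remaining listed term, enumerate **all shortest paths**
(by edge count) from it to the root, eliminate every other listed term lying
on any of them, repeat. Non-empty input therefore always retains at least
one term, every eliminated term sits strictly below its eliminator, and the
loop terminates because each round removes the retained term itself.

```{r}
ch <- chainDAG(as.character(1:18))
prioritizedTerms(ch, assignLevels(ch), c("5", "9", "17"))
```

Two decisions deserve a note:

* Elimination follows *shortest* paths only. A listed ancestor that reaches
  the retained term exclusively through longer routes survives — this is a
  property of the stated algorithm, preserved rather than "fixed"
  (`test-prioritize.R` pins it with the x4/x8 example, where the shortest
  route to x8 bypasses its ancestor x4).
* Ties among equally deep terms resolve by input-list order, making the
  output a pure function of the input.

Shortest-path enumeration itself is delegated to igraph
(`all_shortest_paths`); an independent DFS enumeration in the test helpers
cross-checks it.

## The synthetic-DAG generator

`randomDAG(n_nodes, n_levels, jump_probability, branching, seed)` emulates
the structural features the algorithms care about, not real GO's degree
distribution. Nodes are spread over the levels with every level non-empty;
each node gets one guaranteed parent on the level above (pinning its
longest-path level by construction), extra next-level parents at a
Poisson(`branching`) rate, and, with probability `jump_probability`, one
extra parent at least two levels up — a jump edge. Defaults
(`jump_probability = 0.2`, `branching = 0.5`) give sparse DAGs with a
realistic mix of all three node categories; `jump_probability = 0`
guarantees a jump-free DAG (no JN anywhere), which the categorisation tests
rely on. All generation is seeded; there is no unseeded entry point, and the
caller's RNG state is restored.

What a green property test does establish: on hundreds of these graphs the
dynamic-programming levels equal exhaustive path enumeration, the reduced
edges equal a brute-force scan, scores stay in (0, 1], and prioritization
partitions its input. What it does not establish: behaviour on real GO
releases (tens of thousands of nodes, deep multi-parent tangles), which
differ in scale but not in the invariants exercised.

## Numerical and degenerate-input choices

* Cycles, multiple roots and dangling parent references are structural
  errors at `buildDAG()` time, each naming the offending nodes.
* A single-node graph is legal everywhere: depth 0, one zero-length
  shortest path, empty categorisation.
* `parseOBO()` keeps the five acyclic, transitive relations (`is_a`,
  `part_of`, `regulates`, `negatively_regulates`, `positively_regulates`),
  silently ignores others (notably `has_part`), resolves `alt_id` aliases
  at parse time, always drops obsolete terms and does not follow
  `replaced_by`. Relation types are kept distinct during parsing but
  unweighted in the graph.
* All scores are exact ratios of small integers; no tolerances are needed
  anywhere in the package.

## Limitations

* No OWL input, no network downloads, no enrichment statistics, no semantic
  similarity — the package is deliberately purely structural and is meant to
  complement, not replace, enrichment pipelines.
* Reduced-DAG output is DOT/GraphML export; no interactive plotting.
* `parseGAF()` maps gene products to terms; mapping gene identifiers to gene
  products (Entrez and friends) is out of scope.
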