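# godagr

Graph-based exploration of Gene Ontology DAGs in R.

Lists of GO-terms — from enrichment analyses, GWAS hits, biomarker panels —
are usually interpreted as flat sets, even though the ontology organises its
terms as a directed acyclic graph whose vertical structure carries meaning:
the deeper a term, the more specific its biology. godagr is for analysts who
want that structure made explicit. It provides:

* **Hierarchy levels** by the longest-path rule. The level of a term is the
  length of the longest directed path from the namespace root; when the
  child-scanning procedure assigns a term several provisional levels (a
  child can "jump" over levels), the largest value is the correct one.
* **Node categories**: every non-root term is a leaf node (LN, no
  children), regular node (RN, all children exactly one level down) or jump
  node (JN, some child skips a level).
* **Reduced DAGs**: collapsing terms onto their (category, level) pairs
  summarises a DAG of thousands of terms into at most three nodes per
  level — small enough to draw (DOT / GraphML export included).
* **Structure-based ranking** of a term list, either by the distance
  `level_max − level` to the deepest path through each term, or by the
  score `s_t = (level/level_max) × (level/depth) ∈ (0, 1]`.
* **Prioritization**: iteratively retain the deepest listed term and
  eliminate listed terms lying on any of its shortest paths to the root,
  yielding a non-redundant subset — parameter- and assumption-free.

Input formats: OBO 1.2 ontologies (`parseOBO`, restricted to the five
acyclic, transitive relations), GAF 2.x annotation files (`parseGAF`) for
organism-specific sub-DAGs, and plain-text term lists. A seeded synthetic
DAG generator (`randomDAG`, `chainDAG`, `toyDAG`) supports testing without
downloading an ontology.

## Worked example

The nine-term example DAG has one jump edge, x2 → x8, so x8 is reachable in
two steps but also in four; the longest path wins:

```r
library(godagr)
g  <- toyDAG()
lv <- assignLevels(g)
termLevels(lv)
#> x1 x2 x3 x4 x5 x6 x7 x8 x9
#>  0  1  1  2  2  3  3  4  4

scoreRanking(g, lv, c("x2", "x6", "x8"))
#>   rank term level max_level dag_depth distance  score
#> 1    1   x8     4         4         4        0 1.0000
#> 2    2   x6     3         4         4        1 0.5625
#> 3    3   x2     1         4         4        3 0.0625
```

x8 is a leaf on the deepest level, so both ratios in its score are 1; x2
sits at level 1 although paths through it reach level 4, hence the weak
score (1/4)·(1/4). Collapsing the whole graph onto categories:

```r
reduceDAG(g, lv)
#> ReducedDAG: 8 summary nodes, 8 edges (root pseudo-node shown)
#>      id category level count
#>  root_0     root     0     1
#>    JN_1       JN     1     1
#>    RN_1       RN     1     1
#>    LN_2       LN     2     1
#>    RN_2       RN     2     1
#>    LN_3       LN     3     1
#>    RN_3       RN     3     1
#>    LN_4       LN     4     2
```

x2 is the jump node (its child x8 skips from level 1 to 4); the two leaves
on level 4 share one summary node with count 2. Prioritizing a list whose
members lie on one chain keeps only the deepest:

```r
ch <- chainDAG(as.character(1:18))
prioritizedTerms(ch, assignLevels(ch), c("5", "9", "17"))
#> PriorityResult: 1 of 3 terms retained
#>   17 (eliminated: 5, 9)
```

## Command line

A thin wrapper over the same functions is installed as `exec/godagr`:

```sh
godagr levels     --obo go-basic.obo --namespace BP --terms list.txt
godagr reduce     --obo go-basic.obo --namespace BP --out reduced.dot
godagr rank       --obo go-basic.obo --namespace BP --terms list.txt --mode score
godagr prioritize --obo go-basic.obo --namespace BP --terms list.txt
godagr synth      --nodes 50 --levels 8 --jump 0.3 --seed 1 --out synth.obo
```

Data goes to `--out` (or stdout) as TSV/DOT; diagnostics go to stderr. Exit
codes: 0 success, 1 data/structural error, 2 usage error.

## Acceptance script

`scripts/acceptance.R` rebuilds the package's reference examples from
scratch — the nine-term DAG via an OBO round-trip (levels, provisional level
sets, categorization) and the 18-node chain prioritization — and writes the
measured quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

See the methods vignette (`vignettes/godagr-methods.Rmd`) for the level
rule, the categorisation and reduction construction, the ranking score, the
prioritization algorithm and the design decisions behind each.
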