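#' @import methods
NULL

#' OntologyDAG: a single-namespace ontology graph
#'
#' Directed acyclic graph of ontology terms with edges oriented parent to
#' child. The graph has exactly one root (the unique node with no parents) and
#' every term is reachable from it. Term identifiers are opaque strings.
#'
#' @slot children named list; for every node, the character vector of its
#'   child term ids (possibly empty). The names enumerate the node set.
#' @slot root character(1), the root term id.
#' @slot namespace character(1), e.g. `"biological_process"`.
#' @slot aliases named character; alternative id -> primary id, populated by
#'   [parseOBO()] from `alt_id` lines so user lists may contain aliases.
#' @slot meta list of free-form metadata (e.g. the OBO `data-version` header).
#'
#' @seealso [buildDAG()], [assignLevels()], [toyDAG()]
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  representation(
    children  = "list",
    root      = "character",
    namespace = "character",
    aliases   = "character",
    meta      = "list"
  ),
  prototype(
    aliases = setNames(character(0), character(0)),
    meta    = list()
  )
)

setValidity("OntologyDAG", function(object) {
  ch <- object@children
  nds <- names(ch)
  if (length(nds) == 0L) return("graph has no nodes")
  if (anyDuplicated(nds)) return("duplicated node ids")
  if (!all(vapply(ch, is.character, logical(1)))) {
    return("children slot must hold character vectors")
  }
  kids <- unlist(ch, use.names = FALSE)
  if (length(kids) && !all(kids %in% nds)) {
    bad <- setdiff(kids, nds)
    return(sprintf("dangling child reference(s): %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
  }
  roots <- setdiff(nds, kids)
  if (length(roots) != 1L) {
    return(sprintf("expected exactly one root, found %d: %s", length(roots),
                   paste(utils::head(roots, 5L), collapse = ", ")))
  }
  if (!identical(object@root, roots)) {
    return(sprintf("root slot '%s' does not match the unique in-degree-0 node '%s'",
                   object@root, roots))
  }
  g <- .as_igraph(object)
  if (!igraph::is_dag(g)) return("graph contains a cycle")
  reach <- .reachable_from(ch, object@root)
  if (length(reach) != length(nds)) {
    return(sprintf("node(s) unreachable from root: %s",
                   paste(utils::head(setdiff(nds, reach), 5L), collapse = ", ")))
  }
  TRUE
})

#' LevelMap: hierarchy levels of an OntologyDAG
#'
#' Stores, for every term, its hierarchy level: the length of the longest
#' directed path from the root to the term. The root has level 0, and along
#' every edge the level strictly increases. `depth` is the maximal level.
#'
#' @slot level named integer, term id -> level.
#' @slot depth integer(1), `max(level)`.
#'
#' @seealso [assignLevels()], [termsOnLevel()], [dagDepth()]
#' @exportClass LevelMap
setClass("LevelMap",
  representation(level = "integer", depth = "integer"))

setValidity("LevelMap", function(object) {
  lv <- object@level
  if (is.null(names(lv)) || anyDuplicated(names(lv))) {
    return("levels must be uniquely named by term id")
  }
  if (any(lv < 0L)) return("levels must be non-negative")
  if (!identical(object@depth, max(lv))) return("depth must equal max(level)")
  TRUE
})

#' CategoryAssignment: LN/RN/JN classification of non-root terms
#'
#' The mapping f(term) = (category, level) applied to every non-root term:
#' leaf node (LN) when the term has no children, regular node (RN) when all
#' children sit exactly one level below, jump node (JN) when at least one
#' child skips a level. The root is excluded by definition.
#'
#' @slot category named character, term id -> one of `"LN"`, `"RN"`, `"JN"`.
#' @slot level named integer, term id -> hierarchy level (same terms, same
#'   order as `category`).
#'
#' @seealso [categorize()], [categoryOf()], [reduceDAG()]
#' @exportClass CategoryAssignment
setClass("CategoryAssignment",
  representation(category = "character", level = "integer"))

setValidity("CategoryAssignment", function(object) {
  if (!identical(names(object@category), names(object@level))) {
    return("category and level must be indexed by the same terms")
  }
  if (!all(object@category %in% c("LN", "RN", "JN"))) {
    return("categories must be LN, RN or JN")
  }
  TRUE
})

#' ReducedDAG: category-level summary of an OntologyDAG
#'
#' Summary graph whose nodes are (category, level) pairs carrying the count of
#' original terms they absorb. At most three category nodes exist per level.
#' Edges connect two summary nodes whenever at least one original edge runs
#' between their member terms; edge multiplicity is kept as metadata. The
#' original root, excluded from categorisation, may be shown as a
#' distinguished pseudo-node at level 0 so the summary stays connected.
#'
#' @slot nodes data.frame with columns `id` (e.g. `"JN_1"`), `category`,
#'   `level`, `count`.
#' @slot edges data.frame with columns `from`, `to` (node ids) and `n`
#'   (number of original edges collapsed onto the summary edge).
#' @slot hasRoot logical(1); whether the level-0 root pseudo-node is present.
#'
#' @seealso [reduceDAG()], [reduceSubDAG()], [writeDOT()]
#' @exportClass ReducedDAG
setClass("ReducedDAG",
  representation(nodes = "data.frame", edges = "data.frame",
                 hasRoot = "logical"))

setValidity("ReducedDAG", function(object) {
  nd <- object@nodes
  need <- c("id", "category", "level", "count")
  if (!all(need %in% names(nd))) {
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(nd$id)) return("duplicated summary node ids")
  cat_nd <- nd[nd$category != "root", , drop = FALSE]
  per <- table(cat_nd$level)
  if (any(per > 3L)) return("more than three category nodes on one level")
  ed <- object@edges
  if (!all(c("from", "to") %in% names(ed))) {
    return("edges must have columns from, to")
  }
  if (nrow(ed) && (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))) {
    return("edge endpoint not among summary nodes")
  }
  if (nrow(ed) && any(ed$from == ed$to)) return("self-loop in reduced graph")
  TRUE
})

#' PriorityResult: outcome of the term-prioritization algorithm
#'
#' Ordered set R of retained terms plus, for each retained term, the input
#' terms it eliminated because they lie on one of its shortest paths to the
#' root.
#'
#' @slot retained character, retained term ids in the order selected.
#' @slot eliminatedBy named list; retained term -> character vector of the
#'   input terms it eliminated (possibly empty).
#' @slot inputSize integer(1), list size after unknown-id filtering.
#' @slot outputSize integer(1), `length(retained)`.
#'
#' @seealso [prioritizedTerms()]
#' @exportClass PriorityResult
setClass("PriorityResult",
  representation(retained = "character", eliminatedBy = "list",
                 inputSize = "integer", outputSize = "integer"))

setValidity("PriorityResult", function(object) {
  if (!identical(names(object@eliminatedBy), object@retained)) {
    return("eliminatedBy must be named by the retained terms, in order")
  }
  if (object@outputSize != length(object@retained)) {
    return("outputSize must equal length(retained)")
  }
  elim <- unlist(object@eliminatedBy, use.names = FALSE)
  if (length(intersect(elim, object@retained))) {
    return("a term cannot be both retained and eliminated")
  }
  if (object@inputSize != length(object@retained) + length(elim)) {
    return("retained plus eliminated must partition the input")
  }
  TRUE
})
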