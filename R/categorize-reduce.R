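#' Categorise every non-root term as leaf, regular or jump node
#'
#' Each non-root term is assigned exactly one of three categories, per level:
#' leaf node (LN) if it has no children; regular node (RN) if it has children
#' and all of them sit on the next level; jump node (JN) if it has children
#' and at least one of them is not on the next level. The root is excluded.
#'
#' @param dag an [OntologyDAG-class].
#' @param levels the matching [LevelMap-class].
#' @return a [CategoryAssignment-class].
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' categoryOf(g, lv, "x2")  # jump node: its child x8 skips from level 1 to 4
#' @export
categorize <- function(dag, levels) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  terms <- setdiff(names(dag@children), dag@root)
  lv <- levels@level
  cat <- vapply(terms, function(t) {
    kids <- dag@children[[t]]
    if (!length(kids)) return("LN")
    if (all(lv[kids] == lv[[t]] + 1L)) "RN" else "JN"
  }, character(1))
  new("CategoryAssignment", category = cat, level = lv[terms])
}

#' Category and level of a single term
#'
#' @inheritParams categorize
#' @param term a single non-root term id.
#' @return named list with elements `category` and `level`.
#' @export
categoryOf <- function(dag, levels, term) {
  .check_term(dag, term)
  if (identical(term, dag@root)) {
    stop("the root is excluded from categorization")
  }
  ca <- categorize(dag, levels)
  list(category = unname(ca@category[[term]]),
       level = unname(ca@level[[term]]))
}

# shared assembly of a ReducedDAG from a member set
.reduce <- function(dag, levels, cats, members, includeRoot) {
  lv <- cats@level
  cat <- cats@category
  node_id <- function(c, l) paste(c, l, sep = "_")
  member_node <- setNames(node_id(cat[members], lv[members]), members)

  uq <- !duplicated(member_node)
  nodes <- data.frame(
    id = unname(member_node[uq]),
    category = unname(cat[members[uq]]),
    level = unname(lv[members[uq]]),
    stringsAsFactors = FALSE
  )
  nodes$count <- as.integer(table(member_node)[nodes$id])

  ed <- .edge_list(dag@children)
  inner <- ed[ed$from %in% members & ed$to %in% members, , drop = FALSE]
  red_edges <- data.frame(from = unname(member_node[inner$from]),
                          to = unname(member_node[inner$to]),
                          stringsAsFactors = FALSE)
  if (includeRoot) {
    root_kids <- intersect(dag@children[[dag@root]], members)
    nodes <- rbind(
      data.frame(id = "root_0", category = "root", level = 0L, count = 1L,
                 stringsAsFactors = FALSE),
      nodes)
    if (length(root_kids)) {
      red_edges <- rbind(
        data.frame(from = "root_0", to = unname(member_node[root_kids]),
                   stringsAsFactors = FALSE),
        red_edges)
    }
  }
  if (nrow(red_edges)) {
    key <- paste(red_edges$from, red_edges$to, sep = "\r")
    mult <- table(key)
    uq <- !duplicated(key)
    red_edges <- red_edges[uq, , drop = FALSE]
    red_edges$n <- as.integer(mult[paste(red_edges$from, red_edges$to,
                                         sep = "\r")])
    stopifnot(all(red_edges$from != red_edges$to))  # levels strictly increase
  } else {
    red_edges <- data.frame(from = character(0), to = character(0),
                            n = integer(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$level, nodes$category), , drop = FALSE]
  rownames(nodes) <- rownames(red_edges) <- NULL
  new("ReducedDAG", nodes = nodes, edges = red_edges, hasRoot = includeRoot)
}

#' Collapse a GO-DAG into its reduced category DAG
#'
#' Builds the summary graph whose nodes are (category, level) pairs: each
#' non-root term is absorbed by its pair, so a level carries at most three
#' summary nodes (one per category actually present) and the counts over all
#' category nodes sum to the number of non-root terms. A summary edge joins
#' two pairs whenever at least one original edge runs between their members;
#' parallel original edges collapse onto one summary edge whose multiplicity
#' is kept in the `n` column. A graph of thousands of terms typically reduces
#' to a few dozen summary nodes, which makes it drawable.
#'
#' The root term has no category. By default it is shown as a distinguished
#' pseudo-node at level 0 with edges to the categories of its children, which
#' keeps the summary connected; disable with `includeRoot = FALSE`.
#'
#' @inheritParams categorize
#' @param cats the [CategoryAssignment-class] computed from `dag` and
#'   `levels`; computed on the fly when omitted.
#' @param includeRoot logical; show the root pseudo-node (default `TRUE`).
#' @return a [ReducedDAG-class].
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' reduceDAG(g, lv)
#' @export
reduceDAG <- function(dag, levels, cats = categorize(dag, levels),
                      includeRoot = TRUE) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"),
            is(cats, "CategoryAssignment"))
  .reduce(dag, levels, cats, members = names(cats@category),
          includeRoot = includeRoot)
}

#' Reduced DAG restricted to a set of terms
#'
#' Same construction as [reduceDAG()] but with the categorisation restricted
#' to the given terms: counts only cover the restriction and summary edges
#' require an original edge between two restricted members. Useful for
#' summarising a list of significant terms rather than the whole ontology.
#' Category and level still come from the full DAG, so a term keeps its
#' global classification.
#'
#' @inheritParams reduceDAG
#' @param terms character vector of term ids (root ignored; unknown ids
#'   skipped with a warning).
#' @param includeRoot logical; default `FALSE` for restrictions.
#' @return a [ReducedDAG-class].
#' @export
reduceSubDAG <- function(dag, levels, cats = categorize(dag, levels), terms,
                         includeRoot = FALSE) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"),
            is(cats, "CategoryAssignment"))
  if (missing(terms) || !length(terms)) stop("empty term restriction")
  members <- setdiff(.resolve_ids(dag, as.character(terms)), dag@root)
  if (!length(members)) stop("no restricted term is present in the DAG")
  .reduce(dag, levels, cats, members = members, includeRoot = includeRoot)
}
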