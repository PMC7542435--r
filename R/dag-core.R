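#' Build a validated ontology DAG from term records
#'
#' Assembles an [OntologyDAG-class] from a list of term records, each carrying
#' an id and its parent ids. Edges are oriented parent to child. The result is
#' validated: it must be acyclic, have exactly one root (the unique node
#' without parents) and every node must be reachable from that root.
#'
#' @param terms either the output of [parseOBO()] or a list of records, each a
#'   `list(id = , parents = )` where `parents` is a character vector of parent
#'   ids (or a data.frame with a `parent` column, as produced by [parseOBO()]).
#' @param namespace namespace label stored on the graph; taken from the
#'   records when they carry one.
#' @return an [OntologyDAG-class].
#' @examples
#' g <- buildDAG(list(list(id = "r", parents = character(0)),
#'                    list(id = "a", parents = "r"),
#'                    list(id = "b", parents = c("r", "a"))))
#' dagRoot(g)
#' @export
buildDAG <- function(terms, namespace = NA_character_) {
  if (!length(terms)) stop("empty term list")
  ids <- vapply(terms, function(t) as.character(t$id), character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated term id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  children <- rep(list(character(0)), length(ids))
  names(children) <- ids
  for (t in terms) {
    p <- t$parents
    if (is.data.frame(p)) p <- p$parent
    p <- unique(as.character(p))
    if (!length(p)) next
    missing <- setdiff(p, ids)
    if (length(missing)) {
      stop(sprintf("term '%s' references unknown parent(s): %s",
                   t$id, paste(missing, collapse = ", ")))
    }
    for (u in p) children[[u]] <- c(children[[u]], t$id)
  }
  children <- lapply(children, unique)
  # diagnose structural failures before the validity method fires, so the
  # error names the offending nodes rather than a slot
  kids <- unlist(children, use.names = FALSE)
  roots <- setdiff(ids, kids)
  if (length(roots) == 0L) {
    cyc <- .find_cycle(children)
    stop(sprintf("no root: every node has a parent (cycle through %s)",
                 paste(cyc, collapse = " -> ")))
  }
  if (length(roots) > 1L) {
    stop(sprintf("multiple root candidates: %s", paste(roots, collapse = ", ")))
  }
  cyc <- .find_cycle(children)
  if (!is.null(cyc)) {
    stop(sprintf("cycle detected: %s", paste(cyc, collapse = " -> ")))
  }
  ns <- namespace
  if (is.na(ns)) {
    rec_ns <- unique(unlist(lapply(terms, function(t) t$namespace)))
    ns <- if (length(rec_ns) == 1L) rec_ns else NA_character_
  }
  meta <- list()
  dv <- attr(terms, "data_version")
  if (!is.null(dv) && !is.na(dv)) meta$data_version <- dv
  al <- attr(terms, "aliases")
  if (is.null(al)) al <- setNames(character(0), character(0))
  al <- al[unname(al) %in% ids]
  new("OntologyDAG", children = children, root = roots,
      namespace = as.character(ns), aliases = al, meta = meta)
}

# One directed cycle as a node sequence, or NULL. DFS with colour marks.
.find_cycle <- function(children) {
  colour <- structure(integer(length(children)), names = names(children))
  stack <- character(0)
  found <- NULL
  visit <- function(u) {
    if (!is.null(found)) return()
    colour[[u]] <<- 1L
    stack <<- c(stack, u)
    for (v in children[[u]]) {
      if (colour[[v]] == 1L) {
        i <- match(v, stack)
        found <<- c(stack[i:length(stack)], v)
        return()
      }
      if (colour[[v]] == 0L) visit(v)
    }
    colour[[u]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (u in names(children)) if (colour[[u]] == 0L) visit(u)
  found
}

#' Assign hierarchy levels (longest path from the root)
#'
#' A term's hierarchy level is the length of the longest directed path from
#' the root to the term. When the child-scanning procedure assigns several
#' provisional levels to a term (a child reachable along paths of different
#' lengths), the correct level is the largest of them; this function computes
#' that directly by dynamic programming over a topological order.
#'
#' @param dag an [OntologyDAG-class].
#' @return a [LevelMap-class]; `termLevels()` gives the per-term levels and
#'   `dagDepth()` the maximal level.
#' @examples
#' lv <- assignLevels(toyDAG())
#' termLevels(lv)[["x8"]]  # 4: the long route wins over the direct edge
#' @seealso [levelSets()] for the full sets of provisional levels.
#' @export
assignLevels <- function(dag) {
  stopifnot(is(dag, "OntologyDAG"))
  children <- dag@children
  lv <- structure(rep(0L, length(children)), names = names(children))
  for (u in .topo_order(children)) {
    for (v in children[[u]]) {
      lv[[v]] <- max(lv[[v]], lv[[u]] + 1L)
    }
  }
  new("LevelMap", level = lv, depth = max(lv))
}

#' Provisional level sets from the iterative child-scanning procedure
#'
#' Replays the naive level-assignment procedure: the root gets level 0 and
#' every scan of a child list hands each child its parent's level plus one,
#' values accumulating as a set. A term reachable along paths of different
#' lengths therefore collects several values — the set of distinct
#' root-to-term path lengths. `max()` over each set reproduces
#' [assignLevels()].
#'
#' @param dag an [OntologyDAG-class].
#' @return named list, term id -> sorted integer vector of provisional levels.
#' @examples
#' levelSets(toyDAG())[["x8"]]  # 2 and 4: direct edge vs. the long route
#' @export
levelSets <- function(dag) {
  stopifnot(is(dag, "OntologyDAG"))
  children <- dag@children
  sets <- rep(list(integer(0)), length(children))
  names(sets) <- names(children)
  rec <- function(u, len) {
    sets[[u]] <<- union(sets[[u]], len)
    for (v in children[[u]]) rec(v, len + 1L)
  }
  rec(dag@root, 0L)
  lapply(sets, function(s) sort(as.integer(s)))
}

#' Terms located on a hierarchy level
#'
#' @param dag an [OntologyDAG-class].
#' @param levels the matching [LevelMap-class].
#' @param l level of interest, between 0 and `dagDepth(levels)`.
#' @return character vector of the term ids with level `l`.
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' termsOnLevel(g, lv, 1)
#' @export
termsOnLevel <- function(dag, levels, l) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 0L || l > levels@depth) {
    stop(sprintf("level must lie in [0, %d]", levels@depth))
  }
  names(levels@level)[levels@level == l]
}

#' Children of a term together with their hierarchy levels
#'
#' Children need not sit on the next level: an edge may jump several levels
#' down, which is exactly what the returned levels expose.
#'
#' @inheritParams termsOnLevel
#' @param term a single term id.
#' @return data.frame with columns `child` and `level`; zero rows for leaves.
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' childrenWithLevels(g, lv, "x2")  # its only child x8 sits on level 4
#' @export
childrenWithLevels <- function(dag, levels, term) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  .check_term(dag, term)
  kids <- dag@children[[term]]
  data.frame(child = kids, level = unname(levels@level[kids]),
             stringsAsFactors = FALSE)
}

#' Parents of a term
#'
#' @param dag an [OntologyDAG-class].
#' @param term a single term id.
#' @return character vector of parents; empty only for the root.
#' @examples
#' parentsOf(toyDAG(), "x8")
#' @export
parentsOf <- function(dag, term) {
  .check_term(dag, term)
  names(dag@children)[vapply(dag@children, function(k) term %in% k, logical(1))]
}

#' Descendants and ancestors of a term
#'
#' Transitive closure along child (respectively parent) edges, excluding the
#' term itself.
#'
#' @param dag an [OntologyDAG-class].
#' @param term a single term id.
#' @return character vector of term ids.
#' @examples
#' termDescendants(toyDAG(), "x4")
#' termAncestors(toyDAG(), "x8")
#' @export
termDescendants <- function(dag, term) {
  .check_term(dag, term)
  setdiff(.reachable_from(dag@children, term), term)
}

#' @rdname termDescendants
#' @export
termAncestors <- function(dag, term) {
  .check_term(dag, term)
  parents <- .parent_index(dag@children)
  setdiff(.reachable_from(parents, term), term)
}

#' Induce an organism-specific (or otherwise annotated) sub-DAG
#'
#' Restricts the DAG to a set of annotated terms plus all their ancestors, so
#' the result is ancestor-closed and remains a valid single-root DAG. Typical
#' input is the union of terms annotated to an organism's gene products, e.g.
#' from [parseGAF()]. Levels inside the sub-DAG differ in general from the
#' full-DAG levels (paths may be lost), so they are recomputed by default.
#'
#' @param dag an [OntologyDAG-class].
#' @param annotated character vector of term ids (aliases resolved, unknown
#'   ids skipped with a warning).
#' @return an [OntologyDAG-class] on `annotated` and all their ancestors.
#' @examples
#' sub <- organismSubDAG(toyDAG(), c("x9"))
#' dagNodes(sub)
#' @export
organismSubDAG <- function(dag, annotated) {
  stopifnot(is(dag, "OntologyDAG"))
  if (!length(annotated)) stop("empty annotated term set")
  ids <- .resolve_ids(dag, as.character(annotated))
  if (!length(ids)) stop("no annotated term is present in the DAG")
  keep <- unique(c(ids, unlist(lapply(ids, termAncestors, dag = dag))))
  children <- lapply(dag@children[keep], intersect, keep)
  al <- dag@aliases[unname(dag@aliases) %in% keep]
  new("OntologyDAG", children = children, root = dag@root,
      namespace = dag@namespace, aliases = al, meta = dag@meta)
}

#' Maximal depth of paths passing through a term
#'
#' The deepest hierarchy level reachable along directed paths through the
#' term: the maximum level over the term and all its descendants. For a leaf
#' it equals the term's own level. This is the `level_max` entering the
#' structure-based ranking score.
#'
#' @inheritParams termsOnLevel
#' @param term a single term id.
#' @return integer level.
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' maxDepthThrough(g, lv, "x2")  # 4, via its child x8
#' @export
maxDepthThrough <- function(dag, levels, term) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  .check_term(dag, term)
  max(levels@level[c(term, termDescendants(dag, term))])
}
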