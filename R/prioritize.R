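#' All shortest paths from the root to a term
#'
#' Enumerates every directed path of minimal edge count from the root to the
#' term. Node levels strictly increase along each path. For the root itself a
#' single zero-length path is returned.
#'
#' @param dag an [OntologyDAG-class].
#' @param term a single term id.
#' @return list of character vectors, each a node sequence `root, ..., term`.
#' @examples
#' shortestPathsToRoot(toyDAG(), "x8")  # x1 -> x2 -> x8 beats the long route
#' @export
shortestPathsToRoot <- function(dag, term) {
  stopifnot(is(dag, "OntologyDAG"))
  .check_term(dag, term)
  if (identical(term, dag@root)) return(list(dag@root))
  g <- .as_igraph(dag)
  sp <- igraph::all_shortest_paths(g, from = dag@root, to = term,
                                   mode = "out")
  lapply(sp$vpaths, function(p) igraph::as_ids(p))
}

#' Prioritise a list of terms by iterative shortest-path elimination
#'
#' Comparing terms across branches of an ontology is hard, but along a single
#' path it is easy: the deeper term is the more specific one. This algorithm
#' exploits that vertical logic iteratively. It picks the remaining listed
#' term with the highest level, retains it, computes all its shortest paths
#' to the root, and eliminates every other listed term lying on one of those
#' paths (such terms are ancestors on a lower level, hence redundant). The
#' loop repeats until the list is exhausted, so a non-empty input always
#' yields at least one retained term.
#'
#' Only shortest paths (by edge count) are searched: a listed ancestor that
#' reaches the retained term exclusively through longer routes survives.
#' Ties among equally deep terms resolve by input-list order, which makes the
#' result deterministic.
#'
#' @param dag an [OntologyDAG-class].
#' @param levels the matching [LevelMap-class].
#' @param terms character vector of term ids; unknown ids are dropped with a
#'   warning.
#' @return a [PriorityResult-class].
#' @examples
#' g <- chainDAG(as.character(1:18))
#' lv <- assignLevels(g)
#' retained(prioritizedTerms(g, lv, c("5", "9", "17")))  # "17"
#' @export
prioritizedTerms <- function(dag, levels, terms) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  if (!length(terms)) stop("empty term list")
  remaining <- .resolve_ids(dag, as.character(terms))
  if (!length(remaining)) stop("no listed term is present in the DAG")
  n_in <- length(remaining)

  ret <- character(0)
  elim <- list()
  while (length(remaining)) {
    lv <- levels@level[remaining]
    pick <- remaining[[which.max(lv)]]  # which.max keeps input order on ties
    on_paths <- unique(unlist(shortestPathsToRoot(dag, pick)))
    gone <- setdiff(intersect(remaining, on_paths), pick)
    ret <- c(ret, pick)
    elim[[pick]] <- gone
    remaining <- setdiff(remaining, c(pick, gone))
  }
  new("PriorityResult", retained = ret, eliminatedBy = elim,
      inputSize = n_in, outputSize = length(ret))
}
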