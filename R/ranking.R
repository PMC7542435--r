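#' Structure-based score of a term
#'
#' Quantifies the trade-off between the relative and absolute vertical
#' position of a term in the DAG:
#'
#' \deqn{s_t = \frac{level(t)}{level_{max}(t)} \times \frac{level(t)}{depth}}
#'
#' where `level_max(t)` is the deepest level reachable along paths through
#' `t` (see [maxDepthThrough()]) and `depth` is the DAG's maximal level. Both
#' factors lie in (0, 1], so the score does too; it attains 1 exactly for
#' leaves sitting on the DAG's deepest level. The root (level 0) has no
#' score.
#'
#' @param dag an [OntologyDAG-class].
#' @param levels the matching [LevelMap-class].
#' @param term a single non-root term id.
#' @return numeric score in (0, 1].
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' scoreTerm(g, lv, "x6")  # (3/4) * (3/4)
#' @export
scoreTerm <- function(dag, levels, term) {
  stopifnot(is(dag, "OntologyDAG"), is(levels, "LevelMap"))
  .check_term(dag, term)
  if (identical(term, dag@root)) {
    stop("the root (level 0) has no structure-based score")
  }
  l <- levels@level[[term]]
  lmax <- maxDepthThrough(dag, levels, term)
  (l / lmax) * (l / levels@depth)
}

# shared table construction + tie rules (level descending, then id ascending)
.ranked_table <- function(dag, levels, ids) {
  l <- unname(levels@level[ids])
  lmax <- vapply(ids, maxDepthThrough, integer(1), dag = dag, levels = levels)
  data.frame(
    term = ids,
    level = l,
    max_level = unname(lmax),
    dag_depth = levels@depth,
    distance = unname(lmax) - l,
    score = (l / unname(lmax)) * (l / levels@depth),
    stringsAsFactors = FALSE
  )
}

.rank_order <- function(tab, primary, decreasing) {
  key <- if (decreasing) -xtfrm(tab[[primary]]) else xtfrm(tab[[primary]])
  tab <- tab[order(key, -tab$level, tab$term), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", "term", "level", "max_level", "dag_depth",
          "distance", "score")]
}

#' Rank a term list by distance to its maximal attainable depth
#'
#' Orders terms by `distance = level_max - level`: how far a term sits from
#' the end of the deepest path passing through it. Small distances mean the
#' term is close to the most specific annotation its branch offers, so the
#' ranking is ascending (most specific first). Ties break by level
#' (descending, deeper term first) and then term id, so output is
#' deterministic.
#'
#' @param dag an [OntologyDAG-class].
#' @param levels the matching [LevelMap-class].
#' @param terms character vector of term ids; the root is rejected, unknown
#'   ids are dropped with a warning.
#' @param decreasing logical; set `TRUE` to invert the ordering.
#' @return data.frame with columns `rank`, `term`, `level`, `max_level`,
#'   `dag_depth`, `distance`, `score`.
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' distRanking(g, lv, c("x2", "x6", "x8"))
#' @export
distRanking <- function(dag, levels, terms, decreasing = FALSE) {
  ids <- .ranking_ids(dag, terms)
  .rank_order(.ranked_table(dag, levels, ids), "distance", decreasing)
}

#' Rank a term list by the structure-based score
#'
#' Orders terms by [scoreTerm()] descending (best trade-off between relative
#' and absolute depth first). The distance and score rankings are similar but
#' not identical: a deep term on a shallow branch can top one and not the
#' other. Same tie rules as [distRanking()].
#'
#' @inheritParams distRanking
#' @return data.frame as in [distRanking()], ordered by `score`.
#' @examples
#' g <- toyDAG(); lv <- assignLevels(g)
#' scoreRanking(g, lv, c("x2", "x6", "x8"))
#' @export
scoreRanking <- function(dag, levels, terms, decreasing = TRUE) {
  ids <- .ranking_ids(dag, terms)
  .rank_order(.ranked_table(dag, levels, ids), "score", decreasing)
}

.ranking_ids <- function(dag, terms) {
  if (!length(terms)) stop("empty term list")
  ids <- .resolve_ids(dag, as.character(terms))
  if (dag@root %in% ids) {
    stop("the root has no rank; remove it from the list")
  }
  if (!length(ids)) stop("no listed term is present in the DAG")
  ids
}
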