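#' The nine-node example DAG
#'
#' The small worked example used throughout the documentation and tests: nine
#' terms `x1..x9`, root `x1`, nine edges, including the jump edge `x2 -> x8`
#' that carries `x8` from a provisional level 2 down to its true level 4.
#'
#' @return an [OntologyDAG-class] with 9 nodes and 9 edges.
#' @examples
#' termLevels(assignLevels(toyDAG()))
#' @export
toyDAG <- function() {
  children <- list(
    x1 = c("x2", "x3"),
    x2 = "x8",
    x3 = c("x4", "x5"),
    x4 = c("x6", "x7"),
    x5 = character(0),
    x6 = c("x8", "x9"),
    x7 = character(0),
    x8 = character(0),
    x9 = character(0)
  )
  new("OntologyDAG", children = children, root = "x1",
      namespace = "biological_process")
}

#' A chain (path) DAG
#'
#' @param labels ordered, distinct term ids; the first becomes the root and
#'   each label is the single child of its predecessor. Levels run
#'   `0..length(labels)-1`.
#' @return an [OntologyDAG-class].
#' @examples
#' dagDepth(assignLevels(chainDAG(letters[1:5])))
#' @export
chainDAG <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("need at least one label")
  if (anyDuplicated(labels)) stop("labels must be distinct")
  n <- length(labels)
  children <- c(as.list(labels[-1L])[seq_len(n - 1L)],
                list(character(0)))
  names(children) <- labels
  if (n == 1L) children <- setNames(list(character(0)), labels)
  new("OntologyDAG", children = children, root = labels[[1L]],
      namespace = "biological_process")
}

#' Generate a seeded random ontology-like DAG
#'
#' Builds a single-root DAG with a prescribed number of levels and controlled
#' jump-edge structure, for testing the level, categorisation, reduction and
#' prioritisation machinery without a real ontology. Nodes are spread over
#' the levels (each level non-empty); every node on level `l` gets at least
#' one parent on level `l-1`, which pins its longest-path level to `l`.
#' Additional within-level-step edges are added according to `branching`, and
#' with probability `jump_probability` a node at level `l >= 2` receives an
#' extra parent from a level `<= l-2`, creating a jump edge. With
#' `jump_probability = 0` every child sits exactly one level below each of
#' its parents, so categorisation yields no jump nodes at all.
#'
#' @param n_nodes total number of nodes (>= 1).
#' @param n_levels number of levels including the root level; must not
#'   exceed `n_nodes`. Default: about half the nodes, at least 2.
#' @param jump_probability probability in `[0, 1]` that a node two or more
#'   levels below the root receives an extra jump parent. Default 0.2.
#' @param branching mean number of extra next-level parents sampled per node
#'   (on top of the guaranteed one). Default 0.5.
#' @param seed integer seed; generation is fully reproducible and the
#'   caller's RNG state is left untouched.
#' @return an [OntologyDAG-class]; always passes validation.
#' @examples
#' g <- randomDAG(12, n_levels = 4, jump_probability = 0.5, seed = 7)
#' dagDepth(assignLevels(g))
#' @export
randomDAG <- function(n_nodes, n_levels = max(2L, ceiling(n_nodes / 2)),
                      jump_probability = 0.2, branching = 0.5, seed) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) stop("n_nodes must be >= 1")
  if (n_nodes == 1L) n_levels <- 1L
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L || n_levels > n_nodes) {
    stop("n_levels must lie in [1, n_nodes]")
  }
  if (jump_probability < 0 || jump_probability > 1) {
    stop("jump_probability must lie in [0, 1]")
  }
  if (missing(seed)) stop("a seed is required")

  ids <- paste0("t", seq_len(n_nodes))
  children <- setNames(rep(list(character(0)), n_nodes), ids)
  if (n_nodes == 1L) {
    return(new("OntologyDAG", children = children, root = ids,
               namespace = "synthetic"))
  }

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # one node per level guaranteed, the rest spread over levels 1..n_levels-1
  level <- integer(n_nodes)
  level[seq_len(n_levels)] <- seq_len(n_levels) - 1L
  extra <- n_nodes - n_levels
  if (extra > 0L) {
    level[(n_levels + 1L):n_nodes] <-
      sample(seq_len(n_levels - 1L), extra, replace = TRUE)
  }
  by_level <- split(ids, level)

  add_edge <- function(parent, child) {
    children[[parent]] <<- union(children[[parent]], child)
  }
  for (l in seq_len(n_levels - 1L)) {
    above <- by_level[[as.character(l - 1L)]]
    for (node in by_level[[as.character(l)]]) {
      picks <- unique(c(
        sample(above, 1L),
        if (length(above) > 1L && branching > 0) {
          k <- min(stats::rpois(1L, branching), length(above) - 1L)
          sample(above, k)
        }))
      for (p in picks) add_edge(p, node)
      if (l >= 2L && stats::runif(1L) < jump_probability) {
        shallow <- ids[level <= l - 2L]
        add_edge(sample(shallow, 1L), node)
      }
    }
  }
  new("OntologyDAG", children = children, root = ids[[1L]],
      namespace = "synthetic")
}
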