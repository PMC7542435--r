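# Independent brute-force oracles. These work off the public accessors only
# and enumerate paths explicitly, so they share no code path with the
# dynamic-programming / igraph implementations they check.

# adjacency as a plain named list via the accessors
adjacency_of <- function(dag) {
  sapply(dagNodes(dag), function(t) dagChildren(dag, t), simplify = FALSE)
}

# all directed root-to-node paths (node sequences) by exhaustive DFS
enumerate_paths <- function(dag) {
  adj <- adjacency_of(dag)
  paths <- list()
  walk <- function(node, prefix) {
    prefix <- c(prefix, node)
    paths[[length(paths) + 1L]] <<- prefix
    for (k in adj[[node]]) walk(k, prefix)
  }
  walk(dagRoot(dag), character(0))
  paths
}

# longest-path level per node from the explicit path enumeration
brute_levels <- function(dag) {
  lv <- setNames(rep(0L, length(dagNodes(dag))), dagNodes(dag))
  for (p in enumerate_paths(dag)) {
    end <- p[[length(p)]]
    lv[[end]] <- max(lv[[end]], length(p) - 1L)
  }
  lv
}

# sets of distinct root-to-node path lengths (provisional level sets)
brute_level_sets <- function(dag) {
  sets <- setNames(rep(list(integer(0)), length(dagNodes(dag))), dagNodes(dag))
  for (p in enumerate_paths(dag)) {
    end <- p[[length(p)]]
    sets[[end]] <- sort(union(sets[[end]], length(p) - 1L))
  }
  sets
}

# minimum-edge-count root-to-term paths from the explicit enumeration
brute_shortest_paths <- function(dag, term) {
  ending <- Filter(function(p) identical(p[[length(p)]], term),
                   enumerate_paths(dag))
  lens <- vapply(ending, length, integer(1))
  ending[lens == min(lens)]
}

# categorisation straight from the definitions, per term
brute_category <- function(dag, term) {
  lv <- brute_levels(dag)
  kids <- dagChildren(dag, term)
  if (!length(kids)) return("LN")
  if (all(lv[kids] == lv[[term]] + 1L)) "RN" else "JN"
}

# reduced-DAG edge set by scanning every original edge through f
brute_reduced_edges <- function(dag, include_root = TRUE) {
  adj <- adjacency_of(dag)
  lv <- brute_levels(dag)
  node_of <- function(t) {
    if (identical(t, dagRoot(dag))) "root_0"
    else paste(brute_category(dag, t), lv[[t]], sep = "_")
  }
  out <- character(0)
  for (u in names(adj)) {
    if (!include_root && identical(u, dagRoot(dag))) next
    for (v in adj[[u]]) out <- c(out, paste(node_of(u), node_of(v)))
  }
  sort(unique(out))
}

# a spread of seeded random DAG shapes used by the property suites
random_case <- function(seed, max_nodes = 12L) {
  n <- 2L + (seed %% (max_nodes - 1L))
  randomDAG(
    n_nodes = n,
    n_levels = max(2L, 1L + (seed %% n)),
    jump_probability = c(0, 0.2, 0.5, 0.9)[1L + seed %% 4L],
    branching = c(0.3, 0.8, 1.5)[1L + seed %% 3L],
    seed = seed)
}

toy_records <- function() {
  ch <- list(x1 = c("x2", "x3"), x2 = "x8", x3 = c("x4", "x5"),
             x4 = c("x6", "x7"), x5 = character(0), x6 = c("x8", "x9"),
             x7 = character(0), x8 = character(0), x9 = character(0))
  parents <- lapply(setNames(names(ch), names(ch)), function(t) {
    names(ch)[vapply(ch, function(k) t %in% k, logical(1))]
  })
  lapply(names(ch), function(t) list(id = t, parents = parents[[t]]))
}
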