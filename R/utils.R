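# Internal helpers shared across modules.

# Edge list (from, to) of a children adjacency, possibly empty.
.edge_list <- function(children) {
  n <- vapply(children, length, integer(1))
  data.frame(
    from = rep(names(children), n),
    to = unlist(children, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# igraph view of an OntologyDAG (or raw children list); vertices keep term ids.
.as_igraph <- function(x) {
  children <- if (is(x, "OntologyDAG")) x@children else x
  ed <- .edge_list(children)
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = names(children)))
}

# Nodes reachable from `start` following child edges, including `start`.
.reachable_from <- function(children, start) {
  seen <- structure(logical(length(children)), names = names(children))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (k in children[[cur]]) {
      if (!seen[[k]]) {
        seen[[k]] <- TRUE
        queue <- c(queue, k)
      }
    }
  }
  names(seen)[seen]
}

# parent adjacency: term -> character vector of parents
.parent_index <- function(children) {
  ed <- .edge_list(children)
  idx <- split(ed$from, factor(ed$to, levels = names(children)))
  lapply(idx, as.character)
}

# Kahn topological order over the children adjacency (root first).
.topo_order <- function(children) {
  indeg <- structure(integer(length(children)), names = names(children))
  for (kids in children) {
    if (length(kids)) indeg[kids] <- indeg[kids] + 1L
  }
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, cur)
    for (k in children[[cur]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(children)) stop("cycle detected in adjacency")
  out
}

.check_term <- function(dag, term) {
  if (length(term) != 1L || !is.character(term)) {
    stop("'term' must be a single term id")
  }
  if (!term %in% names(dag@children)) {
    stop(sprintf("unknown term '%s' (not in the DAG)", term))
  }
  invisible(term)
}

# Map possibly-aliased ids onto primary ids, drop unknowns with one warning.
# Returns ids in input order, duplicates removed after resolution.
.resolve_ids <- function(dag, ids) {
  al <- dag@aliases
  hit <- ids %in% names(al)
  ids[hit] <- unname(al[ids[hit]])
  known <- ids %in% names(dag@children)
  if (any(!known)) {
    warning(sprintf("skipping %d unknown term id(s): %s", sum(!known),
                    paste(utils::head(ids[!known], 5L), collapse = ", ")))
  }
  unique(ids[known])
}
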