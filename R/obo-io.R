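.GO_NAMESPACES <- c("biological_process", "molecular_function",
                    "cellular_component")
.GO_RELATIONS <- c("is_a", "part_of", "regulates",
                   "negatively_regulates", "positively_regulates")
.GAF_ASPECT <- c(biological_process = "P", molecular_function = "F",
                 cellular_component = "C")

# accept the BP/MF/CC shorthands used on the command line
.normalize_namespace <- function(namespace) {
  alias <- c(BP = "biological_process", MF = "molecular_function",
             CC = "cellular_component")
  if (namespace %in% names(alias)) namespace <- alias[[namespace]]
  if (!namespace %in% .GO_NAMESPACES) {
    stop(sprintf("unknown namespace '%s' (use one of %s or BP/MF/CC)",
                 namespace, paste(.GO_NAMESPACES, collapse = ", ")))
  }
  namespace
}

#' Read an OBO 1.2 ontology restricted to one namespace
#'
#' Parses the `[Term]` stanzas of an OBO 1.2 flat file (the `go-basic.obo`
#' layout) into term records. Only non-obsolete terms of the requested
#' namespace are kept, and parent links are restricted to the requested
#' relation types; `is_a:` lines and `relationship:` lines both contribute.
#' Relations outside the five acyclic, transitive go-basic relations (e.g.
#' `has_part`) are silently ignored. `alt_id` entries are recorded as aliases
#' of their primary term so user lists may contain superseded ids.
#'
#' @param file path to an OBO 1.2 file, or a character vector of its lines.
#' @param namespace one of `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"` (or the shorthands `"BP"`, `"MF"`, `"CC"`).
#' @param relations relation types to keep as parent links; non-empty subset
#'   of the five go-basic relations.
#' @return list of term records (`id`, `name`, `namespace`, `obsolete`,
#'   `parents` data.frame with columns `parent`/`relation`, `alt_ids`), with
#'   attributes `aliases` (named character, alt id -> primary id) and
#'   `data_version` (the OBO header, when present). Feed it to [buildDAG()].
#' @examples
#' obo <- writeOBO(toyDAG())
#' length(parseOBO(obo, "biological_process"))
#' @export
parseOBO <- function(file, namespace,
                     relations = .GO_RELATIONS) {
  namespace <- .normalize_namespace(namespace)
  if (!length(relations) || !all(relations %in% .GO_RELATIONS)) {
    stop(sprintf("relations must be a non-empty subset of: %s",
                 paste(.GO_RELATIONS, collapse = ", ")))
  }
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }

  data_version <- NA_character_
  records <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE

  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id)) {
        stop(sprintf("malformed stanza starting at line %d: missing id",
                     cur_line))
      }
      records[[length(records) + 1L]] <<- cur
    }
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])  # trailing comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NA_character_,
                    namespace = NA_character_, obsolete = FALSE,
                    parents = list(), alt_ids = character(0))
        cur_line <- i
      }
      next
    }
    if (!grepl(":", line, fixed = TRUE)) {
      stop(sprintf("malformed OBO line %d: '%s'", i, lines[[i]]))
    }
    key <- sub(":.*$", "", line)
    value <- trimws(sub("^[^:]+:", "", line))
    if (!in_term) {
      if (key == "data-version") data_version <- value
      next
    }
    if (key == "id") {
      if (value == "") stop(sprintf("malformed OBO line %d: empty id", i))
      cur$id <- value
    } else if (key == "name") {
      cur$name <- value
    } else if (key == "namespace") {
      cur$namespace <- value
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(value, "true")
    } else if (key == "alt_id") {
      cur$alt_ids <- c(cur$alt_ids, value)
    } else if (key == "is_a") {
      cur$parents[[length(cur$parents) + 1L]] <-
        c(parent = value, relation = "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(value, "[[:space:]]+")[[1L]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed relationship at line %d: '%s'", i, lines[[i]]))
      }
      cur$parents[[length(cur$parents) + 1L]] <-
        c(parent = parts[[2L]], relation = parts[[1L]])
    }
  }
  flush()

  # namespace + obsolete filtering, then relation filtering
  keep <- vapply(records, function(r) {
    !r$obsolete && identical(r$namespace, namespace)
  }, logical(1))
  records <- records[keep]
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated term id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  records <- lapply(records, function(r) {
    pr <- do.call(rbind, r$parents)
    pr <- if (is.null(pr)) {
      data.frame(parent = character(0), relation = character(0),
                 stringsAsFactors = FALSE)
    } else {
      as.data.frame(pr, stringsAsFactors = FALSE)
    }
    # links to out-of-namespace terms and non-requested relations drop here
    pr <- pr[pr$relation %in% relations & pr$parent %in% ids, , drop = FALSE]
    rownames(pr) <- NULL
    r$parents <- pr
    r
  })

  aliases <- unlist(lapply(records, function(r) {
    if (length(r$alt_ids)) setNames(rep(r$id, length(r$alt_ids)), r$alt_ids)
  }))
  if (is.null(aliases)) aliases <- setNames(character(0), character(0))
  structure(records, aliases = aliases, data_version = data_version)
}

#' Read a GAF 2.x annotation file into a gene-to-terms map
#'
#' Parses the tab-separated Gene Association File format: column 2 is the
#' gene-product identifier, column 4 the qualifier, column 5 the term id and
#' column 9 the aspect (P/F/C). Rows are restricted to the aspect matching
#' the requested namespace, and rows whose qualifier contains `NOT` are
#' dropped — a negated annotation must not place a gene in the sub-DAG.
#'
#' @param file path to a GAF 2.1/2.2 file, or a character vector of lines.
#' @param namespace namespace (or BP/MF/CC shorthand) selecting the aspect.
#' @return named list, gene-product id -> character vector of term ids (no
#'   empty entries).
#' @export
parseGAF <- function(file, namespace) {
  namespace <- .normalize_namespace(namespace)
  aspect <- .GAF_ASPECT[[namespace]]
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  rows <- which(keep)
  out <- list()
  for (i in rows) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L) {
      stop(sprintf("GAF row %d has %d columns, expected >= 15", i, length(f)))
    }
    if (f[[9L]] != aspect) next
    if (grepl("(^|\\|)NOT($|\\|)", f[[4L]])) next
    gene <- f[[2L]]
    out[[gene]] <- unique(c(out[[gene]], f[[5L]]))
  }
  out
}

#' Read a plain-text term list
#'
#' One term id per line; blank lines and `#` comments are ignored.
#'
#' @param file path to the list file.
#' @return character vector of term ids.
#' @export
readTermList <- function(file) {
  lines <- trimws(sub("#.*$", "", readLines(file, warn = FALSE)))
  lines[nzchar(lines)]
}

#' Write a minimal OBO 1.2 representation of a DAG
#'
#' Emits one `[Term]` stanza per node with `is_a` links for every edge, such
#' that [parseOBO()] followed by [buildDAG()] round-trips to the same graph.
#' Intended for fixtures and for exporting synthetic DAGs.
#'
#' @param dag an [OntologyDAG-class].
#' @param file optional output path.
#' @return character vector of OBO lines; invisibly when `file` is given.
#' @export
writeOBO <- function(dag, file = NULL) {
  stopifnot(is(dag, "OntologyDAG"))
  # synthetic / unset namespaces serialise as BP so the file stays parseable
  ns <- if (is.na(dag@namespace) || !dag@namespace %in% .GO_NAMESPACES) {
    "biological_process"
  } else {
    dag@namespace
  }
  parents <- .parent_index(dag@children)
  out <- c("format-version: 1.2",
           sprintf("data-version: godagr/%s", utils::packageVersion("godagr")),
           "")
  for (t in names(dag@children)) {
    out <- c(out, "[Term]",
             sprintf("id: %s", t),
             sprintf("name: %s", t),
             sprintf("namespace: %s", ns),
             sprintf("is_a: %s", parents[[t]]),
             "")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.dot_quote <- function(x) sprintf('"%s"', gsub('"', '\\\\"', x))

.dot_lines <- function(node_ids, node_labels, edges, level_of) {
  out <- c("digraph ontology {",
           "  rankdir=TB;",
           "  node [shape=box, style=rounded];")
  for (i in seq_along(node_ids)) {
    out <- c(out, sprintf("  %s [label=%s];",
                          .dot_quote(node_ids[[i]]),
                          .dot_quote(node_labels[[i]])))
  }
  for (l in sort(unique(level_of))) {
    members <- node_ids[level_of == l]
    out <- c(out, sprintf("  { rank=same; %s }",
                          paste(.dot_quote(members), collapse = "; ")))
  }
  if (nrow(edges)) {
    out <- c(out, sprintf("  %s -> %s;",
                          vapply(edges$from, .dot_quote, character(1)),
                          vapply(edges$to, .dot_quote, character(1))))
  }
  c(out, "}")
}

#' @describeIn writeDOT full ontology graph; one rank per hierarchy level.
setMethod("writeDOT", "OntologyDAG", function(x, file = NULL, ...) {
  lv <- assignLevels(x)@level
  ids <- names(x@children)
  out <- .dot_lines(ids, ids, .edge_list(x@children), unname(lv[ids]))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
})

#' @describeIn writeDOT reduced DAG; nodes carry category, level and member
#'   count.
setMethod("writeDOT", "ReducedDAG", function(x, file = NULL, ...) {
  nd <- x@nodes
  if (!nrow(nd)) stop("empty graph")
  labels <- ifelse(nd$category == "root", "root",
                   sprintf("%s\\nlevel %d\\nn=%d",
                           nd$category, nd$level, nd$count))
  out <- .dot_lines(nd$id, labels, x@edges, nd$level)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
})

#' @describeIn writeGraphML term graph with `level` vertex attribute.
setMethod("writeGraphML", "OntologyDAG", function(x, file) {
  g <- .as_igraph(x)
  lv <- assignLevels(x)@level
  igraph::V(g)$level <- unname(lv[igraph::V(g)$name])
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
})

#' @describeIn writeGraphML summary graph with category/level/count vertex
#'   attributes.
setMethod("writeGraphML", "ReducedDAG", function(x, file) {
  g <- igraph::graph_from_data_frame(
    x@edges[, c("from", "to"), drop = FALSE], directed = TRUE,
    vertices = x@nodes[, c("id", "category", "level", "count"), drop = FALSE])
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
})
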