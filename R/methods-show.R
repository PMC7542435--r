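#' Accessors for OntologyDAG objects
#'
#' @param x an [OntologyDAG-class].
#' @param term a single term id.
#' @return `dagNodes`: character vector of all term ids; `dagRoot`,
#'   `dagNamespace`: character(1); `dagChildren`: character vector of the
#'   term's children; `dagAliases`: named character mapping alternative ids to
#'   primary ids.
#' @name OntologyDAG-accessors
#' @examples
#' g <- toyDAG()
#' dagRoot(g)
#' dagChildren(g, "x3")
NULL

#' @rdname OntologyDAG-accessors
setMethod("dagNodes", "OntologyDAG", function(x) names(x@children))

#' @rdname OntologyDAG-accessors
setMethod("dagRoot", "OntologyDAG", function(x) x@root)

#' @rdname OntologyDAG-accessors
setMethod("dagNamespace", "OntologyDAG", function(x) x@namespace)

#' @rdname OntologyDAG-accessors
setMethod("dagChildren", "OntologyDAG", function(x, term) {
  .check_term(x, term)
  x@children[[term]]
})

#' @rdname OntologyDAG-accessors
setMethod("dagAliases", "OntologyDAG", function(x) x@aliases)

setMethod("show", "OntologyDAG", function(object) {
  ne <- length(unlist(object@children, use.names = FALSE))
  cat(sprintf("OntologyDAG: %d terms, %d edges\n",
              length(object@children), ne))
  cat(sprintf("  namespace: %s\n  root: %s\n",
              object@namespace, object@root))
  if (length(object@aliases)) {
    cat(sprintf("  aliases: %d\n", length(object@aliases)))
  }
  if (!is.null(object@meta$data_version)) {
    cat(sprintf("  data-version: %s\n", object@meta$data_version))
  }
})

#' Accessors for LevelMap objects
#'
#' @param x a [LevelMap-class].
#' @return `termLevels`: named integer of hierarchy levels; `dagDepth`: the
#'   maximal level in the DAG (an integer).
#' @name LevelMap-accessors
#' @examples
#' lv <- assignLevels(toyDAG())
#' dagDepth(lv)
NULL

#' @rdname LevelMap-accessors
setMethod("termLevels", "LevelMap", function(x) x@level)

#' @rdname LevelMap-accessors
setMethod("dagDepth", "LevelMap", function(x) x@depth)

setMethod("show", "LevelMap", function(object) {
  cat(sprintf("LevelMap: %d terms, depth %d\n",
              length(object@level), object@depth))
  tb <- table(object@level)
  cat("  terms per level:",
      paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
})

#' Accessor for CategoryAssignment objects
#'
#' @param x a [CategoryAssignment-class].
#' @return data.frame with columns `term`, `category`, `level`, one row per
#'   non-root term.
#' @name CategoryAssignment-accessors
NULL

#' @rdname CategoryAssignment-accessors
setMethod("categories", "CategoryAssignment", function(x) {
  data.frame(term = names(x@category), category = unname(x@category),
             level = unname(x@level), stringsAsFactors = FALSE)
})

setMethod("show", "CategoryAssignment", function(object) {
  cat(sprintf("CategoryAssignment: %d non-root terms\n",
              length(object@category)))
  print(table(category = object@category))
})

#' Accessors for ReducedDAG objects
#'
#' @param x a [ReducedDAG-class].
#' @return `summaryNodes`: data.frame (`id`, `category`, `level`, `count`);
#'   `summaryEdges`: data.frame (`from`, `to`, `n`).
#' @name ReducedDAG-accessors
NULL

#' @rdname ReducedDAG-accessors
setMethod("summaryNodes", "ReducedDAG", function(x) x@nodes)

#' @rdname ReducedDAG-accessors
setMethod("summaryEdges", "ReducedDAG", function(x) x@edges)

setMethod("show", "ReducedDAG", function(object) {
  cat(sprintf("ReducedDAG: %d summary nodes, %d edges%s\n",
              nrow(object@nodes), nrow(object@edges),
              if (object@hasRoot) " (root pseudo-node shown)" else ""))
  print(object@nodes, row.names = FALSE)
})

#' Accessors for PriorityResult objects
#'
#' @param x a [PriorityResult-class].
#' @return `retained`: retained term ids in selection order; `eliminatedBy`:
#'   named list mapping each retained term to the terms it eliminated.
#' @name PriorityResult-accessors
NULL

#' @rdname PriorityResult-accessors
setMethod("retained", "PriorityResult", function(x) x@retained)

#' @rdname PriorityResult-accessors
setMethod("eliminatedBy", "PriorityResult", function(x) x@eliminatedBy)

setMethod("show", "PriorityResult", function(object) {
  cat(sprintf("PriorityResult: %d of %d terms retained\n",
              object@outputSize, object@inputSize))
  for (t in object@retained) {
    el <- object@eliminatedBy[[t]]
    cat(sprintf("  %s%s\n", t,
                if (length(el)) paste0(" (eliminated: ",
                                       paste(el, collapse = ", "), ")")
                else ""))
  }
})
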