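# Accessor generics. Prefixed with dag- to avoid clashing with igraph's
# function names when both packages are attached.

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("dagRoot", function(x) standardGeneric("dagRoot"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("dagNamespace", function(x) standardGeneric("dagNamespace"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("dagChildren", function(x, term) standardGeneric("dagChildren"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("dagAliases", function(x) standardGeneric("dagAliases"))

#' @rdname LevelMap-accessors
#' @export
setGeneric("termLevels", function(x) standardGeneric("termLevels"))

#' @rdname LevelMap-accessors
#' @export
setGeneric("dagDepth", function(x) standardGeneric("dagDepth"))

#' @rdname PriorityResult-accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' @rdname PriorityResult-accessors
#' @export
setGeneric("eliminatedBy", function(x) standardGeneric("eliminatedBy"))

#' @rdname ReducedDAG-accessors
#' @export
setGeneric("summaryNodes", function(x) standardGeneric("summaryNodes"))

#' @rdname ReducedDAG-accessors
#' @export
setGeneric("summaryEdges", function(x) standardGeneric("summaryEdges"))

#' @rdname CategoryAssignment-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' Export a graph as DOT text
#'
#' Renders an [OntologyDAG-class] or a [ReducedDAG-class] as a Graphviz DOT
#' digraph. Hierarchy levels become `rank=same` groups, so standard DOT layout
#' engines draw levels as horizontal layers. Reduced-DAG nodes are labelled
#' `"<category>\\nlevel <l>\\nn=<count>"`.
#'
#' @param x graph to export.
#' @param file optional path; when given the DOT text is also written there.
#' @param ... unused.
#' @return character vector of DOT lines, invisibly when `file` is given.
#' @examples
#' dot <- writeDOT(toyDAG())
#' @export
setGeneric("writeDOT", function(x, file = NULL, ...) standardGeneric("writeDOT"))

#' Export a graph as GraphML
#'
#' @param x an [OntologyDAG-class] or [ReducedDAG-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
setGeneric("writeGraphML", function(x, file) standardGeneric("writeGraphML"))
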