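#' @name accessors
#' @title Accessors for myoGRN classes
#' @param x an object.
#' @return the slot contents; see the class documentation.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))
#' @rdname accessors
#' @export
setGeneric("stageNames", function(x) standardGeneric("stageNames"))
#' @rdname accessors
#' @export
setGeneric("stageSetList", function(x) standardGeneric("stageSetList"))
#' @rdname accessors
#' @export
setGeneric("hubs", function(x) standardGeneric("hubs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
setMethod("exprValues", "ExprMatrix", function(x)
  SummarizedExperiment::assay(x, "expr"))
#' @rdname accessors
setMethod("valueKind", "ExprMatrix", function(x) x@valueKind)
#' @rdname accessors
setMethod("geneLengths", "ExprMatrix", function(x) {
  gl <- SummarizedExperiment::rowData(x)$gene_length
  if (is.null(gl)) NULL else stats::setNames(gl, rownames(x))
})
#' @rdname accessors
setMethod("geneIds", "ExprMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("sampleIds", "ExprMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("stageNames", "StageProfiles", function(x) colnames(x))

#' @rdname accessors
setMethod("setName", "GeneSet", function(x) x@name)
#' @rdname accessors
setMethod("members", "GeneSet", function(x) x@members)
#' @rdname accessors
setMethod("geneIds", "GeneSet", function(x) x@members)

#' @rdname accessors
setMethod("graphNodes", "InteractionGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "InteractionGraph", function(x) x@edges)
#' @rdname accessors
setMethod("nodeDegree", "InteractionGraph", function(x) {
  d <- stats::setNames(integer(length(x@nodes)), x@nodes)
  if (nrow(x@edges)) {
    tab <- table(c(x@edges$node_a, x@edges$node_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
})

#' @rdname accessors
setMethod("stageNames", "StageSets", function(x) x@stages)
#' @rdname accessors
setMethod("stageSetList", "StageSets", function(x) x@sets)

#' @rdname accessors
setMethod("hubs", "CoreGRN", function(x) x@hubs)
#' @rdname accessors
setMethod("provenance", "CoreGRN", function(x) x@provenance)
#' @rdname accessors
setMethod("graphEdges", "CoreGRN", function(x) x@edges)

setMethod("show", "ExprMatrix", function(object) {
  cat(sprintf("%s: %d genes x %d samples [%s]\n", class(object),
              nrow(object), ncol(object), object@valueKind))
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes)", object@name, length(object@members)))
  if (length(object@members))
    cat(": ", paste(utils::head(object@members, 5L), collapse = ", "),
        if (length(object@members) > 5L) ", ..." else "", sep = "")
  cat("\n")
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "StageSets", function(object) {
  sizes <- vapply(object@sets, length, integer(1))
  cat("StageSets:", paste(sprintf("%s=%d", object@stages, sizes),
                          collapse = ", "), "\n")
})

setMethod("show", "CoreGRN", function(object) {
  cat(sprintf("CoreGRN: %d hubs (of %d candidates), %d hub-hub edges\n",
              length(object@hubs@members), object@candidateSize,
              nrow(object@edges)))
})

setMethod("show", "MaturityReport", function(object) {
  cat(sprintf("MaturityReport for %d cell type(s): %s\n",
              length(object@perCellType),
              paste(names(object@perCellType), collapse = ", ")))
})
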