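#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor sd quantile hclust cutree as.dist lm coef rnorm runif rexp setNames
#' @importFrom utils head read.delim write.table
NULL

VALUE_KINDS <- c("counts", "fpkm", "log2fpkm1", "nx")

#' Gene-by-sample expression matrix with a declared value kind
#'
#' `ExprMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"expr"` (genes in rows, samples in columns) and a declared
#' `valueKind`: raw counts, FPKM, `log2(FPKM + 1)` or consensus normalized
#' expression (NX, one column per tissue). Optional per-gene transcript
#' lengths (base pairs) live in `rowData(x)$gene_length` and are required
#' for FPKM conversion.
#'
#' @slot valueKind one of `"counts"`, `"fpkm"`, `"log2fpkm1"`, `"nx"`.
#' @export
setClass("ExprMatrix",
  contains = "SummarizedExperiment",
  representation(valueKind = "character"))

setValidity("ExprMatrix", function(object) {
  msg <- character()
  if (length(object@valueKind) != 1L || !object@valueKind %in% VALUE_KINDS)
    msg <- c(msg, sprintf("valueKind must be one of %s",
                          paste(VALUE_KINDS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, "expr")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present and unique")
  if (any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "values must be finite or NA")
  if (length(object@valueKind) == 1L &&
      object@valueKind %in% c("counts", "fpkm", "nx") &&
      any(v < 0, na.rm = TRUE))
    msg <- c(msg, sprintf("%s values must be >= 0", object@valueKind))
  gl <- SummarizedExperiment::rowData(object)$gene_length
  if (!is.null(gl) && any(!is.na(gl) & gl <= 0))
    msg <- c(msg, "gene lengths must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an ExprMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples/tissues/stages in columns (colnames = sample ids).
#' @param valueKind one of `"counts"`, `"fpkm"`, `"log2fpkm1"`, `"nx"`.
#' @param geneLengths optional named numeric vector of transcript lengths
#'   (bp), names matching gene ids.
#' @return an [ExprMatrix-class] object.
#' @export
ExprMatrix <- function(values, valueKind = c("counts", "fpkm", "log2fpkm1", "nx"),
                       geneLengths = NULL) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(geneLengths)) {
    if (is.null(names(geneLengths)))
      stop("geneLengths must be a named vector")
    rd$gene_length <- unname(geneLengths[rownames(values)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), rowData = rd)
  new("ExprMatrix", se, valueKind = valueKind)
}

#' Stage-ordered mean-expression profiles
#'
#' An [ExprMatrix-class] whose columns are ordered myo-differentiation
#' stages (pluripotent -> presomite -> myogenic progenitor -> myoblast ->
#' myotube) holding per-stage mean expression on the FPKM scale. Column
#' order is meaningful and preserved.
#' @export
setClass("StageProfiles", contains = "ExprMatrix")

setValidity("StageProfiles", function(object) {
  if (ncol(object) < 2L) "at least 2 stages required" else TRUE
})

#' Construct stage profiles
#' @param values gene x stage matrix of stage-mean expression (FPKM scale).
#' @param stages optional character vector of ordered stage names
#'   (defaults to `colnames(values)`).
#' @return a [StageProfiles-class] object.
#' @export
StageProfiles <- function(values, stages = colnames(values)) {
  values <- as.matrix(values)
  colnames(values) <- stages
  em <- ExprMatrix(values, valueKind = "fpkm")
  new("StageProfiles", em)
}

#' Named gene collection (GMT-compatible)
#'
#' @slot name set name (non-empty).
#' @slot description free-text description.
#' @slot members unique gene identifiers.
#' @export
setClass("GeneSet",
  representation(name = "character", description = "character",
                 members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#' @param name set name.
#' @param members character vector of gene ids (deduplicated with a warning).
#' @param description optional description.
#' @return a [GeneSet-class].
#' @export
GeneSet <- function(name, members, description = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warning(sprintf("duplicate members in gene set '%s' removed", name))
    members <- unique(members)
  }
  new("GeneSet", name = name, description = description, members = members)
}

#' Undirected scored interaction graph
#'
#' Gene nodes with undirected edges carrying a confidence score in `[0, 1]`
#' (STRING-style combined scores divided by 1000 fit this scale). Isolated
#' nodes are representable: the node set is stored explicitly.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `node_a`, `node_b`, `score`.
#' @export
setClass("InteractionGraph",
  representation(nodes = "character", edges = "data.frame"))

setValidity("InteractionGraph", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  e <- object@edges
  if (!all(c("node_a", "node_b", "score") %in% names(e)))
    msg <- c(msg, "edges must have columns node_a, node_b, score")
  else if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-loops not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be graph nodes")
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    if (any(e$score < 0 | e$score > 1)) msg <- c(msg, "scores must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionGraph
#' @param edges data.frame with columns `node_a`, `node_b`, `score`
#'   (score in `[0,1]`).
#' @param nodes optional node universe; defaults to the union of edge
#'   endpoints. Extra names become isolated nodes.
#' @return an [InteractionGraph-class].
#' @export
InteractionGraph <- function(edges = data.frame(node_a = character(),
                                                node_b = character(),
                                                score = numeric()),
                             nodes = NULL) {
  edges <- as.data.frame(edges)
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (is.null(nodes)) nodes <- union(edges$node_a, edges$node_b)
  new("InteractionGraph", nodes = as.character(nodes), edges = edges)
}

#' Disjoint partition of genes by expression-onset stage
#'
#' @slot stages ordered stage names.
#' @slot sets named list (one character vector per stage) of genes whose
#'   persistent expression starts at that stage; pairwise disjoint.
#' @export
setClass("StageSets",
  representation(stages = "character", sets = "list"))

setValidity("StageSets", function(object) {
  msg <- character()
  if (!identical(names(object@sets), object@stages))
    msg <- c(msg, "sets must be named by stages, in stage order")
  all_members <- unlist(object@sets, use.names = FALSE)
  if (anyDuplicated(all_members))
    msg <- c(msg, "stage sets must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' @rdname StageSets-class
#' @param stages ordered stage names.
#' @param sets list of character vectors, one per stage.
#' @return a [StageSets-class].
#' @export
StageSets <- function(stages, sets) {
  names(sets) <- stages
  new("StageSets", stages = as.character(stages),
      sets = lapply(sets, as.character))
}

#' Core gene regulatory network of hub genes
#'
#' @slot hubs [GeneSet-class] of hub genes (each with degree >= 3 in the
#'   confidence-filtered graph).
#' @slot edges data.frame of edges among hubs (`node_a`, `node_b`, `score`).
#' @slot provenance per-candidate data.frame recording degree, the number
#'   of centrality methods ranking it within the top-k, seed association
#'   and the final hub call.
#' @slot candidateSize size of the candidate set the hubs were drawn from.
#' @export
setClass("CoreGRN",
  representation(hubs = "GeneSet", edges = "data.frame",
                 provenance = "data.frame", candidateSize = "integer"))

setValidity("CoreGRN", function(object) {
  p <- object@provenance
  need <- c("gene", "degree", "n_top_methods", "seed_associated", "is_hub")
  if (!all(need %in% names(p)))
    return(sprintf("provenance must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(p) && any(p$is_hub & p$degree < 3))
    return("every hub must have degree >= 3")
  TRUE
})

#' Per-cell-type maturity report
#'
#' Overlap counts and percentages of each cell type's differentially
#' expressed genes against the core GRN hubs, the muscle-restricted
#' signature, the stage-onset sets and the maintenance genes; plus the
#' common up/down intersections across cell types.
#'
#' @slot perCellType named list of per-cell-type metric lists.
#' @slot common list with `up`, `down` (common DEG sets) or empty list.
#' @slot params list of the thresholds and inputs used.
#' @export
setClass("MaturityReport",
  representation(perCellType = "list", common = "list", params = "list"))

setValidity("MaturityReport", function(object) {
  ok <- vapply(object@perCellType, is.list, logical(1))
  if (!all(ok)) "perCellType must be a list of lists" else TRUE
})
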