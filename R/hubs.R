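#' Filter interaction edges by confidence score
#'
#' Keeps edges with `score >= minScore` (inclusive; the study cutoff is
#' the highest-confidence 0.9). Isolated nodes are retained in the node
#' set. Idempotent.
#'
#' @param graph an [InteractionGraph-class].
#' @param minScore minimum confidence score (default 0.9).
#' @return the filtered [InteractionGraph-class].
#' @export
filterEdges <- function(graph, minScore = 0.9) {
  stopifnot(is(graph, "InteractionGraph"))
  e <- graph@edges
  InteractionGraph(e[e$score >= minScore, , drop = FALSE],
                   nodes = graph@nodes)
}

#' Degree-based hub calling
#'
#' Hubs are nodes with more than 2 connections to immediate neighbors,
#' i.e. degree `>= minDegree` with the default of 3.
#'
#' @param graph an [InteractionGraph-class].
#' @param minDegree minimum degree (default 3).
#' @return a [GeneSet-class] of hub nodes.
#' @export
degreeHubs <- function(graph, minDegree = 3L) {
  d <- nodeDegree(graph)
  GeneSet("degree_hubs", names(d)[d >= minDegree],
          sprintf("nodes with degree >= %d", minDegree))
}

#' Rank candidates by topological centralities and call hubs
#'
#' A candidate becomes a hub iff (i) its degree is at least `minDegree`,
#' (ii) it is ranked within the top `topK` (dense ranks, ties share a
#' rank) by at least `minMethods` of the requested centrality methods,
#' and (iii) it is a seed marker or directly adjacent to one. Provenance
#' records all three criteria for every candidate.
#'
#' @param graph an [InteractionGraph-class] (already confidence-filtered).
#' @param methods centrality method names (see [nodeCentrality()]).
#' @param candidates a [GeneSet-class] or character vector, subset of the
#'   graph's nodes.
#' @param seeds a [GeneSet-class] or character vector of seed markers
#'   (fiber type I/II markers in the reference analysis).
#' @param topK rank cutoff (default: number of candidates, a permissive
#'   reading).
#' @param minMethods how many methods must rank a candidate within
#'   `topK` (default 1).
#' @param minDegree degree criterion (default 3).
#' @param epcReductions,epcRetainP,epcSeed EPC parameters (see
#'   [epcCentrality()]).
#' @return a [CoreGRN-class].
#' @export
rankHubs <- function(graph, methods = CENTRALITY_METHODS, candidates, seeds,
                     topK = NULL, minMethods = 1L, minDegree = 3L,
                     epcReductions = 1000L, epcRetainP = 0.5, epcSeed = 1L) {
  stopifnot(is(graph, "InteractionGraph"))
  if (!length(methods)) stop("at least one centrality method required")
  cand <- if (is(candidates, "GeneSet")) members(candidates)
          else as.character(candidates)
  seedGenes <- if (is(seeds, "GeneSet")) members(seeds)
               else as.character(seeds)
  if (!all(cand %in% graph@nodes))
    stop("candidates must be a subset of graph nodes")
  if (is.null(topK)) topK <- length(cand)
  deg <- nodeDegree(graph)
  ranks <- vapply(methods, function(m) {
    sc <- if (m == "epc")
      epcCentrality(graph, nReductions = epcReductions,
                    retainP = epcRetainP, seed = epcSeed)
    else nodeCentrality(graph, m)
    as.numeric(denseRank(sc))
  }, numeric(length(graph@nodes)))
  ranks <- matrix(ranks, nrow = length(graph@nodes),
                  dimnames = list(graph@nodes, methods))
  ranks <- ranks[cand, , drop = FALSE]
  nTop <- rowSums(ranks <= topK)
  adj <- .adjList(graph)
  seedAssoc <- vapply(cand, function(v)
    v %in% seedGenes || any(adj[[v]] %in% seedGenes), logical(1))
  isHub <- deg[cand] >= minDegree & nTop >= minMethods & seedAssoc
  prov <- data.frame(gene = cand,
                     degree = as.integer(deg[cand]),
                     n_top_methods = as.integer(nTop),
                     seed_associated = seedAssoc,
                     is_hub = unname(isHub),
                     stringsAsFactors = FALSE, row.names = NULL)
  prov <- cbind(prov, as.data.frame(ranks)[, methods, drop = FALSE])
  hubGenes <- cand[isHub]
  e <- graph@edges
  hubEdges <- e[e$node_a %in% hubGenes & e$node_b %in% hubGenes, ,
                drop = FALSE]
  new("CoreGRN",
      hubs = GeneSet("core_grn_hubs", hubGenes,
                     "hub genes passing degree, rank and seed criteria"),
      edges = hubEdges, provenance = prov,
      candidateSize = length(cand))
}

#' Assemble the core gene regulatory network
#'
#' Candidate genes are the intersection of the co-expressed set and the
#' functionally annotated set; the interaction graph is restricted to
#' the candidates, confidence-filtered, and hubs are called via
#' [rankHubs()].
#'
#' @param coexpressed a [GeneSet-class] or character vector of genes
#'   co-expressed in the target tissue.
#' @param functional a [GeneSet-class] or character vector of genes with
#'   tissue-relevant functional annotation.
#' @param graph the full [InteractionGraph-class].
#' @param seeds seed marker genes (see [rankHubs()]).
#' @param minScore edge-confidence cutoff (default 0.9).
#' @param ... further arguments to [rankHubs()].
#' @return a [CoreGRN-class]; `@candidateSize` records the size of the
#'   intersection.
#' @export
assembleCoreGRN <- function(coexpressed, functional, graph, seeds,
                            minScore = 0.9, ...) {
  co <- if (is(coexpressed, "GeneSet")) members(coexpressed)
        else as.character(coexpressed)
  fn <- if (is(functional, "GeneSet")) members(functional)
        else as.character(functional)
  cand <- intersect(co, fn)
  cand <- intersect(cand, graph@nodes)
  e <- graph@edges
  sub <- InteractionGraph(
    e[e$node_a %in% cand & e$node_b %in% cand, , drop = FALSE],
    nodes = cand)
  sub <- filterEdges(sub, minScore)
  if (!length(cand))
    return(new("CoreGRN", hubs = GeneSet("core_grn_hubs", character()),
               edges = sub@edges,
               provenance = data.frame(gene = character(),
                                       degree = integer(),
                                       n_top_methods = integer(),
                                       seed_associated = logical(),
                                       is_hub = logical()),
               candidateSize = 0L))
  rankHubs(sub, candidates = cand, seeds = seeds, ...)
}
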