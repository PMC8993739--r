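CENTRALITY_METHODS <- c("degree", "epc", "mnc", "dmnc", "mcc", "bottleneck",
                        "eccentricity", "closeness", "radiality",
                        "betweenness", "stress", "clustering_coefficient")

#' Topological centrality scores for hub ranking
#'
#' Twelve node-importance measures used to rank hub candidates, defined
#' on the unweighted undirected graph:
#' \describe{
#'   \item{degree}{edge count.}
#'   \item{epc}{edge-percolated component (Monte Carlo; see
#'     [epcCentrality()]).}
#'   \item{mnc}{size of the largest connected component of the induced
#'     neighbor subgraph.}
#'   \item{dmnc}{`|E| / |V|^1.7` of that component.}
#'   \item{mcc}{sum over maximal cliques `C` containing the node with
#'     `|C| >= 2` of `(|C| - 1)!`; 0 for isolated nodes.}
#'   \item{bottleneck}{number of single-source shortest-path trees in
#'     which the node's descendant count strictly exceeds a quarter of
#'     the tree size.}
#'   \item{eccentricity}{reciprocal of the node's eccentricity within its
#'     component (0 for isolated nodes).}
#'   \item{closeness}{harmonic closeness, `sum_w 1/d(v, w)` with
#'     `1/Inf = 0`.}
#'   \item{radiality}{`sum_w (diam_C + 1 - d(v, w)) / (n_C - 1)` over the
#'     node's component `C`.}
#'   \item{betweenness}{`sum_{s<t} sigma_st(v) / sigma_st`.}
#'   \item{stress}{number of shortest s--t paths passing through the
#'     node.}
#'   \item{clustering_coefficient}{`2 e_N / (deg (deg - 1))`, 0 for
#'     degree < 2.}
#' }
#' Isolated nodes score 0 under every method.
#'
#' @param graph an [InteractionGraph-class].
#' @param method one of the method names above (`"epc"` delegates to
#'   [epcCentrality()] with defaults).
#' @param ... passed on to [epcCentrality()] when `method = "epc"`.
#' @return named numeric vector of node scores.
#' @export
nodeCentrality <- function(graph, method, ...) {
  stopifnot(is(graph, "InteractionGraph"))
  if (!method %in% CENTRALITY_METHODS)
    stop("unknown centrality method '", method, "'")
  if (method == "epc") return(epcCentrality(graph, ...))
  g <- asIgraph(graph)
  nodes <- graph@nodes
  n <- length(nodes)
  zero <- stats::setNames(numeric(n), nodes)
  if (n == 0L) return(zero)
  deg <- stats::setNames(as.numeric(igraph::degree(g)), nodes)
  if (method == "degree") return(deg)
  if (method == "clustering_coefficient") {
    adj <- .adjList(graph)
    cc <- vapply(nodes, function(v) {
      nb <- adj[[v]]
      d <- length(nb)
      if (d < 2L) return(0)
      eN <- 0L
      for (i in seq_len(d - 1L)) for (j in (i + 1L):d)
        if (nb[j] %in% adj[[nb[i]]]) eN <- eN + 1L
      2 * eN / (d * (d - 1))
    }, numeric(1))
    return(cc)
  }
  if (method %in% c("mnc", "dmnc")) {
    adj <- .adjList(graph)
    out <- zero
    for (v in nodes) {
      nb <- adj[[v]]
      if (!length(nb)) next
      sub <- igraph::induced_subgraph(g, nb)
      comp <- igraph::components(sub)
      big <- which(comp$csize == max(comp$csize))
      # deterministic tie-break: component holding the smallest-index node
      memberIdx <- lapply(big, function(cid)
        match(igraph::V(sub)$name[comp$membership == cid], nodes))
      pick <- big[which.min(vapply(memberIdx, min, integer(1)))]
      vs <- igraph::V(sub)[comp$membership == pick]
      csub <- igraph::induced_subgraph(sub, vs)
      out[v] <- if (method == "mnc") length(vs)
                else igraph::ecount(csub) / length(vs)^1.7
    }
    return(out)
  }
  if (method == "mcc") {
    out <- zero
    if (igraph::ecount(g) > 0) {
      cliques <- igraph::max_cliques(g, min = 2L)
      for (cl in cliques) {
        w <- factorial(length(cl) - 1L)
        nm <- igraph::V(g)$name[as.integer(cl)]
        out[nm] <- out[nm] + w
      }
    }
    return(out)
  }
  # shortest-path based measures
  D <- igraph::distances(g)
  D <- D[nodes, nodes, drop = FALSE]
  if (method == "closeness") {
    inv <- 1 / D
    diag(inv) <- 0
    inv[is.infinite(D)] <- 0
    return(rowSums(inv))
  }
  if (method == "eccentricity") {
    out <- zero
    for (v in nodes) {
      dv <- D[v, ]
      finite <- dv[is.finite(dv) & names(dv) != v]
      if (length(finite) && max(finite) > 0) out[v] <- 1 / max(finite)
    }
    return(out)
  }
  if (method == "radiality") {
    out <- zero
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      mem <- igraph::V(g)$name[comp$membership == cid]
      nC <- length(mem)
      if (nC < 2L) next
      sub <- D[mem, mem, drop = FALSE]
      diam <- max(sub)
      for (v in mem)
        out[v] <- sum(diam + 1 - sub[v, setdiff(mem, v)]) / (nC - 1)
    }
    return(out)
  }
  if (method %in% c("betweenness", "stress")) {
    sp <- .pathCounts(graph)
    out <- zero
    for (si in seq_len(n - 1L)) for (ti in (si + 1L):n) {
      if (!is.finite(sp$dist[si, ti])) next
      tot <- sp$sigma[si, ti]
      if (tot == 0) next
      onPath <- is.finite(sp$dist[si, ]) & is.finite(sp$dist[, ti]) &
        sp$dist[si, ] + sp$dist[, ti] == sp$dist[si, ti]
      onPath[c(si, ti)] <- FALSE
      through <- sp$sigma[si, ] * sp$sigma[, ti] * onPath
      out <- out + if (method == "stress") through else through / tot
    }
    return(out)
  }
  if (method == "bottleneck") return(.bottleneck(graph))
  stop("unreachable")
}

# adjacency list keyed by node name, neighbors ordered by node index
.adjList <- function(graph) {
  nodes <- graph@nodes
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  e <- graph@edges
  for (i in seq_len(nrow(e))) {
    adj[[e$node_a[i]]] <- c(adj[[e$node_a[i]]], e$node_b[i])
    adj[[e$node_b[i]]] <- c(adj[[e$node_b[i]]], e$node_a[i])
  }
  idx <- stats::setNames(seq_along(nodes), nodes)
  lapply(adj, function(nb) nb[order(idx[nb])])
}

# all-pairs geodesic distances and shortest-path counts via BFS per source
.pathCounts <- function(graph) {
  nodes <- graph@nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adjI <- lapply(.adjList(graph), function(nb) unname(idx[nb]))
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- numeric(n); sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adjI[[v]]) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  list(dist = dist, sigma = sigma)
}

# Bottleneck: deterministic BFS trees (parent = smallest-index neighbor at
# the shallower level); +1 whenever a node's proper-descendant count
# strictly exceeds a quarter of its tree's size.
.bottleneck <- function(graph) {
  nodes <- graph@nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- .adjList(graph)
  g <- asIgraph(graph)
  D <- igraph::distances(g)[nodes, nodes, drop = FALSE]
  out <- stats::setNames(numeric(n), nodes)
  for (s in nodes) {
    tree <- nodes[is.finite(D[s, ])]
    ns <- length(tree)
    if (ns < 2L) next
    parent <- stats::setNames(rep(NA_character_, ns), tree)
    for (v in setdiff(tree, s)) {
      shal <- adj[[v]][D[s, adj[[v]]] == D[s, v] - 1]
      parent[v] <- shal[which.min(idx[shal])]
    }
    desc <- stats::setNames(numeric(ns), tree)
    for (v in tree[order(-D[s, tree])]) {
      p <- parent[v]
      if (!is.na(p)) desc[p] <- desc[p] + desc[v] + 1
    }
    hit <- tree[desc > ns / 4]
    out[hit] <- out[hit] + 1
  }
  out
}

#' Edge-percolated component centrality (Monte Carlo)
#'
#' Over `nReductions` random subgraphs -- each edge kept independently
#' with probability `retainP` -- a node's EPC is the mean number of other
#' nodes reachable from it. Fixed `seed` gives byte-identical output.
#'
#' @param graph an [InteractionGraph-class].
#' @param nReductions number of percolation draws (>= 1; default 1000).
#' @param retainP edge retention probability (default 0.5).
#' @param seed RNG seed for the percolation draws.
#' @return named numeric vector of EPC scores.
#' @export
epcCentrality <- function(graph, nReductions = 1000L, retainP = 0.5,
                          seed = 1L) {
  stopifnot(is(graph, "InteractionGraph"))
  if (nReductions < 1L) stop("nReductions must be >= 1")
  nodes <- graph@nodes
  e <- graph@edges
  acc <- stats::setNames(numeric(length(nodes)), nodes)
  withSeed(seed, {
    for (r in seq_len(nReductions)) {
      keep <- stats::runif(nrow(e)) < retainP
      sub <- igraph::graph_from_data_frame(
        e[keep, c("node_a", "node_b"), drop = FALSE],
        directed = FALSE, vertices = data.frame(name = nodes))
      comp <- igraph::components(sub)
      reach <- comp$csize[comp$membership] - 1
      acc <- acc + stats::setNames(reach[match(nodes, igraph::V(sub)$name)],
                                   nodes)
    }
  })
  acc / nReductions
}
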