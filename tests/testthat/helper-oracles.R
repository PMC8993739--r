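# Independent brute-force oracles. These re-derive every quantity from
# first principles (subset/path enumeration, exhaustive percolation,
# integer arithmetic) and share no code with the package implementation.

# ---- random fixtures --------------------------------------------------

randomAdjacency <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (runif(1) < p) { ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j]) }
  InteractionGraph(data.frame(node_a = ea, node_b = eb,
                              score = rep(1, length(ea))),
                   nodes = nodes)
}

graphAdjMatrix <- function(graph) {
  nodes <- graphNodes(graph)
  M <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- graphEdges(graph)
  for (i in seq_len(nrow(e))) {
    M[e$node_a[i], e$node_b[i]] <- 1L
    M[e$node_b[i], e$node_a[i]] <- 1L
  }
  M
}

# ---- TOM oracle -------------------------------------------------------

bruteTom <- function(A) {
  n <- nrow(A)
  out <- matrix(1, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, ]); kj <- sum(A[j, ])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  out
}

# ---- shortest-path oracle via exhaustive simple-path enumeration ------

# all simple paths s -> t, returning for the minimal length: the count
# and how many minimal paths pass through each interior node
brutePathInfo <- function(M, s, t) {
  n <- nrow(M)
  best <- Inf; count <- 0; through <- numeric(n)
  walk <- function(v, visited, len) {
    if (v == t) {
      if (len < best) { best <<- len; count <<- 0; through <<- numeric(n) }
      if (len == best) {
        count <<- count + 1
        inner <- setdiff(visited, c(s, t))
        through[inner] <<- through[inner] + 1
      }
      return()
    }
    if (len >= best) return()
    for (w in which(M[v, ] == 1L))
      if (!w %in% visited) walk(w, c(visited, w), len + 1L)
  }
  walk(s, s, 0L)
  list(dist = best, count = count, through = through)
}

bruteShortestPaths <- function(M) {
  n <- nrow(M)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, c(n, n, n))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    pi <- brutePathInfo(M, s, t)
    dist[s, t] <- pi$dist
    sigma[s, t] <- pi$count
    through[s, t, ] <- pi$through
  }
  list(dist = dist, sigma = sigma, through = through)
}

bruteBetweennessStress <- function(M) {
  sp <- bruteShortestPaths(M)
  n <- nrow(M)
  btw <- numeric(n); str <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(sp$dist[s, t]) || sp$sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      str[v] <- str[v] + sp$through[s, t, v]
      btw[v] <- btw[v] + sp$through[s, t, v] / sp$sigma[s, t]
    }
  }
  list(betweenness = btw, stress = str, dist = sp$dist)
}

bruteCloseness <- function(dist) {
  n <- nrow(dist)
  vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    sum(ifelse(is.finite(d) & d > 0, 1 / d, 0))
  }, numeric(1))
}

bruteEccentricity <- function(dist) {
  n <- nrow(dist)
  vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    d <- d[is.finite(d)]
    if (!length(d) || max(d) == 0) 0 else 1 / max(d)
  }, numeric(1))
}

bruteRadiality <- function(dist) {
  n <- nrow(dist)
  out <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(dist[v, ]))
    nC <- length(comp)
    if (nC < 2L) next
    diam <- max(dist[comp, comp])
    out[v] <- sum(diam + 1 - dist[v, setdiff(comp, v)]) / (nC - 1)
  }
  out
}

bruteClusteringCoef <- function(M) {
  n <- nrow(M)
  vapply(seq_len(n), function(v) {
    nb <- which(M[v, ] == 1L)
    d <- length(nb)
    if (d < 2L) return(0)
    eN <- sum(M[nb, nb]) / 2
    2 * eN / (d * (d - 1))
  }, numeric(1))
}

# flood-fill connected components of an induced subgraph
bruteComponents <- function(M, vs) {
  comps <- list()
  left <- vs
  while (length(left)) {
    frontier <- left[1L]; comp <- frontier
    left <- setdiff(left, frontier)
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v)
        intersect(which(M[v, ] == 1L), left))))
      comp <- c(comp, nxt)
      left <- setdiff(left, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

bruteMncDmnc <- function(M) {
  n <- nrow(M)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(M[v, ] == 1L)
    if (!length(nb)) next
    comps <- bruteComponents(M, nb)
    sizes <- vapply(comps, length, integer(1))
    big <- comps[sizes == max(sizes)]
    # deterministic tie-break: component holding the smallest-index node
    pick <- big[[which.min(vapply(big, min, integer(1)))]]
    mnc[v] <- length(pick)
    dmnc[v] <- (sum(M[pick, pick]) / 2) / length(pick)^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

bruteMcc <- function(M) {
  n <- nrow(M)
  out <- numeric(n)
  idx <- seq_len(n)
  isClique <- function(S) {
    if (length(S) < 2L) return(FALSE)
    all(M[S, S][upper.tri(M[S, S])] == 1L)
  }
  for (bits in seq_len(2^n - 1L)) {
    S <- idx[bitwAnd(bits, 2^(idx - 1L)) > 0]
    if (length(S) < 2L || !isClique(S)) next
    maximal <- !any(vapply(setdiff(idx, S), function(w)
      all(M[w, S] == 1L), logical(1)))
    if (maximal) out[S] <- out[S] + factorial(length(S) - 1L)
  }
  out
}

# independent re-derivation of the deterministic bottleneck rule
bruteBottleneck <- function(M, dist) {
  n <- nrow(M)
  out <- numeric(n)
  for (s in seq_len(n)) {
    tree <- which(is.finite(dist[s, ]))
    ns <- length(tree)
    if (ns < 2L) next
    parent <- rep(NA_integer_, n)
    for (v in setdiff(tree, s)) {
      cand <- which(M[v, ] == 1L & dist[s, ] == dist[s, v] - 1)
      parent[v] <- min(cand)
    }
    descCount <- function(v) {
      kids <- which(parent == v)
      if (!length(kids)) return(0)
      sum(vapply(kids, function(k) 1 + descCount(k), numeric(1)))
    }
    for (v in tree) if (descCount(v) > ns / 4) out[v] <- out[v] + 1
  }
  out
}

# exhaustive expected percolated reachability over all 2^|E| subgraphs
bruteEpcExpectation <- function(graph, retainP) {
  nodes <- graphNodes(graph)
  e <- graphEdges(graph)
  m <- nrow(e)
  exp_reach <- setNames(numeric(length(nodes)), nodes)
  for (bits in 0:(2^m - 1L)) {
    keep <- if (m) bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0 else logical(0)
    w <- prod(c(retainP^sum(keep), (1 - retainP)^sum(!keep)))
    sub <- InteractionGraph(e[keep, , drop = FALSE], nodes = nodes)
    M <- graphAdjMatrix(sub)
    comps <- bruteComponents(M, seq_along(nodes))
    for (comp in comps)
      exp_reach[nodes[comp]] <- exp_reach[nodes[comp]] +
        w * (length(comp) - 1)
  }
  exp_reach
}

# exact half-away-from-zero rounding of 100 * k / n via integer arithmetic
bruteRoundPct <- function(k, n, digits) {
  num <- as.numeric(k) * 100 * 10^digits
  q <- num %/% n
  r <- num %% n
  (q + as.numeric(2 * r >= n)) / 10^digits
}
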