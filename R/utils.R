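#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all reported overlap percentages (e.g. 42/116 of a
#' reference -> 36.21%).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (>= 0).
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0L) {
  p <- 10^digits
  s <- sign(x)
  a <- abs(x) * p
  f <- floor(a)
  up <- (a - f) >= 0.5
  s * (f + as.numeric(up)) / p
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Substream seeds: distinct deterministic offsets per generator keep one
# generator call from perturbing another's draws. Kept below 2^31.
subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

asIgraph <- function(graph) {
  stopifnot(is(graph, "InteractionGraph"))
  e <- graph@edges
  igraph::graph_from_data_frame(
    d = if (nrow(e)) e[, c("node_a", "node_b", "score")]
        else data.frame(node_a = character(), node_b = character(),
                        score = numeric()),
    directed = FALSE,
    vertices = data.frame(name = graph@nodes))
}

# Dense competition-free ranks: highest score -> rank 1; ties share a rank
# and the next distinct score gets the next consecutive rank.
denseRank <- function(scores) {
  u <- sort(unique(scores), decreasing = TRUE)
  match(scores, u)
}

geneSetFrom <- function(x, name = "set") {
  if (is(x, "GeneSet")) x else GeneSet(name, as.character(x))
}
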