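#' Parameters for weighted co-expression network construction
#'
#' @param candidatePowers soft-threshold powers to scan (default 1..20).
#' @param targetR2 scale-free fit target for the signed R^2 (default 0.8,
#'   the criterion under which a power of 14 was selected on the
#'   473-sample skeletal-muscle reference compendium).
#' @param minModuleSize smallest reportable module (default 30).
#' @param mergeCutHeight eigengene-dissimilarity cut for module merging
#'   (default 0.25, i.e. modules with eigengene correlation above 0.75
#'   are merged).
#' @param nBins equal-count bins for the scale-free degree fit (default 10).
#' @param cutHeightFrac static tree-cut height as a fraction of the
#'   maximum merge height (default 0.99).
#' @return list of class `CoexpressionParams`.
#' @export
coexpressionParams <- function(candidatePowers = 1:20, targetR2 = 0.8,
                               minModuleSize = 30L, mergeCutHeight = 0.25,
                               nBins = 10L, cutHeightFrac = 0.99) {
  stopifnot(all(candidatePowers >= 1), minModuleSize >= 2,
            mergeCutHeight > 0, mergeCutHeight < 1, nBins >= 2)
  structure(list(candidatePowers = as.integer(candidatePowers),
                 targetR2 = targetR2, minModuleSize = as.integer(minModuleSize),
                 mergeCutHeight = mergeCutHeight, nBins = as.integer(nBins),
                 cutHeightFrac = cutHeightFrac),
            class = "CoexpressionParams")
}

# genes x samples value matrix with constant-gene check
.coexprValues <- function(x) {
  v <- if (is(x, "ExprMatrix")) exprValues(x) else as.matrix(x)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop("constant gene present ('",
         rownames(v)[which(sds == 0 | is.na(sds))[1L]],
         "'); run goodSamplesGenes first")
  v
}

#' Exclude outlying samples by standardized connectivity
#'
#' Each sample's connectivity is its summed Pearson correlation to all
#' other samples (over genes); samples whose connectivity z-score falls
#' below `zCut` are removed in a single pass.
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix (>= 4
#'   samples).
#' @param zCut z-score cutoff (default -2.5).
#' @return list with `matrix` (retained [ExprMatrix-class]) and
#'   `excluded` (character vector of removed sample ids, with their
#'   z-scores as names... see `zscores`), plus `zscores`.
#' @export
detectSampleOutliers <- function(x, zCut = -2.5) {
  v <- if (is(x, "ExprMatrix")) exprValues(x) else as.matrix(x)
  if (ncol(v) < 4L) stop("at least 4 samples required")
  C <- stats::cor(v)
  conn <- rowSums(C) - 1
  z <- as.numeric(scale(conn))
  names(z) <- colnames(v)
  if (all(is.na(z))) z[] <- 0   # identical samples: nothing to exclude
  excluded <- colnames(v)[!is.na(z) & z < zCut]
  keep <- setdiff(colnames(v), excluded)
  kind <- if (is(x, "ExprMatrix")) valueKind(x) else "log2fpkm1"
  list(matrix = ExprMatrix(v[, keep, drop = FALSE], valueKind = kind),
       excluded = excluded, zscores = z)
}

#' Select a soft-thresholding power against scale-free topology
#'
#' For each candidate power the weighted connectivity `k_i = sum_j a_ij`
#' is computed, binned into `nBins` equal-count bins, and
#' `log10(frequency)` regressed on `log10(mean k)`; the signed fit index
#' is `-sign(slope) * R^2`, penalizing a positive degree--frequency slope.
#' The chosen power is the smallest with a signed fit at or above
#' `targetR2`; when no power qualifies the best-fitting power is returned
#' with `reached = FALSE`.
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix (>= 10
#'   genes, no constant genes).
#' @param params a [coexpressionParams()].
#' @return list with `beta`, `reached`, and `fit` (data.frame: power,
#'   signed R^2, mean connectivity).
#' @export
pickSoftThreshold <- function(x, params = coexpressionParams()) {
  v <- .coexprValues(x)
  if (nrow(v) < 10L) stop("at least 10 genes required")
  absCor <- abs(stats::cor(t(v)))
  diag(absCor) <- 0
  fit <- data.frame(power = params$candidatePowers, signedR2 = NA_real_,
                    meanK = NA_real_, slope = NA_real_)
  for (i in seq_along(params$candidatePowers)) {
    A <- absCor^params$candidatePowers[i]
    k <- rowSums(A)
    fit$meanK[i] <- mean(k)
    sf <- .scaleFreeFit(k, params$nBins)
    fit$signedR2[i] <- sf$signedR2
    fit$slope[i] <- sf$slope
  }
  ok <- which(!is.na(fit$signedR2) & fit$signedR2 >= params$targetR2)
  if (length(ok)) {
    list(beta = fit$power[ok[1L]], reached = TRUE, fit = fit)
  } else {
    best <- which.max(fit$signedR2)
    list(beta = fit$power[best], reached = FALSE, fit = fit)
  }
}

# Scale-free topology fit: equal-count binning of connectivity, linear
# regression of log10(freq) on log10(mean k) across bins.
.scaleFreeFit <- function(k, nBins) {
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1L)))
  if (length(breaks) < 3L) return(list(signedR2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meanK <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & meanK > 0
  if (sum(keep) < 3L) return(list(signedR2 = NA_real_, slope = NA_real_))
  m <- stats::lm(log10(freq[keep]) ~ log10(meanK[keep]))
  # a perfect fit is legitimate here (few distinct connectivity bins)
  r2 <- suppressWarnings(summary(m)$r.squared)
  slope <- stats::coef(m)[2L]
  list(signedR2 = -sign(slope) * r2, slope = unname(slope))
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` for `i != j`, zero diagonal. The
#' unsigned form treats strong negative co-expression as connection
#' strength, the convention under which correlations are "converted into
#' gene connection strengths".
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix with no
#'   constant genes.
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric gene-by-gene adjacency matrix with entries in
#'   `[0, 1]` and zero diagonal.
#' @export
adjacencyMatrix <- function(x, beta) {
  stopifnot(beta >= 1)
  v <- .coexprValues(x)
  A <- abs(stats::cor(t(v)))^beta
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; `TOM_ii = 1`.
#' Shared-neighbor weight damps spurious pairwise correlations.
#'
#' @param A symmetric adjacency with zero diagonal and entries in `[0, 1]`.
#' @return symmetric TOM with unit diagonal, entries in `[0, 1]`.
#' @export
tomSimilarity <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (any(A < 0 | A > 1)) stop("adjacency entries must be in [0, 1]")
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules by average-linkage clustering of 1 - TOM
#'
#' Average-linkage agglomerative clustering of the TOM dissimilarity with
#' a static cut at `cutHeightFrac` times the maximum merge height;
#' clusters smaller than `minModuleSize` are left unassigned (label 0) and
#' labels 1..M are given in decreasing size order (ties by lowest gene
#' index).
#'
#' @param tom a TOM matrix from [tomSimilarity()].
#' @param params a [coexpressionParams()].
#' @return list with `labels` (named integer vector) and `dendrogram`
#'   (the hclust object).
#' @export
clusterModules <- function(tom, params = coexpressionParams()) {
  genes <- rownames(tom)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(tom)))
  n <- nrow(tom)
  if (n < params$minModuleSize) {
    warning("fewer genes than minModuleSize; all genes unassigned")
    return(list(labels = stats::setNames(rep(0L, n), genes),
                dendrogram = NULL))
  }
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  cutAt <- params$cutHeightFrac * max(h$height)
  raw <- stats::cutree(h, h = cutAt)
  sizes <- table(raw)
  keepIds <- names(sizes)[sizes >= params$minModuleSize]
  labels <- stats::setNames(rep(0L, n), genes)
  if (length(keepIds)) {
    firstIdx <- vapply(keepIds, function(id) which(raw == id)[1L], integer(1))
    ord <- order(-as.integer(sizes[keepIds]), firstIdx)
    for (m in seq_along(ord)) {
      labels[raw == as.integer(keepIds[ord[m]])] <- m
    }
  }
  list(labels = labels, dendrogram = h)
}

#' Module eigengenes
#'
#' Genes are standardized across samples; each module's eigengene is the
#' first left singular vector (over samples) of its standardized
#' submatrix, unit norm, with the sign oriented so that its correlation
#' with the module's mean standardized profile is non-negative.
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @return list with `eigengenes` (module x sample matrix, rows named
#'   `ME<label>`) and `varExplained` (fraction of module variance carried
#'   by the eigengene).
#' @export
moduleEigengenes <- function(x, labels) {
  v <- if (is(x, "ExprMatrix")) exprValues(x) else as.matrix(x)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules to summarize")
  E <- matrix(NA_real_, length(mods), ncol(v),
              dimnames = list(paste0("ME", mods), colnames(v)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    sub <- v[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance gene '", genes[sds == 0][1L], "' in module ",
           mods[i])
    z <- t(scale(t(sub)))            # standardize genes across samples
    sv <- svd(t(z), nu = 1L, nv = 0L)  # samples x genes
    eg <- sv$u[, 1L]
    meanProf <- colMeans(z)
    if (sum(eg * meanProf) < 0) eg <- -eg
    E[i, ] <- eg
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, varExplained = ve)
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor` while that dissimilarity is below
#' `mergeCutHeight`, recomputing eigengenes after every merge; terminates
#' when all surviving pairwise eigengene correlations are at or below
#' `1 - mergeCutHeight` (0.75 at the default cut of 0.25). Idempotent.
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @param mergeCutHeight dissimilarity cut (default 0.25).
#' @return named integer labels, relabeled 1..M by decreasing size.
#' @export
mergeModules <- function(x, labels, mergeCutHeight = 0.25) {
  v <- if (is(x, "ExprMatrix")) exprValues(x) else as.matrix(x)
  lab <- labels
  repeat {
    mods <- sort(unique(lab[lab > 0]))
    if (length(mods) < 2L) break
    E <- moduleEigengenes(v, lab)$eigengenes
    C <- stats::cor(t(E))
    diss <- 1 - C
    diag(diss) <- Inf
    ij <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[ij[1L], ij[2L]] >= mergeCutHeight) break
    a <- mods[min(ij)]; b <- mods[max(ij)]
    lab[lab == b] <- a
  }
  # relabel by decreasing size, ties by first gene index
  mods <- sort(unique(lab[lab > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
    firstIdx <- vapply(mods, function(m) which(lab == m)[1L], integer(1))
    ord <- order(-sizes, firstIdx)
    out <- lab
    for (m in seq_along(ord)) out[lab == mods[ord[m]]] <- m
    lab <- out
  }
  lab
}

#' Run the full co-expression pipeline
#'
#' Outlier exclusion (optional), soft-threshold selection, adjacency,
#' TOM, static-cut module detection and eigengene merging, in order.
#'
#' @param x an [ExprMatrix-class] or genes-by-samples matrix.
#' @param params a [coexpressionParams()].
#' @param excludeOutliers run [detectSampleOutliers()] first (default
#'   FALSE; needs >= 4 samples).
#' @return list with `labels`, `beta`, `fit`, `excluded`, `dendrogram`.
#' @export
runCoexpression <- function(x, params = coexpressionParams(),
                            excludeOutliers = FALSE) {
  excluded <- character()
  if (excludeOutliers) {
    o <- detectSampleOutliers(x)
    x <- o$matrix
    excluded <- o$excluded
  }
  st <- pickSoftThreshold(x, params)
  A <- adjacencyMatrix(x, st$beta)
  tom <- tomSimilarity(A)
  cl <- clusterModules(tom, params)
  labels <- cl$labels
  if (length(unique(labels[labels > 0])) >= 2L)
    labels <- mergeModules(x, labels, params$mergeCutHeight)
  list(labels = labels, beta = st$beta, fit = st$fit,
       excluded = excluded, dendrogram = cl$dendrogram)
}
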