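#' Configuration for the synthetic-data generators
#'
#' One shared configuration drives every generator: a master seed (each
#' generator derives its own substream, so adding one generator call does
#' not perturb another's draws), the number of pure-noise background
#' genes, the Gaussian noise level, and the expression threshold -- a
#' value is "expressed" when it exceeds `exprThreshold`, mirroring the
#' NX > 1 convention used throughout the analysis.
#'
#' @param seed integer master seed.
#' @param nBackground number of background genes (>= 0).
#' @param noiseSd non-negative Gaussian noise SD.
#' @param exprThreshold expression threshold (default 1.0).
#' @return a `SynthConfig` object.
#' @export
synthConfig <- function(seed = 1L, nBackground = 0L, noiseSd = 0.4,
                        exprThreshold = 1.0) {
  stopifnot(nBackground >= 0, noiseSd >= 0)
  structure(list(seed = as.integer(seed),
                 nBackground = as.integer(nBackground),
                 noiseSd = as.numeric(noiseSd),
                 exprThreshold = as.numeric(exprThreshold)),
            class = "SynthConfig")
}

#' Ordered myo-differentiation stage labels
#'
#' The five reporter-sorted stages of directed myogenic differentiation:
#' pluripotent (OCT4), presomite (MSGN1), myogenic progenitor (PAX7),
#' myoblast (MYOG) and myotube (TUB).
#'
#' @return character vector of 5 ordered stage names.
#' @export
myoStages <- function() c("OCT4", "MSGN1", "PAX7", "MYOG", "TUB")

#' Simulate a multi-tissue consensus expression (NX) table
#'
#' Emulates an HPA-style consensus atlas: each planted muscle-restricted
#' gene gets NX above the expression threshold in skeletal muscle and at
#' or below it in every other tissue; distractors are either broadly
#' expressed (muscle plus at least one other tissue) or silent in muscle.
#'
#' @param tissues ordered tissue names; must contain `muscleTissue`.
#' @param restrictedGenes genes to plant as muscle-restricted.
#' @param nDistractors number of non-restricted genes.
#' @param cfg a [synthConfig()].
#' @param muscleTissue name of the muscle column (default
#'   `"skeletal muscle"`).
#' @return an [ExprMatrix-class] of kind `"nx"`; the planted truth is in
#'   `S4Vectors::metadata(x)$truth`.
#' @export
genConsensusNX <- function(tissues, restrictedGenes, nDistractors, cfg,
                           muscleTissue = "skeletal muscle") {
  if (!muscleTissue %in% tissues)
    stop("muscle tissue '", muscleTissue, "' absent from tissues")
  if (anyDuplicated(tissues)) stop("duplicate tissue names")
  restrictedGenes <- as.character(restrictedGenes)
  distractors <- if (nDistractors > 0)
    sprintf("DIST%05d", seq_len(nDistractors)) else character()
  genes <- c(restrictedGenes, distractors)
  if (anyDuplicated(genes)) stop("duplicate gene names")
  thr <- cfg$exprThreshold
  withSeed(subSeed(cfg$seed, 101L), {
    v <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    other <- setdiff(tissues, muscleTissue)
    for (g in restrictedGenes) {
      v[g, muscleTissue] <- thr + runif(1, 1, 9)
      v[g, other] <- runif(length(other), 0, thr)
    }
    for (i in seq_along(distractors)) {
      g <- distractors[i]
      if (i %% 2L == 1L && length(other)) {      # broad: muscle + >=1 other
        v[g, muscleTissue] <- thr + runif(1, 1, 9)
        v[g, other] <- runif(length(other), 0, thr)
        extra <- other[1L + (i %/% 2L) %% length(other)]
        v[g, extra] <- thr + runif(1, 1, 9)
      } else {                                   # silent in muscle
        v[g, ] <- runif(length(tissues), 0, thr)
        v[g, muscleTissue] <- runif(1, 0, thr)
      }
    }
    out <- ExprMatrix(v, valueKind = "nx")
    S4Vectors::metadata(out)$truth <- list(restricted = restrictedGenes,
                                           muscle_tissue = muscleTissue)
    out
  })
}

#' Simulate stage-ordered expression profiles with planted onset structure
#'
#' For onset stage `k`, planted genes sit at or below the expression
#' threshold at stages before `k` and above it at every stage from `k` on.
#' Maintenance-planted genes additionally increase strictly from onset to
#' the final stage. Distractors either lapse after an expressed stage
#' (violating persistence) or are never expressed.
#'
#' @param stages ordered stage names (default [myoStages()]).
#' @param onsetCounts one count per stage of genes whose persistent
#'   expression starts there.
#' @param maintenanceOnsetCounts per-stage counts of the onset genes that
#'   are additionally monotone increasing; must be 0 for the final stage
#'   (a single-stage profile has no increasing step).
#' @param nDistractors number of persistence-violating / silent genes.
#' @param cfg a [synthConfig()].
#' @return a [StageProfiles-class]; planted truth in
#'   `S4Vectors::metadata(x)$truth`.
#' @export
genStageProfiles <- function(stages = myoStages(), onsetCounts,
                             maintenanceOnsetCounts = rep(0L, length(stages)),
                             nDistractors = 0L, cfg = synthConfig()) {
  S <- length(stages)
  stopifnot(length(onsetCounts) == S, length(maintenanceOnsetCounts) == S)
  if (any(onsetCounts < 0) || any(maintenanceOnsetCounts < 0))
    stop("counts must be non-negative")
  if (any(maintenanceOnsetCounts > onsetCounts))
    stop("maintenance counts cannot exceed onset counts")
  if (maintenanceOnsetCounts[S] > 0)
    stop("maintenance onset at the final stage is not classifiable")
  thr <- cfg$exprThreshold
  total <- sum(onsetCounts) + nDistractors
  withSeed(subSeed(cfg$seed, 202L), {
    v <- matrix(0, total, S)
    genes <- character(total)
    onset <- integer(0)
    maint <- character(0)
    row <- 0L
    for (k in seq_len(S)) {
      nk <- onsetCounts[k]
      if (nk == 0L) next
      ids <- sprintf("S%d_%05d", k, seq_len(nk))
      for (j in seq_len(nk)) {
        row <- row + 1L
        genes[row] <- ids[j]
        if (k > 1L) v[row, seq_len(k - 1L)] <- runif(k - 1L, 0, 0.8 * thr)
        if (j <= maintenanceOnsetCounts[k]) {
          # strictly increasing from onset to the final stage
          steps <- runif(S - k + 1L, 0.2, 1)
          v[row, k:S] <- thr + 0.5 + cumsum(steps)
          maint <- c(maint, ids[j])
        } else if (k < S) {
          # expressed throughout but guaranteed not strictly increasing:
          # final value sits well below the onset value
          v[row, k:S] <- thr + runif(S - k + 1L, 0.2, 4)
          v[row, k] <- thr + 2 + runif(1, 0, 2)
          v[row, S] <- thr + 0.5
        } else {
          v[row, S] <- thr + runif(1, 0.5, 5)
        }
      }
      onset <- c(onset, rep(k, nk))
    }
    if (nDistractors > 0) for (i in seq_len(nDistractors)) {
      row <- row + 1L
      genes[row] <- sprintf("DIST%05d", i)
      if (i %% 2L == 1L) {
        # lapse: expressed at stage j, silent at stage j + 1
        j <- 1L + (i %/% 2L) %% (S - 1L)
        v[row, ] <- runif(S, 0, 2 * thr)
        v[row, j] <- thr + 1 + runif(1, 0, 3)
        v[row, j + 1L] <- runif(1, 0, 0.5 * thr)
      } else {
        v[row, ] <- runif(S, 0, 0.9 * thr)
      }
    }
    rownames(v) <- genes
    colnames(v) <- stages
    out <- StageProfiles(v, stages = stages)
    S4Vectors::metadata(out)$truth <- list(
      onset = stats::setNames(onset, genes[seq_along(onset)]),
      maintenance = maint,
      onset_counts = stats::setNames(as.integer(onsetCounts), stages))
    out
  })
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Single-latent-factor model: gene `g` in module `m` is
#' `loading * f_m + noise`, with an independent standard-normal factor
#' `f_m` per sample and independent Gaussian noise of SD `cfg$noiseSd`;
#' background genes (`cfg$nBackground`) are pure noise.
#'
#' @param moduleSizes integer vector of planted module sizes.
#' @param nSamples number of samples (>= 3).
#' @param latentLoading shared factor loading in (0, 1].
#' @param cfg a [synthConfig()].
#' @return list with `matrix` (an [ExprMatrix-class]) and `labels`
#'   (named integer vector; 0 = background).
#' @export
genModuleExpression <- function(moduleSizes, nSamples, latentLoading, cfg) {
  if (nSamples < 3) stop("at least 3 samples required")
  moduleSizes <- as.integer(moduleSizes)
  if (any(moduleSizes < 0)) stop("module sizes must be non-negative")
  if (latentLoading <= 0 || latentLoading > 1)
    stop("latentLoading must be in (0, 1]")
  nMod <- sum(moduleSizes)
  nTot <- nMod + cfg$nBackground
  if (nTot < 1L) stop("module sizes exceed the available gene budget")
  withSeed(subSeed(cfg$seed, 303L), {
    labels <- integer(0)
    v <- matrix(0, nTot, nSamples)
    row <- 0L
    for (m in seq_along(moduleSizes)) {
      f <- rnorm(nSamples)
      for (j in seq_len(moduleSizes[m])) {
        row <- row + 1L
        v[row, ] <- latentLoading * f + rnorm(nSamples, 0, cfg$noiseSd)
      }
      labels <- c(labels, rep(m, moduleSizes[m]))
    }
    if (cfg$nBackground > 0) {
      for (i in seq_len(cfg$nBackground)) {
        row <- row + 1L
        v[row, ] <- rnorm(nSamples, 0, max(cfg$noiseSd, 1e-12))
      }
      labels <- c(labels, rep(0L, cfg$nBackground))
    }
    genes <- sprintf("G%05d", seq_len(nTot))
    dimnames(v) <- list(genes, sprintf("sample_%03d", seq_len(nSamples)))
    list(matrix = ExprMatrix(v, valueKind = "log2fpkm1"),
         labels = stats::setNames(labels, genes))
  })
}

#' Simulate a scored interaction graph with planted hubs
#'
#' Planted hubs are wired to exactly their target degree using non-hub
#' partners; every non-hub keeps degree < 3. Edge confidence scores are
#' sampled uniformly in `edgeScoreRange`.
#'
#' @param nNodes total node count.
#' @param hubSpec named integer vector, hub node name -> target degree.
#' @param edgeScoreRange length-2 numeric in `[0, 1]`.
#' @param cfg a [synthConfig()].
#' @return an [InteractionGraph-class] whose planted hubs are
#'   `names(hubSpec)`.
#' @export
genInteractionGraph <- function(nNodes, hubSpec = integer(),
                                edgeScoreRange = c(0.9, 1), cfg = synthConfig()) {
  stopifnot(length(edgeScoreRange) == 2L,
            all(edgeScoreRange >= 0 & edgeScoreRange <= 1))
  hubNames <- names(hubSpec)
  if (length(hubSpec) && is.null(hubNames))
    stop("hubSpec must be a named vector")
  nHub <- length(hubSpec)
  if (nHub > nNodes) stop("more hubs than nodes")
  nonHub <- sprintf("N%05d", seq_len(nNodes - nHub))
  nodes <- c(hubNames, nonHub)
  if (any(hubSpec > nNodes - 1L))
    stop("infeasible degree sequence: target degree exceeds n - 1")
  if (sum(hubSpec) > 2L * length(nonHub))
    stop("infeasible degree sequence: not enough non-hub capacity")
  withSeed(subSeed(cfg$seed, 404L), {
    cap <- stats::setNames(rep(2L, length(nonHub)), nonHub)
    ea <- character(0); eb <- character(0)
    for (h in hubNames) {
      want <- hubSpec[[h]]
      # spread over partners with the most remaining capacity, index ties
      ord <- order(-cap, seq_along(cap))
      partners <- names(cap)[ord][seq_len(want)]
      if (any(cap[partners] <= 0L))
        stop("infeasible degree sequence: not enough non-hub capacity")
      cap[partners] <- cap[partners] - 1L
      ea <- c(ea, rep(h, want)); eb <- c(eb, partners)
    }
    score <- runif(length(ea), edgeScoreRange[1L], edgeScoreRange[2L])
    InteractionGraph(data.frame(node_a = ea, node_b = eb, score = score,
                                stringsAsFactors = FALSE),
                     nodes = nodes)
  })
}

#' Simulate a DEG table with a planted reference overlap
#'
#' Produces a table that passes [filterDeg()] unchanged: exactly
#' `nOverlapUp` reference genes upregulated (fold >= 2, p < 0.05),
#' `nOverlapDown` downregulated, plus `nExtra` non-reference genes.
#'
#' @param reference a [GeneSet-class] or character vector.
#' @param nOverlapUp,nOverlapDown disjoint overlap counts (sum <= size of
#'   reference).
#' @param nExtra number of non-reference DEGs.
#' @param cfg a [synthConfig()].
#' @return a DEG data.frame (see [DegTable()]).
#' @export
genDegTable <- function(reference, nOverlapUp, nOverlapDown = 0L,
                        nExtra = 0L, cfg = synthConfig()) {
  ref <- if (is(reference, "GeneSet")) members(reference)
         else as.character(reference)
  if (nOverlapUp + nOverlapDown > length(ref))
    stop("overlap exceeds reference size")
  upGenes <- ref[seq_len(nOverlapUp)]
  downGenes <- ref[nOverlapUp + seq_len(nOverlapDown)]
  extra <- if (nExtra > 0) sprintf("XTRA%05d", seq_len(nExtra)) else character()
  extraUp <- extra[seq_along(extra) %% 2L == 1L]
  extraDown <- setdiff(extra, extraUp)
  withSeed(subSeed(cfg$seed, 505L), {
    g <- c(upGenes, extraUp, downGenes, extraDown)
    nUp <- length(upGenes) + length(extraUp)
    fc <- c(runif(nUp, 2, 8), -runif(length(g) - nUp, 2, 8))
    DegTable(g, fc, runif(length(g), 1e-4, 0.049))
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates every fixture the scoring workflow consumes -- at the study's
#' reference sizes by default -- and writes them as plain-text TSV/GMT
#' files plus a JSON ground-truth manifest.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synthConfig()].
#' @param restrictedGenes genes planted as muscle-restricted.
#' @param onsetCounts,maintenanceOnsetCounts per-stage planted counts.
#' @param nTissues total tissue count for the consensus table.
#' @return named list of the generated objects, invisibly.
#' @export
writeFixtureBundle <- function(dir, cfg = synthConfig(1),
    restrictedGenes = c("DUPD1", "KLHL38", "METTL11B", "MYH6", "MYL7",
                        "OR5H2", "OR6C70", "OR9Q1"),
    onsetCounts = c(4252L, 158L, 266L, 198L, 330L),
    maintenanceOnsetCounts = c(54L, 17L, 0L, 0L, 0L),
    nTissues = 62L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissues <- c("skeletal muscle", sprintf("tissue_%02d", seq_len(nTissues - 1L)))
  nx <- genConsensusNX(tissues, restrictedGenes, nDistractors = 500L, cfg)
  prof <- genStageProfiles(myoStages(), onsetCounts, maintenanceOnsetCounts,
                           nDistractors = 1000L, cfg)
  writeExprMatrix(nx, file.path(dir, "consensus_nx.tsv"))
  writeExprMatrix(prof, file.path(dir, "stage_profiles.tsv"))
  writeGmt(GeneSet("muscle_restricted", restrictedGenes,
                   "planted muscle-restricted signature"),
           file.path(dir, "signature.gmt"))
  truth <- S4Vectors::metadata(prof)$truth
  manifest <- list(seed = cfg$seed,
                   expr_threshold = cfg$exprThreshold,
                   restricted_genes = restrictedGenes,
                   onset_counts = as.list(truth$onset_counts),
                   maintenance_total = length(truth$maintenance))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(consensus = nx, profiles = prof))
}
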