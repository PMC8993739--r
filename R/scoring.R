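.upSet <- function(table) unique(table$gene_id[table$direction == "up"])
.downSet <- function(table) unique(table$gene_id[table$direction == "down"])

#' Common differentially expressed genes across cell types
#'
#' Intersects the up-sets and the down-sets of two or more filtered DEG
#' tables. A gene called up in one table and down in another cannot be
#' common in either direction; such conflicts are excluded and reported.
#'
#' @param tables named list (>= 2) of DEG data.frames already passed
#'   through [filterDeg()].
#' @return list with `up`, `down` ([GeneSet-class]) and `conflicted`
#'   (character).
#' @export
commonDegs <- function(tables) {
  if (length(tables) < 2L) stop("at least 2 DEG tables required")
  ups <- lapply(tables, .upSet)
  downs <- lapply(tables, .downSet)
  conflicted <- intersect(unique(unlist(ups)), unique(unlist(downs)))
  if (length(conflicted))
    message(length(conflicted),
            " gene(s) up in one cell type and down in another; excluded")
  up <- setdiff(Reduce(intersect, ups), conflicted)
  down <- setdiff(Reduce(intersect, downs), conflicted)
  list(up = GeneSet("common_up", up, "upregulated in every cell type"),
       down = GeneSet("common_down", down,
                      "downregulated in every cell type"),
       conflicted = conflicted)
}

#' Overlap of up/down DEG sets with a reference gene set
#'
#' Counts and percentages (of the reference size) of the up- and
#' downregulated genes found in the reference, with percentages rounded
#' half-away-from-zero to `pctDecimals` places -- e.g. 42 of a 116-gene
#' reference gives 36.21.
#'
#' @param up,down [GeneSet-class] or character vectors.
#' @param reference non-empty [GeneSet-class] or character vector.
#' @param pctDecimals decimal places for percentages (default 2).
#' @return list with `up_count`, `down_count`, `up_pct`, `down_pct`,
#'   `reference_size`.
#' @export
overlapStats <- function(up, down, reference, pctDecimals = 2L) {
  ref <- if (is(reference, "GeneSet")) members(reference)
         else as.character(reference)
  if (!length(ref)) stop("reference set must be non-empty")
  u <- if (is(up, "GeneSet")) members(up) else as.character(up)
  d <- if (is(down, "GeneSet")) members(down) else as.character(down)
  cu <- length(intersect(u, ref))
  cd <- length(intersect(d, ref))
  list(up_count = cu, down_count = cd,
       up_pct = roundHalfAway(100 * cu / length(ref), pctDecimals),
       down_pct = roundHalfAway(100 * cd / length(ref), pctDecimals),
       reference_size = length(ref))
}

#' Stage composition of an upregulated gene set
#'
#' For each differentiation stage, the count and percentage (relative to
#' the stage set's size) of upregulated genes belonging to that stage's
#' onset set. Empty stage sets report count 0 and `NA` percentage.
#'
#' @param up a [GeneSet-class] or character vector.
#' @param stageSets a [StageSets-class].
#' @param pctDecimals decimal places (default 2).
#' @return data.frame with columns `stage`, `set_size`, `count`, `pct`.
#' @export
stageComposition <- function(up, stageSets, pctDecimals = 2L) {
  u <- if (is(up, "GeneSet")) members(up) else as.character(up)
  stages <- stageSets@stages
  out <- data.frame(stage = stages,
                    set_size = vapply(stageSets@sets, length, integer(1)),
                    count = NA_integer_, pct = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(stages)) {
    s <- stageSets@sets[[i]]
    out$count[i] <- length(intersect(u, s))
    out$pct[i] <- if (length(s))
      roundHalfAway(100 * out$count[i] / length(s), pctDecimals)
    else NA_real_
  }
  out
}

#' Coverage of a marker signature
#'
#' Number of signature genes present in an expressed or upregulated set.
#'
#' @param expressedOrUp a [GeneSet-class] or character vector.
#' @param signature a [GeneSet-class] or character vector.
#' @return integer count.
#' @export
signatureCoverage <- function(expressedOrUp, signature) {
  e <- if (is(expressedOrUp, "GeneSet")) members(expressedOrUp)
       else as.character(expressedOrUp)
  s <- if (is(signature, "GeneSet")) members(signature)
       else as.character(signature)
  length(intersect(e, s))
}

#' Coverage of the maintenance gene set in a reference transcriptome
#'
#' @param referenceTranscriptome expressed genes of the reference tissue
#'   ([GeneSet-class] or character).
#' @param maintenance non-empty maintenance [GeneSet-class] or character
#'   vector.
#' @param pctDecimals decimal places (default 0; 61 of 71 gives 86).
#' @return list with `count` and `pct`.
#' @export
maintenanceCoverage <- function(referenceTranscriptome, maintenance,
                                pctDecimals = 0L) {
  m <- if (is(maintenance, "GeneSet")) members(maintenance)
       else as.character(maintenance)
  if (!length(m)) stop("maintenance set must be non-empty")
  r <- if (is(referenceTranscriptome, "GeneSet"))
    members(referenceTranscriptome) else as.character(referenceTranscriptome)
  cnt <- length(intersect(m, r))
  list(count = cnt, pct = roundHalfAway(100 * cnt / length(m), pctDecimals))
}

#' Build a per-cell-type maturity report
#'
#' Runs the full scoring workflow: DEG filtering, common-DEG
#' intersection (when more than one cell type is given), overlap with
#' the core GRN hubs, stage composition, signature coverage and
#' maintenance coverage, per cell type.
#'
#' The configuration is a YAML file (or equivalent nested list) with
#' sections:
#' \preformatted{
#' inputs:
#'   deg_tables: {hFB: path.tsv, hADMSC: path.tsv, ...}
#'   fold_scale: linear            # or log2
#'   grn: hubs.gmt
#'   signature: signature.gmt
#'   stage_sets: stage_sets.gmt    # one set per stage, stage order
#'   maintenance: maintenance.gmt
#'   smt_transcriptome: smt.gmt    # optional; maintenance coverage ref
#' thresholds: {p_max: 0.05, min_fold: 2}
#' scoring: {pct_decimals: 2, maintenance_pct_decimals: 0}
#' }
#'
#' @param config path to a YAML config file, or the equivalent list.
#' @return a [MaturityReport-class].
#' @export
buildMaturityReport <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  inp <- cfg$inputs
  need <- c("deg_tables", "grn", "signature", "stage_sets", "maintenance")
  miss <- need[!need %in% names(inp)]
  if (length(miss))
    stop("config missing input key(s): ", paste(miss, collapse = ", "))
  thr <- cfg$thresholds
  pMax <- if (!is.null(thr$p_max)) thr$p_max else 0.05
  minFold <- if (!is.null(thr$min_fold)) thr$min_fold else 2
  sc <- cfg$scoring
  pctDec <- if (!is.null(sc$pct_decimals)) sc$pct_decimals else 2L
  maintDec <- if (!is.null(sc$maintenance_pct_decimals))
    sc$maintenance_pct_decimals else 0L

  loadSet <- function(x, what) {
    if (is(x, "GeneSet")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      return(readGmt(x)[[1L]])
    if (is.character(x)) return(GeneSet(what, x))
    stop("cannot interpret input '", what, "'")
  }
  grn <- loadSet(inp$grn, "grn")
  signature <- loadSet(inp$signature, "signature")
  maintenance <- loadSet(inp$maintenance, "maintenance")
  stageSets <- if (is(inp$stage_sets, "StageSets")) inp$stage_sets
  else {
    sets <- readGmt(inp$stage_sets)
    StageSets(names(sets), lapply(sets, members))
  }
  smt <- if (!is.null(inp$smt_transcriptome))
    loadSet(inp$smt_transcriptome, "smt") else NULL

  foldScale <- if (!is.null(inp$fold_scale)) inp$fold_scale else "linear"
  tables <- lapply(inp$deg_tables, function(t)
    if (is.data.frame(t)) t else readDegTable(t, foldScale = foldScale))
  filtered <- lapply(tables, filterDeg, pMax = pMax, minFold = minFold)

  per <- lapply(filtered, function(tab) {
    up <- .upSet(tab); down <- .downSet(tab)
    ov <- overlapStats(up, down, grn, pctDec)
    comp <- stageComposition(up, stageSets, pctDec)
    res <- list(
      grn_up_count = ov$up_count, grn_down_count = ov$down_count,
      grn_up_pct = ov$up_pct, grn_down_pct = ov$down_pct,
      stage_composition = comp,
      signature_expressed_count = signatureCoverage(up, signature),
      maintenance_expressed_count = signatureCoverage(up, maintenance))
    res
  })
  common <- if (length(filtered) >= 2L) {
    cd <- commonDegs(filtered)
    list(up = members(cd$up), down = members(cd$down),
         up_count = length(members(cd$up)),
         down_count = length(members(cd$down)))
  } else list()
  params <- list(p_max = pMax, min_fold = minFold, pct_decimals = pctDec,
                 grn_size = length(members(grn)),
                 signature_size = length(members(signature)),
                 maintenance_size = length(members(maintenance)))
  if (!is.null(smt)) {
    mc <- maintenanceCoverage(smt, maintenance, maintDec)
    params$smt_maintenance_count <- mc$count
    params$smt_maintenance_pct <- mc$pct
  }
  new("MaturityReport", perCellType = per, common = common, params = params)
}

#' Write a maturity report as JSON and TSV
#'
#' The JSON mirrors the report structure; the TSV is flat with one row
#' per (cell type, metric). Regenerating from the same inputs yields
#' byte-identical files.
#'
#' @param report a [MaturityReport-class].
#' @param jsonPath,tsvPath output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
writeMaturityReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  stopifnot(is(report, "MaturityReport"))
  if (!is.null(jsonPath)) {
    payload <- list(per_cell_type = lapply(report@perCellType, function(p) {
      p$stage_composition <- as.list(p$stage_composition)
      p
    }), common = report@common, params = report@params)
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsvPath)) {
    rows <- do.call(rbind, lapply(names(report@perCellType), function(ct) {
      p <- report@perCellType[[ct]]
      flat <- p[!vapply(p, is.data.frame, logical(1))]
      base <- data.frame(cell_type = ct, metric = names(flat),
                         value = as.numeric(unlist(flat)),
                         stringsAsFactors = FALSE)
      comp <- p$stage_composition
      stage <- data.frame(cell_type = ct,
                          metric = c(paste0("stage_count_", comp$stage),
                                     paste0("stage_pct_", comp$stage)),
                          value = c(comp$count, comp$pct),
                          stringsAsFactors = FALSE)
      rbind(base, stage)
    }))
    utils::write.table(rows, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = jsonPath, tsv = tsvPath))
}
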