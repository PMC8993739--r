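#' Default keyword list for muscle-related GO term mining
#'
#' Keywords matched case-insensitively as substrings of GO term text to
#' pull out annotations characteristic of skeletal-muscle structure and
#' function (sarcomere organization, fiber types, contractile proteins,
#' myoblast fusion). Curation beyond these shipped defaults is the
#' user's input.
#'
#' @return character vector of keywords.
#' @export
muscleGoKeywords <- function() {
  c("skeletal muscle", "Z disk", "I band", "M band", "striated muscle",
    "sarcomere", "muscle fiber", "slow-twitch muscle fiber",
    "fast-twitch muscle fiber", "troponin", "tropomyosin",
    "transition between fast and slow fiber", "actinin",
    "myoblast fusion", "actin")
}

#' Mine a GO annotation table by term-text keywords
#'
#' A GO term matches when any keyword is a case-insensitive substring of
#' its term text (exact substring; variant spellings such as "Z disc"
#' versus "Z disk" are the caller's responsibility). Returns the matched
#' GO ids and the union of genes annotated to them.
#'
#' @param annotations data.frame with columns `gene_id`, `go_id`,
#'   `go_term`, `ontology` (see [readAnnotations()]).
#' @param keywords non-empty character vector of keywords.
#' @return list with `goIds` (character) and `genes` (a
#'   [GeneSet-class]).
#' @export
mineGoAnnotations <- function(annotations, keywords = muscleGoKeywords()) {
  if (!length(keywords)) stop("at least one keyword required")
  termLower <- tolower(annotations$go_term)
  hit <- rep(FALSE, nrow(annotations))
  for (kw in tolower(keywords))
    hit <- hit | grepl(kw, termLower, fixed = TRUE)
  matched <- annotations[hit, , drop = FALSE]
  list(goIds = unique(matched$go_id),
       genes = GeneSet("go_keyword_genes", unique(matched$gene_id),
                       sprintf("genes annotated to %d keyword-matched GO terms",
                               length(unique(matched$go_id)))))
}

#' Map genes through an ortholog table
#'
#' Table-driven one-to-one mapping (e.g. mouse symbols to approved human
#' orthologs). Targets are deduplicated; sources without a mapping are
#' logged in input order.
#'
#' @param genes a [GeneSet-class] or character vector of source genes.
#' @param map data.frame with columns `source_gene`, `target_gene`
#'   (NA = unmapped; see [readOrthologMap()]).
#' @return list with `mapped` (a [GeneSet-class] of targets), `unmapped`
#'   (source genes without a target, input order), and `collapsed`
#'   (targets hit by more than one source).
#' @export
mapOrthologs <- function(genes, map) {
  src <- if (is(genes, "GeneSet")) members(genes) else as.character(genes)
  tgt <- map$target_gene[match(src, map$source_gene)]
  unmapped <- src[is.na(tgt)]
  mappedTargets <- tgt[!is.na(tgt)]
  dup <- unique(mappedTargets[duplicated(mappedTargets)])
  if (length(dup))
    message(length(dup), " target(s) hit by multiple sources; counted once")
  list(mapped = GeneSet("orthologs", unique(mappedTargets),
                        "approved orthologs of the input genes"),
       unmapped = unmapped, collapsed = dup)
}

#' Derive a tissue-restricted expression signature
#'
#' Genes expressed strictly above `exprThreshold` in the target tissue
#' and at or below it in every other tissue of a consensus NX atlas.
#'
#' @param consensus an [ExprMatrix-class] of kind `"nx"`, tissues in
#'   columns.
#' @param targetTissue tissue column to restrict to (default
#'   `"skeletal muscle"`).
#' @param exprThreshold expression cutoff (strict in the target tissue;
#'   default 1.0, the NX > 1 convention).
#' @return a [GeneSet-class].
#' @export
restrictedSignature <- function(consensus, targetTissue = "skeletal muscle",
                                exprThreshold = 1.0) {
  stopifnot(is(consensus, "ExprMatrix"))
  v <- exprValues(consensus)
  if (!targetTissue %in% colnames(v))
    stop("target tissue '", targetTissue, "' absent")
  other <- setdiff(colnames(v), targetTissue)
  inTarget <- v[, targetTissue] > exprThreshold
  elsewhere <- if (length(other))
    apply(v[, other, drop = FALSE] > exprThreshold, 1L, any)
  else rep(FALSE, nrow(v))
  GeneSet("restricted_signature", rownames(v)[inTarget & !elsewhere],
          sprintf("genes with NX > %g in %s only", exprThreshold,
                  targetTissue))
}

#' Partition genes by persistent expression-onset stage
#'
#' A gene has onset stage `k` iff its expression is at or below
#' `exprThreshold` at every stage before `k` and strictly above it at
#' every stage from `k` on. Genes that are never expressed, or whose
#' expression lapses after onset, are excluded; the output is a disjoint
#' partition of the included genes.
#'
#' @param profiles a [StageProfiles-class].
#' @param exprThreshold expression cutoff (default 1.0).
#' @return a [StageSets-class].
#' @export
stageOnsetSets <- function(profiles, exprThreshold = 1.0) {
  stopifnot(is(profiles, "StageProfiles"))
  v <- exprValues(profiles)
  stages <- colnames(v)
  S <- length(stages)
  expressed <- v > exprThreshold
  onset <- apply(expressed, 1L, function(e) {
    k <- which(e)[1L]
    if (is.na(k)) return(NA_integer_)
    if (all(e[k:S])) k else NA_integer_
  })
  sets <- lapply(seq_len(S), function(k) rownames(v)[!is.na(onset) & onset == k])
  StageSets(stages, sets)
}

#' Identify maintenance genes with monotonically increasing expression
#'
#' Among persistently expressed genes (see [stageOnsetSets()]), those
#' whose stage means increase strictly from onset to the final stage,
#' each step exceeding `minRelIncrease` times the previous value. A gene
#' whose onset is the final stage has no step to evaluate and is
#' excluded. The increasing trend toward the differentiated stage marks
#' genes supporting maintenance of the muscle phenotype.
#'
#' @param profiles a [StageProfiles-class].
#' @param exprThreshold expression cutoff (default 1.0).
#' @param minRelIncrease minimum relative per-step increase (default 0,
#'   i.e. strict increase).
#' @return list with `genes` (a [GeneSet-class]) and `breakdown`
#'   (named integer vector of counts per onset stage).
#' @export
maintenanceGenes <- function(profiles, exprThreshold = 1.0,
                             minRelIncrease = 0.0) {
  onset <- stageOnsetSets(profiles, exprThreshold)
  v <- exprValues(profiles)
  S <- ncol(v)
  stages <- colnames(v)
  keep <- character(0)
  breakdown <- stats::setNames(integer(S), stages)
  for (k in seq_len(S)) {
    for (g in onset@sets[[k]]) {
      if (k >= S) next                      # no post-onset step to assess
      seq_ <- v[g, k:S]
      inc <- diff(seq_) > minRelIncrease * seq_[-length(seq_)] &
             diff(seq_) > 0
      if (all(inc)) {
        keep <- c(keep, g)
        breakdown[k] <- breakdown[k] + 1L
      }
    }
  }
  list(genes = GeneSet("maintenance_genes", keep,
                       "persistently expressed genes increasing toward the final stage"),
       breakdown = breakdown)
}

#' Label-unique members among candidate genes
#'
#' For each labeled set, returns its intersection with the candidate
#' list minus the union of all other labels' sets -- e.g. channel genes
#' upregulated in exactly one cell type.
#'
#' @param sets named list (>= 2) of [GeneSet-class] or character
#'   vectors, one per label.
#' @param candidates a [GeneSet-class] or character vector.
#' @return named list of [GeneSet-class], one per label.
#' @export
uniqueUpregulated <- function(sets, candidates) {
  if (length(sets) < 2L) stop("at least 2 labeled sets required")
  mem <- lapply(sets, function(s)
    if (is(s, "GeneSet")) members(s) else as.character(s))
  cand <- if (is(candidates, "GeneSet")) members(candidates)
          else as.character(candidates)
  out <- lapply(names(mem), function(lab) {
    others <- unique(unlist(mem[setdiff(names(mem), lab)]))
    GeneSet(paste0("unique_", lab),
            setdiff(intersect(mem[[lab]], cand), others))
  })
  stats::setNames(out, names(mem))
}

#' Write stage-onset and maintenance calls as a per-gene table
#'
#' @param stageSets a [StageSets-class].
#' @param maintenance a [GeneSet-class] of maintenance genes.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeStageTable <- function(stageSets, maintenance, path) {
  rows <- do.call(rbind, lapply(stageSets@stages, function(st)
    if (length(stageSets@sets[[st]]))
      data.frame(gene_id = stageSets@sets[[st]], onset_stage = st,
                 stringsAsFactors = FALSE)
    else NULL))
  if (is.null(rows))
    rows <- data.frame(gene_id = character(), onset_stage = character())
  rows$maintenance <- rows$gene_id %in% members(maintenance)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
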