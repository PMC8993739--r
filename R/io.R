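#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and gene
#' ids in the first column. Missing values may be encoded as an empty cell
#' or `NA`. Malformed input is rejected with the offending row/column
#' named, never silently coerced.
#'
#' @param path file path.
#' @param valueKind declared value kind (`"counts"`, `"fpkm"`,
#'   `"log2fpkm1"`, `"nx"`).
#' @param geneLengths optional named vector of transcript lengths (bp).
#' @return an [ExprMatrix-class].
#' @export
readExprMatrix <- function(path, valueKind = c("counts", "fpkm", "log2fpkm1", "nx"),
                           geneLengths = NULL) {
  valueKind <- match.arg(valueKind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncols <- length(header)
  samples <- trimws(header[-1L])
  rows <- fields[-1L]
  genes <- character(length(rows))
  values <- matrix(NA_real_, length(rows), ncols - 1L)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncols)
      stop(sprintf("ragged row %d: expected %d fields, found %d",
                   i + 1L, ncols, length(r)))
    genes[i] <- trimws(r[1L])
    cells <- r[-1L]
    blank <- !nzchar(trimws(cells)) | trimws(cells) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !blank)
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                   i + 1L, genes[i], samples[bad[1L]]))
    num[blank] <- NA_real_
    values[i, ] <- num
  }
  if (anyDuplicated(genes))
    stop("duplicate gene id: '", genes[duplicated(genes)][1L], "'")
  if (anyDuplicated(samples))
    stop("duplicate sample id: '", samples[duplicated(samples)][1L], "'")
  dimnames(values) <- list(genes, samples)
  ExprMatrix(values, valueKind = valueKind, geneLengths = geneLengths)
}

#' Write an expression matrix as TSV
#'
#' Writes with full precision (format `%.17g`) so a write/read round trip
#' reproduces values exactly.
#'
#' @param x an [ExprMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExprMatrix <- function(x, path) {
  v <- exprValues(x)
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               cells <- ifelse(is.na(v[i, ]), "NA", sprintf("%.17g", v[i, ]))
               paste(c(rownames(v)[i], cells), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' GMT v1: one set per line, tab-separated `name`, `description`, then
#' members. Duplicate members within a line are removed with a warning;
#' lines with fewer than 3 fields are rejected.
#'
#' @param path file path.
#' @return `readGmt`: a list of [GeneSet-class]; `writeGmt`: `path`,
#'   invisibly.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields; at least 3 required",
                   i, length(f)))
    GeneSet(f[1L], f[-(1:2)], description = f[2L])
  })
  names(sets) <- vapply(sets, setName, character(1))
  sets
}

#' @rdname readGmt
#' @param sets a list of [GeneSet-class] (or a single one).
#' @export
writeGmt <- function(sets, path) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s@name, s@description, s@members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a differential-expression table
#'
#' Fold changes are stored signed on the linear scale: `+4` means 4-fold
#' up, `-2.5` means 2.5-fold down; `|fold_change|` is the linear fold and
#' the `direction` column is derived from the sign. Microarray exports
#' that report log2 fold changes can be read with `foldScale = "log2"`,
#' which converts `lfc` to `sign(lfc) * 2^|lfc|`.
#'
#' @param gene_id character vector of gene ids.
#' @param fold_change signed numeric fold changes.
#' @param p_value p-values in `[0, 1]`.
#' @param foldScale `"linear"` (default) or `"log2"`.
#' @return data.frame with columns `gene_id`, `fold_change`, `p_value`,
#'   `direction`.
#' @export
DegTable <- function(gene_id, fold_change, p_value,
                     foldScale = c("linear", "log2")) {
  foldScale <- match.arg(foldScale)
  fold_change <- as.numeric(fold_change)
  if (foldScale == "log2")
    fold_change <- sign(fold_change) * 2^abs(fold_change)
  p_value <- as.numeric(p_value)
  if (any(is.na(p_value)) || any(p_value < 0 | p_value > 1))
    stop("p_value must be in [0, 1]")
  if (any(!is.finite(fold_change)))
    stop("fold_change must be finite")
  data.frame(gene_id = as.character(gene_id),
             fold_change = fold_change,
             p_value = p_value,
             direction = ifelse(fold_change >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Read / write DEG tables as TSV
#'
#' Requires columns `gene_id`, `fold_change`, `p_value`.
#'
#' @param path file path.
#' @param foldScale scale of the `fold_change` column (see [DegTable()]).
#' @return `readDegTable`: a DEG data.frame; `writeDegTable`: `path`,
#'   invisibly.
#' @export
readDegTable <- function(path, foldScale = c("linear", "log2")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "fold_change", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "))
  DegTable(df$gene_id, df$fold_change, df$p_value, foldScale = foldScale)
}

#' @rdname readDegTable
#' @param table a DEG data.frame.
#' @export
writeDegTable <- function(table, path) {
  utils::write.table(table[, c("gene_id", "fold_change", "p_value", "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert raw counts to FPKM
#'
#' `fpkm[g,s] = counts[g,s] * 1e9 / (length[g] * libsize[s])`, with the
#' library size taken as the column sum of counts over the genes present
#' in the matrix.
#'
#' @param x an [ExprMatrix-class] with `valueKind == "counts"` and gene
#'   lengths for every gene.
#' @return an [ExprMatrix-class] with `valueKind == "fpkm"`.
#' @export
countsToFpkm <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  if (valueKind(x) != "counts") stop("input must be of kind 'counts'")
  gl <- geneLengths(x)
  if (is.null(gl)) stop("gene lengths required for FPKM conversion")
  miss <- rownames(x)[is.na(gl)]
  if (length(miss))
    stop("missing gene length for gene '", miss[1L], "'")
  v <- exprValues(x)
  lib <- colSums(v)
  zero <- colnames(v)[lib <= 0]
  if (length(zero))
    stop("zero library size for sample '", zero[1L], "'")
  fpkm <- v * 1e9 / outer(as.numeric(gl), lib)
  ExprMatrix(fpkm, valueKind = "fpkm", geneLengths = gl)
}

#' Elementwise log2(x + 1) transform
#'
#' @param x an [ExprMatrix-class] with non-negative values (FPKM scale).
#' @return an [ExprMatrix-class] with `valueKind == "log2fpkm1"`.
#' @export
log2Plus1 <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  v <- exprValues(x)
  if (any(v < 0, na.rm = TRUE)) stop("negative values not allowed")
  ExprMatrix(log2(v + 1), valueKind = "log2fpkm1", geneLengths = geneLengths(x))
}

#' Filter a DEG table on significance and fold change
#'
#' Keeps rows with `p_value < pMax` (strict) and `|fold_change| >= minFold`
#' (inclusive), preserving the up/down partition. Idempotent; the output is
#' always a subset of the input.
#'
#' @param table a DEG data.frame (see [DegTable()]).
#' @param pMax p-value cutoff (strict; default 0.05).
#' @param minFold minimum absolute linear fold change (inclusive; default 2).
#' @return the filtered DEG data.frame.
#' @export
filterDeg <- function(table, pMax = 0.05, minFold = 2) {
  keep <- table$p_value < pMax & abs(table$fold_change) >= minFold
  table[keep, , drop = FALSE]
}

#' Iteratively remove uninformative genes and samples
#'
#' Alternates two passes until a fixed point: drop genes with zero variance
#' (over non-missing values) or more than `maxMissingFrac` missing entries,
#' then drop samples with more than `maxMissingFrac` missing entries.
#' Removals are logged in order.
#'
#' @param x an [ExprMatrix-class].
#' @param maxMissingFrac maximum tolerated missing fraction (default 0.5).
#' @return list with `matrix` (the filtered [ExprMatrix-class]) and
#'   `removed` (data.frame: `what`, `id`, `reason`, `iteration`).
#' @export
goodSamplesGenes <- function(x, maxMissingFrac = 0.5) {
  stopifnot(is(x, "ExprMatrix"))
  v <- exprValues(x)
  log <- data.frame(what = character(), id = character(),
                    reason = character(), iteration = integer(),
                    stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    if (nrow(v)) {
      missFrac <- rowMeans(is.na(v))
      vari <- apply(v, 1L, function(r) {
        r <- r[!is.na(r)]
        if (length(r) < 2L) 0 else stats::sd(r)
      })
      badGene <- missFrac > maxMissingFrac | vari == 0
      if (any(badGene)) {
        reason <- ifelse(missFrac[badGene] > maxMissingFrac,
                         "missing", "zero variance")
        log <- rbind(log, data.frame(what = "gene",
                                     id = rownames(v)[badGene],
                                     reason = reason, iteration = iter,
                                     stringsAsFactors = FALSE))
        v <- v[!badGene, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (nrow(v) == 0L) stop("no informative genes")
    if (ncol(v)) {
      sMiss <- colMeans(is.na(v))
      badSample <- sMiss > maxMissingFrac
      if (any(badSample)) {
        log <- rbind(log, data.frame(what = "sample",
                                     id = colnames(v)[badSample],
                                     reason = "missing", iteration = iter,
                                     stringsAsFactors = FALSE))
        v <- v[, !badSample, drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  gl <- geneLengths(x)
  list(matrix = ExprMatrix(v, valueKind = valueKind(x),
                           geneLengths = if (is.null(gl)) NULL
                                         else gl[rownames(v)]),
       removed = log)
}

#' Read / write interaction edge lists
#'
#' TSV with columns `node_a`, `node_b`, `score` (also accepts the
#' STRING-export header `protein1`, `protein2`, `combined_score`).
#' STRING-style integer scores on the 0--1000 scale are divided by 1000
#' when `scale1000 = TRUE`.
#'
#' @param path file path.
#' @param scale1000 divide scores by 1000 (default FALSE).
#' @param nodes optional explicit node universe (adds isolated nodes).
#' @return `readEdgeList`: an [InteractionGraph-class]; `writeEdgeList`:
#'   `path`, invisibly.
#' @export
readEdgeList <- function(path, scale1000 = FALSE, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  alias <- c(protein1 = "node_a", protein2 = "node_b",
             combined_score = "score")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  need <- c("node_a", "node_b", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("edge list missing column(s): ", paste(miss, collapse = ", "))
  if (scale1000) df$score <- df$score / 1000
  InteractionGraph(df[, need], nodes = nodes)
}

#' @rdname readEdgeList
#' @param graph an [InteractionGraph-class].
#' @export
writeEdgeList <- function(graph, path) {
  utils::write.table(graphEdges(graph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GO annotation table
#'
#' Flat annotation rows `(gene_id, go_id, go_term, ontology)`. The default
#' expects those column names in a TSV; `format = "gaf"` reads GAF 2.x
#' column positions (gene symbol in column 3, GO id in column 5, aspect in
#' column 9) -- GAF carries no term text, so `go_term` is empty there
#' unless supplied via a separate term map.
#'
#' @param path file path.
#' @param format `"tsv"` (named columns) or `"gaf"`.
#' @return data.frame with columns `gene_id`, `go_id`, `go_term`,
#'   `ontology`, fully duplicated rows removed.
#' @export
readAnnotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "go_id", "go_term", "ontology")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("annotation table missing column(s): ",
           paste(miss, collapse = ", "))
    df <- df[, need]
  } else {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "!",
                             stringsAsFactors = FALSE)
    aspect <- c(P = "BP", C = "CC", F = "MF")
    df <- data.frame(gene_id = raw[[3L]], go_id = raw[[5L]],
                     go_term = "", ontology = unname(aspect[raw[[9L]]]),
                     stringsAsFactors = FALSE)
  }
  bad <- !grepl("^GO:\\d{7}$", df$go_id)
  if (any(bad))
    stop("malformed GO id: '", df$go_id[bad][1L], "'")
  unique(df)
}

#' Read a two-column ortholog mapping table
#'
#' Columns `source_gene`, `target_gene`; an empty or `"unmapped"` target
#' marks a source with no approved ortholog. Source genes must be unique.
#'
#' @param path file path.
#' @return data.frame with columns `source_gene`, `target_gene` (NA where
#'   unmapped).
#' @export
readOrthologMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_gene", "target_gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ortholog map missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$source_gene))
    stop("duplicate source gene: '",
         df$source_gene[duplicated(df$source_gene)][1L], "'")
  df$target_gene[!nzchar(trimws(df$target_gene)) |
                 df$target_gene == "unmapped"] <- NA_character_
  df[, need]
}
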