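## Readers and writers for the package's tabular interfaces. Everything is
## plain TSV; trees are newick with supports as internal-node labels.

.readCountTSV <- function(path, idName) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus samples")
  ids <- as.character(df[[1L]])
  raw <- as.matrix(df[, -1L, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw),
                               dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(m) | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer cell in ", path, ": ", idName, " '",
         ids[bad[1L, 1L]], "', sample '", colnames(m)[bad[1L, 2L]],
         "' (value ", raw[bad[1L, 1L], bad[1L, 2L]], ")")
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a community table with sample metadata
#'
#' The table is TSV with taxon rows and sample columns (first column = taxon
#' id, integer cells); the metadata TSV is keyed by a `sample` column and
#' typically carries `core`, `year`, `layer`, `depth_top_mm`,
#' `depth_bottom_mm`. Taxa with zero counts in every sample are dropped (the
#' number is reported via `message`). Non-integer cells and samples missing
#' from the metadata are errors.
#'
#' @param path path to the count TSV.
#' @param metadataPath path to the sample-metadata TSV.
#' @param treePath optional newick file; tips must cover the taxa.
#' @param taxonomyPath optional TSV with columns taxon id, lineage.
#' @return a \linkS4class{MatCommunity}.
#' @export
readCommunityTable <- function(path, metadataPath, treePath = NULL,
                               taxonomyPath = NULL) {
  m <- .readCountTSV(path, "taxon")
  allZero <- rowSums(m) == 0
  if (any(allZero)) {
    message("dropping ", sum(allZero), " taxa absent from all samples")
    m <- m[!allZero, , drop = FALSE]
  }
  md <- read.delim(metadataPath, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(md))
    stop("metadata needs a 'sample' column")
  rownames(md) <- md$sample
  md$sample <- NULL
  missing <- setdiff(colnames(m), rownames(md))
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  tree <- if (!is.null(treePath)) readNewick(file = treePath) else NULL
  if (!is.null(tree)) tree <- pruneToTips(tree, rownames(m))
  lineage <- NULL
  if (!is.null(taxonomyPath)) {
    tx <- read.delim(taxonomyPath, stringsAsFactors = FALSE)
    lineage <- setNames(as.character(tx[[2L]]), as.character(tx[[1L]]))
  }
  MatCommunity(m, md, lineage = lineage, tree = tree)
}

#' Read an ortholog trait table
#'
#' TSV with ortholog-group rows and sample columns, plus an optional
#' group-to-category map. `exclude` drops groups by id (e.g. an upstream
#' hypothetical-protein exclusion list). Annotation provenance thresholds
#' applied upstream of this package (e-value, minimum alignment length) can
#' be recorded for the run manifest; they change nothing here.
#'
#' @param path count TSV (first column group id).
#' @param categoryPath optional TSV with columns group, category.
#' @param namespace ortholog namespace ("KO", "COG", "NOG").
#' @param exclude character vector of group ids to drop.
#' @param evalueThreshold,minAlignLength optional provenance fields.
#' @return a \linkS4class{TraitExperiment}.
#' @export
readTraitTable <- function(path, categoryPath = NULL, namespace = "KO",
                           exclude = NULL, evalueThreshold = NULL,
                           minAlignLength = NULL) {
  m <- .readCountTSV(path, "group")
  if (length(exclude)) m <- m[!rownames(m) %in% exclude, , drop = FALSE]
  cm <- if (!is.null(categoryPath)) {
    x <- read.delim(categoryPath, stringsAsFactors = FALSE)
    colnames(x)[1:2] <- c("group", "category")
    x[x$group %in% rownames(m), , drop = FALSE]
  } else NULL
  tt <- TraitExperiment(m, categoryMap = cm, namespace = namespace)
  S4Vectors::metadata(tt)$provenance <-
    list(evalue_threshold = evalueThreshold,
         min_align_length = minAlignLength, excluded = length(exclude))
  tt
}

## provenance-headed TSV writer used by the pipeline
.writeOutput <- function(df, path, hash, seed, rowNames = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# matdiversity output; config_hash=%s; seed=%d",
                     hash, as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = rowNames)
  invisible(path)
}

#' Write a labelled distance matrix as TSV
#'
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @param phylip also write a square PHYLIP-style copy alongside
#'   (`<path>.phylip`).
#' @return the path, invisibly.
#' @export
writeDistanceMatrix <- function(d, path, phylip = FALSE) {
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (phylip) {
    con <- file(paste0(path, ".phylip"), "w")
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i],
                         sprintf("%.6f", d[i, ])), collapse = "  "), con)
    close(con)
  }
  invisible(path)
}
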