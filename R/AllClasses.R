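#' MatCommunity: a taxa-by-sample count table with tree and taxonomy
#'
#' S4 container for a layered-community survey: an integer count matrix
#' (taxa in rows, samples in columns) stored as a
#' \linkS4class{SummarizedExperiment} assay named `"counts"`, per-sample
#' metadata (`core`, `year`, `layer`, `depth_top_mm`, `depth_bottom_mm`) in
#' `colData`, per-taxon lineage strings in `rowData$lineage`, and an optional
#' rooted `ape::phylo` tree whose tip set covers the taxa.
#'
#' Depth intervals are half-open `[depth_top_mm, depth_bottom_mm)` so adjacent
#' layers never overlap.
#'
#' @slot tree an `ape::phylo` object or `NULL`.
#' @exportClass MatCommunity
setClass("MatCommunity",
  contains = "SummarizedExperiment",
  slots = c(tree = "ANY"),
  prototype = prototype(tree = NULL)
)

setValidity("MatCommunity", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be present and unique")
  if (!is.null(object@tree)) {
    if (!inherits(object@tree, "phylo"))
      msg <- c(msg, "tree must be an ape 'phylo' object")
    else {
      missing <- setdiff(rownames(object), object@tree$tip.label)
      if (length(missing))
        msg <- c(msg, paste0(length(missing),
                             " taxa absent from tree tips (e.g. ",
                             missing[1L], ")"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MatCommunity
#'
#' @param counts integer matrix, taxa in rows, samples in columns; both
#'   dimensions named.
#' @param sampleData data.frame of per-sample metadata keyed by sample id
#'   (rownames or a `sample` column); typically `core`, `year`, `layer`,
#'   `depth_top_mm`, `depth_bottom_mm`.
#' @param lineage optional character vector of semicolon-delimited lineage
#'   strings, named by taxon id.
#' @param tree optional rooted `ape::phylo` whose tips cover the taxa.
#' @return a \linkS4class{MatCommunity}.
#' @examples
#' cnt <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'               dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' md <- data.frame(row.names = c("S1", "S2"), core = "OM-10", year = 2010,
#'                  layer = c("green", "pink"),
#'                  depth_top_mm = c(0, 2), depth_bottom_mm = c(2, 5))
#' MatCommunity(cnt, md)
#' @export
MatCommunity <- function(counts, sampleData = NULL, lineage = NULL,
                         tree = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- as.data.frame(sampleData)
    if (!is.null(sampleData$sample) &&
        !identical(rownames(sampleData), sampleData$sample)) {
      rownames(sampleData) <- sampleData$sample
      sampleData$sample <- NULL
    }
    missing <- setdiff(colnames(counts), rownames(sampleData))
    if (length(missing))
      stop("sample metadata missing for: ", paste(missing, collapse = ", "))
    sampleData <- S4Vectors::DataFrame(sampleData[colnames(counts), ,
                                                  drop = FALSE])
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(lineage)) rd$lineage <- unname(lineage[rownames(counts)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData, rowData = rd)
  new("MatCommunity", se, tree = tree)
}

#' TraitExperiment: ortholog-group instance counts per sample
#'
#' S4 container for gene-centric trait data: an integer matrix of
#' ortholog-group instance counts (groups in rows, samples in columns) with a
#' namespace tag (`"KO"`, `"COG"` or `"NOG"`) and a many-to-many group-to-
#' category map (a group may belong to several functional categories).
#'
#' @slot namespace single string, the ortholog database the groups come from.
#' @slot categoryMap data.frame with columns `group` and `category`.
#' @exportClass TraitExperiment
setClass("TraitExperiment",
  contains = "SummarizedExperiment",
  slots = c(namespace = "character", categoryMap = "data.frame")
)

setValidity("TraitExperiment", function(object) {
  msg <- character()
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@namespace) != 1L)
    msg <- c(msg, "namespace must be a single string")
  cm <- object@categoryMap
  if (nrow(cm)) {
    if (!all(c("group", "category") %in% colnames(cm)))
      msg <- c(msg, "categoryMap needs 'group' and 'category' columns")
    else if (!all(cm$group %in% rownames(object)))
      msg <- c(msg, "categoryMap refers to unknown groups")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TraitExperiment
#'
#' @param counts integer matrix, ortholog groups in rows, samples in columns.
#' @param categoryMap data.frame with columns `group`, `category`; optional.
#' @param namespace one of "KO", "COG", "NOG" (free-form accepted).
#' @param sampleData optional per-sample metadata data.frame.
#' @return a \linkS4class{TraitExperiment}.
#' @export
TraitExperiment <- function(counts, categoryMap = NULL, namespace = "KO",
                            sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(categoryMap))
    categoryMap <- data.frame(group = character(), category = character())
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(as.data.frame(sampleData)[colnames(counts), ,
                                                            drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("TraitExperiment", se, namespace = namespace,
      categoryMap = as.data.frame(categoryMap))
}

#' HistoricalDecomposition: branch-level decomposition of a community
#'
#' The phylogenetic Hill number is computed over "historical species" (i, b):
#' extant taxon i paired with branch b on its root-to-tip path. This class
#' stores the per-branch quantities that the diversity equation needs:
#' branch lengths l_b, descendant-tip index sets I_b, per-tip root-to-tip
#' depths T_i, branch abundances a_b = sum of p_j over j in I_b, and the
#' historical-abundance mass c_b = l_b * sum_{i in I_b} p_i / T_i
#' (the sum over i of pi_(i,b) = l_b p_i / T_i). The masses c_b sum to 1.
#'
#' @slot branchLengths numeric, l_b per branch (tree edge).
#' @slot branchTips list of integer vectors, tip indices below each branch.
#' @slot tipDepths numeric, T_i per tip (named).
#' @slot branchAbundance numeric, a_b per branch.
#' @slot branchMass numeric, c_b per branch.
#' @slot abundance numeric, the input relative abundances (named by tip).
#' @exportClass HistoricalDecomposition
setClass("HistoricalDecomposition",
  slots = c(branchLengths = "numeric", branchTips = "list",
            tipDepths = "numeric", branchAbundance = "numeric",
            branchMass = "numeric", abundance = "numeric")
)

setValidity("HistoricalDecomposition", function(object) {
  n <- length(object@branchLengths)
  if (length(object@branchTips) != n || length(object@branchAbundance) != n ||
      length(object@branchMass) != n)
    return("branch-level slots must have equal length")
  if (abs(sum(object@branchMass) - 1) > 1e-8)
    return("historical abundances must sum to 1")
  TRUE
})
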