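#' Accessors for MatCommunity and TraitExperiment
#'
#' `counts` returns the integer count assay; `communityTree` the phylogeny
#' (or NULL); `taxonomyLineage` the per-taxon lineage strings; `sampleData`
#' the per-sample metadata as a data.frame; `sampleDepths` the per-sample
#' count totals; `categoryMap` and `namespace` the trait-table annotation.
#'
#' @param object a \linkS4class{MatCommunity} or \linkS4class{TraitExperiment}.
#' @param value replacement value.
#' @name accessors
#' @aliases counts,MatCommunity-method counts,TraitExperiment-method
NULL

#' @rdname accessors
#' @export
setGeneric("communityTree", function(object) standardGeneric("communityTree"))

#' @rdname accessors
#' @export
setGeneric("communityTree<-",
           function(object, value) standardGeneric("communityTree<-"))

#' @rdname accessors
#' @export
setGeneric("taxonomyLineage",
           function(object) standardGeneric("taxonomyLineage"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(object) standardGeneric("sampleDepths"))

#' @rdname accessors
#' @export
setGeneric("categoryMap", function(object) standardGeneric("categoryMap"))

#' @rdname accessors
#' @export
setGeneric("namespace", function(object) standardGeneric("namespace"))

#' @rdname accessors
#' @export
setMethod("counts", "MatCommunity", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("counts", "TraitExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("communityTree", "MatCommunity", function(object) object@tree)

#' @rdname accessors
#' @export
setMethod("communityTree<-", "MatCommunity", function(object, value) {
  object@tree <- value
  validObject(object)
  object
})

#' @rdname accessors
#' @export
setMethod("taxonomyLineage", "MatCommunity", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"lineage" %in% colnames(rd)) return(NULL)
  setNames(rd$lineage, rownames(object))
})

#' @rdname accessors
#' @export
setMethod("sampleData", "MatCommunity", function(object) {
  as.data.frame(SummarizedExperiment::colData(object))
})

#' @rdname accessors
#' @export
setMethod("sampleDepths", "MatCommunity", function(object) {
  colSums(counts(object))
})

#' @rdname accessors
#' @export
setMethod("categoryMap", "TraitExperiment", function(object) object@categoryMap)

#' @rdname accessors
#' @export
setMethod("namespace", "TraitExperiment", function(object) object@namespace)

setMethod("show", "MatCommunity", function(object) {
  m <- counts(object)
  cat("MatCommunity:", nrow(m), "taxa x", ncol(m), "samples\n")
  cat("  total counts:", sum(m), " (per-sample range ",
      paste(range(colSums(m)), collapse = "-"), ")\n", sep = "")
  if (!is.null(object@tree))
    cat("  tree:", ape::Ntip(object@tree), "tips,",
        if (is.null(object@tree$node.label)) "no" else "with",
        "support labels\n")
  else cat("  tree: none\n")
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  sample metadata:", paste(cd, collapse = ", "), "\n")
})

setMethod("show", "TraitExperiment", function(object) {
  m <- counts(object)
  cat("TraitExperiment [", object@namespace, "]: ", nrow(m), " groups x ",
      ncol(m), " samples, ", sum(m), " instances\n", sep = "")
  if (nrow(object@categoryMap))
    cat("  categories:",
        paste(unique(object@categoryMap$category), collapse = ", "), "\n")
})
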