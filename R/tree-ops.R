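## Tree ingestion and manipulation: newick I/O with support labels,
## cophenetic distances, support-threshold polytomy collapsing, clade
## pruning, and the historical-species branch decomposition.

#' Read a rooted newick tree with support values
#'
#' Internal-node labels that parse as numbers are interpreted as bootstrap-like
#' support values on [0, 100] (the FastTree support-as-label dialect).
#' Unrooted input is rejected unless `midpointRoot = TRUE`, in which case it is
#' midpoint-rooted (the single supported fallback).
#'
#' @param text newick string, or NULL to read from `file`.
#' @param file path to a newick file.
#' @param midpointRoot midpoint-root unrooted input instead of failing.
#' @return an `ape::phylo` object.
#' @export
readNewick <- function(text = NULL, file = NULL, midpointRoot = FALSE) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed newick: ", conditionMessage(w)))
  if (is.null(tr)) stop("malformed newick: no tree parsed")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tr)) {
    if (!midpointRoot) stop("tree is unrooted; set midpointRoot = TRUE ",
                            "to midpoint-root it")
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("midpoint rooting requires the 'phangorn' package")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Write a tree as newick with supports as internal-node labels
#'
#' @param tree an `ape::phylo`.
#' @param file optional output path; when NULL the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the newick string, invisibly when written to file.
#' @export
writeNewick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Numeric support values per internal node
#'
#' Node labels that do not parse as numbers (including empty labels) are
#' treated as full support (100): such nodes are never collapsed.
#'
#' @param tree an `ape::phylo`.
#' @return numeric vector of length `Nnode(tree)`.
#' @export
nodeSupports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(100, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  sup[is.na(sup)] <- 100
  sup
}

#' Cophenetic (path-length) distance matrix
#'
#' d(i, j) is the sum of branch lengths on the path between tips i and j.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames, zero diagonal.
#' @export
copheneticDistances <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Root-to-tip depths
#'
#' T_i, the sum of branch lengths from the root to tip i. Non-ultrametric
#' trees are fully supported: depths are per tip, not global.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return named numeric vector over tips.
#' @export
tipDepths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_len(ape::Ntip(tree))], tree$tip.label)
}

## children list and per-node parent/edge-length lookup, in node-id space
## (tips 1..n, internals n+1..n+Nnode, root n+1 under cladewise order).
.nodeTables <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  parent <- integer(n + nn)
  plen <- numeric(n + nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  list(n = n, nn = nn, root = n + 1L, parent = parent, plen = plen)
}

#' Collapse poorly supported bifurcations into polytomies
#'
#' Every internal non-root node whose support value is below
#' `thresholdPercent` is deleted and its children are attached to its parent,
#' with the deleted branch's length added to each child's branch. This keeps
#' every root-to-tip depth T_i (and hence the historical-species abundances of
#' the diversity equation) exactly unchanged; only the topology, and with it
#' the cophenetic distances, is perturbed. Nodes without a numeric support are
#' never collapsed, nor is the root. A threshold of 0 is the identity.
#'
#' @param tree an `ape::phylo` with branch lengths and support node labels.
#' @param thresholdPercent support threshold in [0, 100]; nodes with
#'   support strictly below it are collapsed (the study design uses 50 and 80).
#' @return an `ape::phylo`, possibly multifurcating.
#' @export
collapseLowSupport <- function(tree, thresholdPercent) {
  stopifnot(thresholdPercent >= 0, thresholdPercent <= 100)
  if (thresholdPercent == 0) return(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  nt <- .nodeTables(tree)
  sup <- nodeSupports(tree)
  ## marked: internal nodes (id space) to dissolve
  internals <- nt$root - 1L + seq_len(nt$nn)
  marked <- logical(nt$n + nt$nn)
  marked[internals] <- sup < thresholdPercent
  marked[nt$root] <- FALSE
  if (!any(marked)) return(tree)
  ## survivors map each kept node to (nearest unmarked ancestor, summed length)
  newParent <- integer(nt$n + nt$nn)
  newLen <- numeric(nt$n + nt$nn)
  keep <- !marked
  for (v in seq_len(nt$n + nt$nn)) {
    if (!keep[v] || v == nt$root) next
    p <- nt$parent[v]
    len <- nt$plen[v]
    while (marked[p]) {
      len <- len + nt$plen[p]
      p <- nt$parent[p]
    }
    newParent[v] <- p
    newLen[v] <- len
  }
  kept <- which(keep)
  children <- split(kept[kept != nt$root], newParent[kept[kept != nt$root]])
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label)) rep("", nt$nn) else tree$node.label)
  build <- function(v) {
    if (v <= nt$n) {
      lab <- tree$tip.label[v]
    } else {
      ch <- children[[as.character(v)]]
      lab <- paste0("(",
                    paste(vapply(ch, build, character(1)), collapse = ","),
                    ")", labs[v])
    }
    if (v == nt$root) paste0(lab, ";")
    else paste0(lab, ":", sprintf("%.15g", newLen[v]))
  }
  ape::read.tree(text = build(nt$root))
}

#' Prune a tree to a set of tips
#'
#' Returns the minimal induced subtree on `labels`: unsampled tips are
#' removed and degree-2 internal nodes are suppressed with branch lengths
#' summed, so pairwise cophenetic distances among the kept tips are unchanged.
#'
#' @param tree an `ape::phylo`.
#' @param labels non-empty character vector of tip labels to keep.
#' @return an `ape::phylo` on `labels`.
#' @export
pruneToTips <- function(tree, labels) {
  labels <- unique(labels)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (!length(labels)) stop("labels must be non-empty")
  ape::keep.tip(tree, labels)
}

## Per-edge descendant tip sets. Returns the postorder-reordered tree and,
## for each edge row k, the integer tip indices below edge k.
.edgeTipSets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    pa <- e[k, 1L]
    sets[[pa]] <- c(sets[[pa]], sets[[e[k, 2L]]])
  }
  list(tree = tree, edgeTips = sets[e[, 2L]])
}

#' Historical-species decomposition of a community on a tree
#'
#' Decomposes a relative-abundance vector over tree tips into "historical
#' species" (i, b): taxon i paired with each branch b on its root-to-tip
#' path. Historical abundances are pi_(i,b) = l_b * p_i / T_i, where l_b is
#' the branch length and T_i the root-to-tip depth of i; they sum to 1
#' whenever p does. The per-branch abundance a_b is the summed relative
#' abundance of the tips below b; it is the similarity-weighted abundance that
#' the phylogenetic Hill number raises to the power q - 1.
#'
#' @param tree rooted `ape::phylo` with branch lengths; tips must cover
#'   `names(p)`.
#' @param p named relative-abundance vector (non-negative, sums to 1 within
#'   `tol`) over a subset of the tips.
#' @param tol tolerance on the abundance sum.
#' @return a \linkS4class{HistoricalDecomposition}.
#' @export
decomposeHistorical <- function(tree, p, tol = 1e-8) {
  if (is.null(names(p))) stop("abundances must be named by tip label")
  unknown <- setdiff(names(p), tree$tip.label)
  if (length(unknown))
    stop("abundance names absent from tree: ", paste(unknown, collapse = ", "))
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("abundances must sum to 1 (observed ", format(sum(p)), ")")
  ets <- .edgeTipSets(tree)
  tr <- ets$tree
  depth <- tipDepths(tr)
  pfull <- setNames(numeric(ape::Ntip(tr)), tr$tip.label)
  pfull[names(p)] <- p
  bad <- names(pfull)[pfull > 0 & depth <= 0]
  if (length(bad))
    stop("degenerate tree: tip(s) with positive abundance at zero ",
         "root-to-tip depth: ", paste(bad, collapse = ", "))
  ratio <- ifelse(depth > 0, pfull / depth, 0)
  lb <- tr$edge.length
  ab <- vapply(ets$edgeTips, function(ix) sum(pfull[ix]), numeric(1))
  cb <- lb * vapply(ets$edgeTips, function(ix) sum(ratio[ix]), numeric(1))
  new("HistoricalDecomposition",
      branchLengths = lb, branchTips = ets$edgeTips,
      tipDepths = depth, branchAbundance = ab, branchMass = cb,
      abundance = pfull)
}

#' Long-format historical abundances pi_(i, b)
#'
#' @param decomp a \linkS4class{HistoricalDecomposition}.
#' @return data.frame with columns `tip`, `branch`, `pi`, `a_b`, restricted to
#'   pairs with positive historical abundance.
#' @export
historicalAbundance <- function(decomp) {
  tips <- names(decomp@tipDepths)
  out <- do.call(rbind, lapply(seq_along(decomp@branchLengths), function(b) {
    ix <- decomp@branchTips[[b]]
    pi <- decomp@branchLengths[b] * decomp@abundance[ix] /
      decomp@tipDepths[ix]
    keep <- pi > 0
    if (!any(keep)) return(NULL)
    data.frame(tip = tips[ix[keep]], branch = b, pi = unname(pi[keep]),
               a_b = decomp@branchAbundance[b])
  }))
  if (is.null(out))
    out <- data.frame(tip = character(), branch = integer(),
                      pi = numeric(), a_b = numeric())
  rownames(out) <- NULL
  out
}

setMethod("show", "HistoricalDecomposition", function(object) {
  cat("HistoricalDecomposition:", length(object@branchLengths), "branches,",
      sum(object@abundance > 0), "taxa with positive abundance\n")
  cat("  sum(pi) =", format(sum(object@branchMass)), "\n")
})
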