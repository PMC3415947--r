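## Unweighted UniFrac: the fraction of tree branch length unique to one of
## two communities, computed over the root-inclusive branch sets (every
## branch on the path from the root to a present tip), the original
## unweighted-UniFrac convention. Presence-based: counts only enter through
## rarefaction.

## logical edge-incidence: edge x tip matrix M with M[e, t] = tip t below e
.edgeIncidence <- function(tree) {
  ets <- .edgeTipSets(tree)
  n <- ape::Ntip(ets$tree)
  M <- matrix(FALSE, length(ets$edgeTips), n)
  for (k in seq_along(ets$edgeTips)) M[k, ets$edgeTips[[k]]] <- TRUE
  list(M = M, len = ets$tree$edge.length, tips = ets$tree$tip.label)
}

#' Unweighted UniFrac distance between two taxa sets
#'
#' `(branch length ancestral to exactly one set) / (branch length ancestral
#' to either set)`, over the branches from the root down to the present
#' tips. Identical sets give 0; sets sharing no branch (e.g. disjoint tips
#' on a star tree) give 1.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param taxaA,taxaB character vectors of present tips (union non-empty).
#' @return distance in [0, 1].
#' @export
unweightedUnifrac <- function(tree, taxaA, taxaB) {
  if (!length(union(taxaA, taxaB))) stop("union of taxa sets is empty")
  unknown <- setdiff(union(taxaA, taxaB), tree$tip.label)
  if (length(unknown))
    stop("taxa absent from tree: ", paste(unknown, collapse = ", "))
  inc <- .edgeIncidence(tree)
  a <- inc$tips %in% taxaA
  b <- inc$tips %in% taxaB
  inA <- inc$M %*% a > 0
  inB <- inc$M %*% b > 0
  either <- inA | inB
  sum(inc$len[xor(inA, inB)]) / sum(inc$len[either])
}

#' Pairwise unweighted UniFrac matrix under matched rarefaction
#'
#' All samples are rarefied to a common depth (default: the smallest sample
#' total) in each of `nReps` matched replicates; per replicate the pairwise
#' unweighted UniFrac distances of the rarefied presence sets are computed,
#' and the replicate matrices are averaged.
#'
#' @param comm a \linkS4class{MatCommunity} with a tree (or a counts matrix,
#'   with `tree` supplied).
#' @param tree rooted `ape::phylo`; taken from `comm` when NULL.
#' @param depth common rarefaction depth (<= every sample total).
#' @param nReps number of matched rarefaction replicates.
#' @param seed optional integer seed.
#' @return symmetric matrix in [0, 1] with zero diagonal and attributes
#'   `depth`, `n_reps`, `seed`.
#' @export
unifracMatrix <- function(comm, tree = NULL, depth = NULL, nReps = 100,
                          seed = NULL) {
  if (is(comm, "MatCommunity")) {
    if (is.null(tree)) tree <- communityTree(comm)
    m <- counts(comm)
  } else {
    m <- as.matrix(comm)
  }
  if (is.null(tree)) stop("unifracMatrix needs a tree")
  if (is.null(depth)) depth <- min(colSums(m))
  if (any(colSums(m) < depth))
    stop("depth exceeds the total count of some sample")
  inc <- .edgeIncidence(tree)
  tipIndex <- setNames(seq_along(inc$tips), inc$tips)
  ns <- ncol(m)
  acc <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      P <- matrix(FALSE, length(inc$tips), ns)
      for (s in seq_len(ns)) {
        cts <- rarefyCounts(setNames(m[, s], rownames(m)), depth)
        P[tipIndex[names(cts)[cts > 0]], s] <- TRUE
      }
      EP <- inc$M %*% P > 0   # edge x sample: branch ancestral to sample
      for (i in seq_len(ns - 1L)) {
        for (j in seq(i + 1L, ns)) {
          either <- EP[, i] | EP[, j]
          u <- sum(inc$len[xor(EP[, i], EP[, j])]) / sum(inc$len[either])
          acc[i, j] <- acc[i, j] + u
        }
      }
    }
  })
  out <- (acc + t(acc)) / nReps
  diag(out) <- 0
  structure(out, depth = depth, n_reps = nReps, seed = seed)
}
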