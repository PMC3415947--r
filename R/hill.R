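## Naive and similarity-sensitive Hill numbers, the phylogenetic diversity
## profile, and rarefaction-averaged profiles.

.checkQ <- function(q) {
  if (length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single non-negative number (Inf allowed)")
  q
}

## Generic Hill evaluation from component masses w and "ordinariness" z:
## D = (sum w * z^(q-1))^(1/(1-q)), with analytic q = 1 and q = Inf limits.
## For the naive case w = z = p; for general similarity w = p, z = (Zp)_i;
## for the phylogenetic case w = c_b (historical mass) and z = a_b.
.hillFromMasses <- function(w, z, q) {
  keep <- w > 0
  w <- w[keep]
  z <- z[keep]
  if (!length(w)) stop("no components with positive abundance")
  if (any(z <= 0))
    stop("degenerate similarity: zero ordinariness at positive abundance")
  if (is.infinite(q)) return(1 / max(z))
  if (abs(q - 1) < 1e-9) return(exp(-sum(w * log(z))))
  sum(w * z^(q - 1))^(1 / (1 - q))
}

#' Naive Hill number of order q
#'
#' The effective number of species (sum of p_i^q)^(1/(1-q)); q tunes the
#' sensitivity to rare taxa. At q = 0 it equals the taxonomic richness S,
#' at q = 1 the exponential of Shannon entropy, and at q = Inf the reciprocal
#' of the Berger-Parker index (1 / max p_i). Zero-abundance taxa are ignored.
#'
#' @param p relative-abundance vector (non-negative, sums to 1 within 1e-9).
#' @param q order, a single value in [0, Inf].
#' @return the effective number, a positive scalar.
#' @examples
#' naiveHill(c(0.5, 0.5), 0)     # 2 taxa
#' naiveHill(c(0.75, 0.25), Inf) # 1/0.75
#' @export
naiveHill <- function(p, q) {
  .assertAbundance(p)
  .checkQ(q)
  p <- p[p > 0]
  .hillFromMasses(p, p, q)
}

#' Similarity-sensitive Hill number
#'
#' Weights each taxon by its similarity-weighted total abundance
#' (Zp)_i = sum_j Z_ij p_j: D = (sum_i p_i (Zp)_i^(q-1))^(1/(1-q)). With the
#' identity matrix this reduces to \code{\link{naiveHill}}; with an all-ones
#' matrix every community has diversity 1 (one effective taxon).
#'
#' @param p named relative-abundance vector.
#' @param Z similarity matrix with entries in [0, 1] and unit diagonal;
#'   dimnames must cover `names(p)` (unnamed inputs are matched by position).
#' @param q order in [0, Inf].
#' @return the effective number.
#' @export
similarityHill <- function(p, Z, q) {
  .assertAbundance(p)
  .checkQ(q)
  Z <- as.matrix(Z)
  if (!is.null(names(p)) && !is.null(rownames(Z))) {
    if (!all(names(p) %in% rownames(Z)))
      stop("similarity matrix is missing taxa present in p")
    Z <- Z[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(Z)) {
    stop("p and Z dimensions disagree")
  }
  if (any(Z < 0) || any(Z > 1)) stop("similarities must lie in [0, 1]")
  if (any(abs(diag(Z) - 1) > 1e-12)) stop("similarity diagonal must be 1")
  zp <- drop(Z %*% p)
  .hillFromMasses(p, zp, q)
}

#' Phylogenetic Hill number from a historical-species decomposition
#'
#' Computes the similarity-sensitive diversity of the community of historical
#' species (i, b), where the ordinariness of (i, b) is the branch abundance
#' a_b (the summed relative abundance of the clade below b):
#' D = (sum_b c_b a_b^(q-1))^(1/(1-q)) with c_b the historical mass on branch
#' b. This is the branch-level form of the historical-species sum; the
#' quadratic (i,b) x (j,c) relatedness matrix is never materialized. On a
#' star tree with equal branch lengths it coincides with the naive Hill
#' number for every q.
#'
#' @param tree rooted `ape::phylo` with branch lengths (or a precomputed
#'   \linkS4class{HistoricalDecomposition}).
#' @param p named relative-abundance vector over tips; ignored when `tree` is
#'   already a decomposition.
#' @param q order in [0, Inf].
#' @return the effective number.
#' @export
phyloHill <- function(tree, p, q) {
  .checkQ(q)
  hd <- if (is(tree, "HistoricalDecomposition")) tree
        else decomposeHistorical(tree, p)
  .hillFromMasses(hd@branchMass, hd@branchAbundance, q)
}

#' Rarefy a count vector without replacement
#'
#' Draws `depth` individuals without replacement (multivariate
#' hypergeometric), so that rare taxa drop out at random and richness-type
#' statistics become comparable across unevenly sequenced samples.
#'
#' @param counts named non-negative integer vector.
#' @param depth target total, at most `sum(counts)`.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return integer vector over the same names, summing exactly to `depth`.
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
  .assertCountVector(counts)
  total <- sum(counts)
  if (depth > total)
    stop("rarefaction depth (", depth, ") exceeds total count (", total, ")")
  if (depth == total) return(counts)
  withSeed(seed, {
    pool <- rep.int(seq_along(counts), counts)
    drawn <- pool[sample.int(length(pool), depth)]
    out <- tabulate(drawn, nbins = length(counts))
    setNames(as.integer(out), names(counts))
  })
}

#' Rarefaction-averaged diversity profile
#'
#' For each order q on the grid, subsamples the counts to `depth` without
#' replacement `nReps` times, computes the (naive or phylogenetic) Hill
#' number of each subsample, and averages the diversity values. With
#' `tree = NULL` the naive profile (identity similarity) is produced, whose
#' q = 0 value is the rarefied taxonomic richness.
#'
#' @param counts named non-negative integer count vector for one sample.
#' @param tree optional rooted `ape::phylo` covering the taxa; NULL for the
#'   naive profile.
#' @param qGrid numeric vector of orders (default 0 to 5 in steps of 0.1).
#' @param depth rarefaction depth (default: the sample total, i.e. no
#'   subsampling).
#' @param nReps number of rarefaction replicates to average over.
#' @param seed optional integer seed.
#' @param sampleId identifier recorded in the output.
#' @return data.frame with columns `sample`, `q`, `value`, `depth`, `n_reps`,
#'   `variant`.
#' @export
rarefiedProfile <- function(counts, tree = NULL, qGrid = seq(0, 5, by = 0.1),
                            depth = sum(counts), nReps = 100, seed = NULL,
                            sampleId = "sample") {
  .assertCountVector(counts)
  stopifnot(nReps >= 1)
  variant <- if (is.null(tree)) "naive" else "phylogenetic"
  withSeed(seed, {
    acc <- numeric(length(qGrid))
    for (r in seq_len(nReps)) {
      cts <- rarefyCounts(counts, depth)
      cts <- cts[cts > 0]
      p <- cts / sum(cts)
      vals <- if (is.null(tree)) {
        vapply(qGrid, function(q) naiveHill(p, q), numeric(1))
      } else {
        hd <- decomposeHistorical(tree, p)
        vapply(qGrid, function(q) phyloHill(hd, q = q), numeric(1))
      }
      acc <- acc + vals
    }
    data.frame(sample = sampleId, q = qGrid, value = acc / nReps,
               depth = depth, n_reps = nReps, variant = variant)
  })
}

#' Diversity profiles for every sample of a community table
#'
#' Convenience wrapper running \code{\link{rarefiedProfile}} per sample at a
#' common depth (by default the smallest sample total, mirroring the
#' rarefy-to-minimum design of uneven amplicon libraries).
#'
#' @param comm a \linkS4class{MatCommunity}.
#' @param variant "phylogenetic" (requires a tree) or "naive".
#' @param qGrid numeric vector of orders.
#' @param depth common rarefaction depth; default min sample total.
#' @param nReps rarefaction replicates per sample.
#' @param seed optional integer seed.
#' @return long data.frame of per-sample profiles.
#' @export
communityProfiles <- function(comm, variant = c("phylogenetic", "naive"),
                              qGrid = seq(0, 5, by = 0.1), depth = NULL,
                              nReps = 100, seed = NULL) {
  variant <- match.arg(variant)
  m <- counts(comm)
  if (is.null(depth)) depth <- min(colSums(m))
  tree <- if (variant == "phylogenetic") {
    if (is.null(communityTree(comm)))
      stop("phylogenetic profiles require a tree")
    communityTree(comm)
  } else NULL
  withSeed(seed, {
    out <- lapply(colnames(m), function(s) {
      rarefiedProfile(setNames(m[, s], rownames(m)), tree = tree,
                      qGrid = qGrid, depth = depth, nReps = nReps,
                      sampleId = s)
    })
    do.call(rbind, out)
  })
}
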