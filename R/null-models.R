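## The three community randomization routines used to standardize MPD:
## independent swap (table shuffling under fixed occupancy margins),
## taxa-label shuffling of the distance matrix, and random draws from the
## taxa pool.

#' Independent-swap randomization of a count table
#'
#' Performs `nSwaps` successful 2x2 checkerboard swaps: submatrices with
#' presence pattern `[x,0;0,y]` (x, y > 0) have their entries moved to the
#' opposite diagonal, carrying the count values with the move. Per-row and
#' per-column occupancy (presence) totals are preserved exactly, which makes
#' this the most constrained — and most conservative — of the three null
#' models. If no swappable submatrix can be found within `maxAttempts`
#' candidate draws the input is returned with a warning and
#' `attr(, "exhausted") = TRUE`.
#'
#' @param m numeric matrix (taxa x samples or samples x taxa; symmetric in
#'   treatment), at least 2 x 2.
#' @param nSwaps number of successful swaps to perform.
#' @param seed optional integer seed.
#' @param binarize reduce counts to presence/absence before swapping.
#' @param maxAttempts cap on candidate submatrix draws.
#' @return randomized matrix with attributes `swaps`, `attempts`,
#'   `exhausted`.
#' @export
nullIndependentSwap <- function(m, nSwaps = 1000, seed = NULL,
                                binarize = FALSE,
                                maxAttempts = 200 * nSwaps + 10000) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("independent swap needs at least a 2 x 2 matrix")
  if (binarize) m[] <- as.numeric(m > 0)
  res <- withSeed(seed,
    .cppCheckerboardSwap(m, as.integer(nSwaps), TRUE, maxAttempts))
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  if (res$exhausted)
    warning("no (further) swappable 2x2 submatrix found after ",
            res$attempts, " attempts; matrix returned after ", res$swaps,
            " swaps")
  structure(out, swaps = res$swaps, attempts = res$attempts,
            exhausted = res$exhausted)
}

## attempted-swap chain step used inside sesMPD (burn-in / between draws)
.swapAttempts <- function(m, nAttempts) {
  res <- .cppCheckerboardSwap(m, as.integer(nAttempts), FALSE, Inf)
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  out
}

#' Taxa-label shuffling of a distance matrix
#'
#' Uniformly permutes the row/column labels of a phylogenetic distance
#' matrix, restricted to a taxa pool; the distance values themselves are
#' untouched, so the multiset of pairwise distances is invariant.
#'
#' @param d symmetric labelled distance matrix.
#' @param pool character vector of labels to permute among themselves
#'   (default: all labels); must have at least 2 members.
#' @param seed optional integer seed.
#' @return the distance matrix with permuted labels.
#' @export
nullTaxaLabels <- function(d, pool = rownames(d), seed = NULL) {
  if (length(pool) < 2) stop("pool must contain at least 2 taxa")
  if (!all(pool %in% rownames(d)))
    stop("pool contains labels absent from the distance matrix")
  withSeed(seed, {
    lab <- rownames(d)
    idx <- match(pool, lab)
    lab[idx] <- pool[sample.int(length(pool))]
    dimnames(d) <- list(lab, lab)
    d
  })
}

#' Random community draw from a taxa pool
#'
#' Draws a community of the observed richness uniformly without replacement
#' from the pool. When abundances are supplied they are reassigned to the
#' drawn taxa in random order (for proportional-weighting statistics).
#'
#' @param taxa observed community: character vector of taxa, or a named
#'   abundance vector.
#' @param pool character vector, the taxa pool (richness <= pool size).
#' @param seed optional integer seed.
#' @return a character vector of drawn taxa, or a named abundance vector
#'   when `taxa` carried abundances.
#' @export
nullPhylogenyPool <- function(taxa, pool, seed = NULL) {
  ab <- NULL
  if (is.numeric(taxa)) {
    ab <- taxa[taxa > 0]
    taxa <- names(ab)
  }
  if (length(taxa) > length(pool))
    stop("observed richness (", length(taxa), ") exceeds pool size (",
         length(pool), ")")
  withSeed(seed, {
    drawn <- .sampleFrom(pool, length(taxa))
    if (is.null(ab)) drawn else setNames(unname(ab), drawn)
  })
}
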