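## Rarefied ortholog-group (trait) richness and pooled resampling nulls.
## Draw sizes are always in gene *instances*, never group counts: the
## rarefaction depth of the observed richness and the draw size of the null
## are the same quantity.

#' Rarefied ortholog-group richness of one sample
#'
#' Mean, over `nReps` replicates, of the number of distinct groups in a
#' without-replacement subsample of `depth` gene instances.
#'
#' @param counts named integer vector of per-group instance counts.
#' @param depth instance subsample size (<= total instances).
#' @param nReps replicates to average.
#' @param seed optional integer seed.
#' @param groups optional restriction: count only distinct groups in this
#'   set (the subsample itself is still drawn from all instances).
#' @return mean distinct-group count.
#' @export
rarefiedTraitRichness <- function(counts, depth, nReps = 100, seed = NULL,
                                  groups = NULL) {
  .assertCountVector(counts)
  total <- sum(counts)
  if (depth > total)
    stop("depth (", depth, ") exceeds total instances (", total, ")")
  withSeed(seed, {
    pool <- rep.int(seq_along(counts), counts)
    keep <- if (is.null(groups)) rep(TRUE, length(counts))
            else names(counts) %in% groups
    mean(vapply(seq_len(nReps), function(r) {
      drawn <- unique(pool[sample.int(length(pool), depth)])
      sum(keep[drawn])
    }, numeric(1)))
  })
}

#' Null distribution of trait richness from a pooled instance multiset
#'
#' Each replicate draws `drawSize` gene instances without replacement from
#' the pooled multiset (all samples of a core combined, instance-weighted, so
#' abundant groups are drawn more often) and records the distinct-group
#' richness. With `poolWeighting = "group"` the pool is deduplicated to one
#' instance per group (an unweighted pool; only meaningful when `drawSize`
#' is at most the number of groups).
#'
#' @param drawSize instances per replicate (<= pool size).
#' @param pool named integer vector: pooled per-group instance counts.
#' @param nReps null replicates (the study design uses 1000).
#' @param seed optional integer seed.
#' @param groups optional category restriction on the richness count.
#' @param poolWeighting "instance" (default) or "group".
#' @return numeric vector of `nReps` null richness values.
#' @export
traitNull <- function(drawSize, pool, nReps = 1000, seed = NULL,
                      groups = NULL,
                      poolWeighting = c("instance", "group")) {
  poolWeighting <- match.arg(poolWeighting)
  .assertCountVector(pool, "pool")
  pool <- pool[pool > 0]
  if (!length(pool)) stop("pool is empty")
  if (poolWeighting == "group") pool[] <- 1L
  vec <- rep.int(seq_along(pool), pool)
  if (drawSize > length(vec))
    stop("drawSize (", drawSize, ") exceeds pool instances (", length(vec),
         ")")
  keep <- if (is.null(groups)) rep(TRUE, length(pool))
          else names(pool) %in% groups
  withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      drawn <- unique(vec[sample.int(length(vec), drawSize)])
      sum(keep[drawn])
    }, numeric(1))
  })
}

#' Trait-richness standardized tests per sample and category
#'
#' For every sample: the observed statistic is the rarefied distinct-group
#' richness at the common instance depth (default: the smallest sample
#' total); the null draws the same number of instances from the pooled
#' multiset of the sample's pool group (all samples sharing the `poolBy`
#' metadata value, or all samples). Ranks, one-tailed p-values and calls
#' follow the same conventions as \code{\link{sesMPD}}: `depleted` when the
#' observed richness falls below 95% of the null values, `enriched` above.
#' Category analyses rarefy to the whole-pool depth and then restrict the
#' richness count to the category's groups (whole-pool randomization, not
#' within-category rarefaction).
#'
#' @param tt a \linkS4class{TraitExperiment}.
#' @param depth common instance depth; default min sample total.
#' @param nReps rarefaction replicates for the observed statistic.
#' @param nNull null replicates.
#' @param categories character vector of categories to test in addition to
#'   "all"; default every category in the map.
#' @param seed optional integer seed.
#' @param alpha one-tailed significance level per direction.
#' @param poolBy optional sample-metadata column defining pool groups
#'   (e.g. "core"); NULL pools all samples.
#' @param poolWeighting passed to \code{\link{traitNull}}.
#' @return data.frame: sample, namespace, category, depth, observed
#'   richness, null mean/sd, ses, rank, p_low, p_high, call.
#' @export
traitSES <- function(tt, depth = NULL, nReps = 100, nNull = 999,
                     categories = NULL, seed = NULL, alpha = 0.05,
                     poolBy = NULL,
                     poolWeighting = c("instance", "group")) {
  poolWeighting <- match.arg(poolWeighting)
  if (nNull < 99) stop("nNull must be at least 99")
  m <- counts(tt)
  if (is.null(depth)) depth <- min(colSums(m))
  if (any(colSums(m) < depth))
    stop("depth exceeds the instance total of some sample")
  cm <- categoryMap(tt)
  if (is.null(categories)) categories <- unique(cm$category)
  catGroups <- c(list(all = NULL),
                 setNames(lapply(categories,
                                 function(ct) cm$group[cm$category == ct]),
                          categories))
  grp <- if (is.null(poolBy)) rep("all", ncol(m))
         else as.character(SummarizedExperiment::colData(tt)[[poolBy]])
  withSeed(seed, {
    out <- list()
    for (g in unique(grp)) {
      ss <- colnames(m)[grp == g]
      pool <- rowSums(m[, ss, drop = FALSE])
      pool <- setNames(as.integer(pool), rownames(m))
      poolRichness <- sum(pool > 0)
      for (ct in names(catGroups)) {
        nulls <- traitNull(depth, pool, nReps = nNull,
                           groups = catGroups[[ct]],
                           poolWeighting = poolWeighting)
        for (s in ss) {
          obs <- rarefiedTraitRichness(setNames(m[, s], rownames(m)), depth,
                                       nReps = nReps,
                                       groups = catGroups[[ct]])
          stopifnot(obs <= poolRichness)
          rs <- .rankStats(obs, nulls, nNull, alpha)
          call <- switch(rs$call, clustered = "depleted",
                         overdispersed = "enriched", rs$call)
          out[[length(out) + 1L]] <- data.frame(
            sample = s, namespace = namespace(tt), category = ct,
            depth = depth, observed = obs, null_mean = rs$nullMean,
            null_sd = rs$nullSd, ses = rs$ses, rank = rs$rank,
            p_low = rs$pLow, p_high = rs$pHigh, call = call)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
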