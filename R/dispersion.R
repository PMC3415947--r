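## Mean pairwise phylogenetic distance (MPD), standardized effect sizes
## against permutation null models, taxa-pool scoping and guild-level tests.

#' Mean pairwise phylogenetic distance of a community
#'
#' Presence weighting averages d(i, j) over all unordered pairs of distinct
#' present taxa; proportional weighting computes
#' `sum_{i != j} p_i p_j d(i, j) / sum_{i != j} p_i p_j`, which reduces to
#' the presence form when all abundances are equal.
#'
#' @param x community: a character vector of present taxa, or a named
#'   abundance/count vector (taxa with positive entries are "present").
#' @param d labelled cophenetic distance matrix covering the taxa.
#' @param weighting "presence" or "proportional".
#' @return the MPD, a non-negative scalar.
#' @export
mpd <- function(x, d, weighting = c("presence", "proportional")) {
  weighting <- match.arg(weighting)
  if (is.numeric(x)) {
    x <- x[x > 0]
    taxa <- names(x)
  } else {
    taxa <- x
  }
  if (length(taxa) < 2)
    stop("MPD is undefined for fewer than 2 present taxa")
  if (!all(taxa %in% rownames(d)))
    stop("taxa absent from the distance matrix")
  if (weighting == "presence" || !is.numeric(x)) {
    k <- length(taxa)
    sum(d[taxa, taxa]) / (k * (k - 1))
  } else {
    p <- x / sum(x)
    drop(p %*% d[taxa, taxa] %*% p) / (1 - sum(p^2))
  }
}

## single-community statistic, optionally rarefaction-averaged; the
## rarefaction depth is capped at the community's own total because
## randomized communities (independent swap moves counts across samples)
## need not preserve library sizes
.mpdStat <- function(cts, d, weighting, rarefyDepth, nReps) {
  one <- function(v) {
    v <- v[v > 0]
    if (length(v) < 2) return(NA_real_)
    mpd(v, d, weighting)
  }
  if (is.null(rarefyDepth)) return(one(cts))
  depth <- min(rarefyDepth, sum(cts))
  mean(vapply(seq_len(nReps),
              function(r) one(rarefyCounts(cts, depth)),
              numeric(1)), na.rm = TRUE)
}

#' Per-sample taxa pools under a scope
#'
#' The pool is the candidate-colonist set against which a community is
#' randomized. Scope "all" pools every taxon detected anywhere; "year"
#' restricts to taxa detected in samples from the same collection year;
#' "core" to taxa detected within the same core. Core pools are subsets of
#' year pools, which are subsets of the global pool.
#'
#' @param comm a \linkS4class{MatCommunity} (scopes "year"/"core" require the
#'   matching metadata column).
#' @param scope "all", "year" or "core".
#' @return named list: for each sample, the character vector of pool taxa.
#' @export
taxaPools <- function(comm, scope = c("all", "year", "core")) {
  scope <- match.arg(scope)
  m <- counts(comm)
  sdta <- sampleData(comm)
  grp <- switch(scope,
    all = rep("all", ncol(m)),
    year = {
      if (is.null(sdta$year)) stop("scope 'year' needs a 'year' column")
      as.character(sdta$year)
    },
    core = {
      if (is.null(sdta$core)) stop("scope 'core' needs a 'core' column")
      as.character(sdta$core)
    })
  pools <- lapply(split(colnames(m), grp), function(ss) {
    rownames(m)[rowSums(m[, ss, drop = FALSE] > 0) > 0]
  })
  setNames(lapply(grp, function(g) pools[[g]]), colnames(m))
}

.rankStats <- function(obs, nulls, nNull, alpha) {
  mu <- mean(nulls)
  sdev <- sd(nulls)
  if (!is.finite(sdev) || sdev == 0) {
    return(list(ses = NA_real_, rank = NA_real_, pLow = NA_real_,
                pHigh = NA_real_, call = "degenerate",
                nullMean = mu, nullSd = sdev))
  }
  rk <- rank(c(obs, nulls), ties.method = "average")[1L]
  pLow <- rk / (nNull + 1)
  pHigh <- (nNull + 2 - rk) / (nNull + 1)
  call <- if (pLow <= alpha) "clustered"
          else if (pHigh <= alpha) "overdispersed" else "ns"
  list(ses = (obs - mu) / sdev, rank = rk, pLow = pLow, pHigh = pHigh,
       call = call, nullMean = mu, nullSd = sdev)
}

#' Standardized effect size of MPD against a permutation null
#'
#' For every sample, compares the (optionally rarefaction-averaged) MPD to
#' `nNull` randomized communities and reports
#' `SES = (obs - mean_null) / sd_null`, the mid-averaged rank of the observed
#' value in the reference set of size `nNull + 1`, one-tailed p-values at
#' both ends, and a significance call at `alpha` per tail: negative SES /
#' low rank means the community is phylogenetically clustered (more related
#' than the null expects, the habitat-filtering signature), positive SES
#' overdispersed. Null communities are processed through exactly the same
#' rarefaction-averaged statistic as the observed one.
#'
#' Null models: `taxa.labels` shuffles the labels of the distance matrix
#' within the pool; `phylogeny.pool` draws communities of the observed
#' richness uniformly from the pool; `independent.swap` randomizes the
#' taxa-by-sample table under fixed occupancy margins via checkerboard swaps
#' (a Markov chain with `swapBurnin` attempted swaps of burn-in and
#' `swapBetween` attempts between successive null draws).
#'
#' A sample that is shuffle-invariant (e.g. containing every pool taxon under
#' `taxa.labels`) has zero null variance and is flagged `degenerate`; samples
#' with fewer than 2 present taxa are flagged `undefined`.
#'
#' @param comm a \linkS4class{MatCommunity} with a tree (or supply
#'   `distMatrix`).
#' @param nullModel one of "taxa.labels", "phylogeny.pool",
#'   "independent.swap".
#' @param poolScope taxa-pool scope, see \code{\link{taxaPools}}.
#' @param weighting "presence" or "proportional" abundance weighting.
#' @param nNull number of null communities (>= 99; 999 for publication-grade
#'   runs).
#' @param rarefyDepth rarefaction depth applied inside the statistic (NULL:
#'   no rarefaction); capped at each community's own total, so sparse guild
#'   tables and swap-randomized communities (whose column totals change)
#'   remain comparable.
#' @param nRarefactions rarefaction replicates averaged per statistic.
#' @param seed optional integer seed driving the whole run.
#' @param alpha one-tailed significance level per direction.
#' @param swapBurnin,swapBetween attempted-swap counts for the
#'   independent-swap chain.
#' @param binarizeSwap reduce the table to presence/absence before swapping
#'   (incompatible with `rarefyDepth`).
#' @param distMatrix optional precomputed cophenetic matrix.
#' @param pool optional explicit taxa pool (character vector) superseding
#'   `poolScope` for every sample — used in calibration and power studies
#'   where the candidate pool (e.g. every tree tip) is known by design
#'   rather than estimated from the table.
#' @param guildLabel value recorded in the `guild` column.
#' @return data.frame, one row per sample: sample, guild, null_model,
#'   pool_scope, weighting, n_null, richness, obs_mpd, null_mean, null_sd,
#'   ses, rank, p_low, p_high, call.
#' @export
sesMPD <- function(comm,
                   nullModel = c("taxa.labels", "phylogeny.pool",
                                 "independent.swap"),
                   poolScope = c("all", "year", "core"),
                   weighting = c("presence", "proportional"),
                   nNull = 999, rarefyDepth = NULL, nRarefactions = 100,
                   seed = NULL, alpha = 0.05,
                   swapBurnin = 10000, swapBetween = 1000,
                   binarizeSwap = FALSE, distMatrix = NULL,
                   pool = NULL, guildLabel = "all") {
  nullModel <- match.arg(nullModel)
  poolScope <- match.arg(poolScope)
  weighting <- match.arg(weighting)
  if (nNull < 99) stop("nNull must be at least 99")
  if (binarizeSwap && !is.null(rarefyDepth))
    stop("binarizeSwap is incompatible with rarefaction of null counts")
  m <- counts(comm)
  D <- if (is.null(distMatrix)) {
    if (is.null(communityTree(comm)))
      stop("sesMPD needs a tree or a distance matrix")
    copheneticDistances(communityTree(comm))
  } else distMatrix
  pools <- if (is.null(pool)) taxaPools(comm, poolScope)
           else {
             bad <- colnames(m)[colSums(m[setdiff(rownames(m), pool), ,
                                          drop = FALSE] > 0) > 0]
             if (length(bad))
               stop("explicit pool misses observed taxa in sample(s): ",
                    paste(bad, collapse = ", "))
             setNames(rep(list(pool), ncol(m)), colnames(m))
           }
  samples <- colnames(m)
  statOf <- function(cts) .mpdStat(cts, D, weighting, rarefyDepth,
                                   nRarefactions)

  withSeed(seed, {
    nullStats <- matrix(NA_real_, nNull, length(samples),
                        dimnames = list(NULL, samples))
    obs <- vapply(samples, function(s) {
      v <- m[, s]
      if (sum(v > 0) < 2) NA_real_ else statOf(v)
    }, numeric(1))

    if (nullModel == "independent.swap") {
      sdta <- sampleData(comm)
      grp <- switch(poolScope, all = rep("all", ncol(m)),
                    year = as.character(sdta$year),
                    core = as.character(sdta$core))
      for (g in unique(grp)) {
        ss <- samples[grp == g]
        sub <- m[pools[[ss[1L]]], ss, drop = FALSE]
        if (binarizeSwap) sub[] <- as.integer(sub > 0)
        cur <- .swapAttempts(sub, swapBurnin)
        for (r in seq_len(nNull)) {
          cur <- .swapAttempts(cur, swapBetween)
          for (s in ss) {
            v <- cur[, s]
            if (sum(v > 0) >= 2) nullStats[r, s] <- statOf(v)
          }
        }
      }
    } else {
      for (s in samples) {
        v <- m[, s]
        v <- v[v > 0]
        if (length(v) < 2) next
        pool <- pools[[s]]
        for (r in seq_len(nNull)) {
          nv <- if (nullModel == "taxa.labels") {
            map <- setNames(pool[sample.int(length(pool))], pool)
            setNames(unname(v), unname(map[names(v)]))
          } else {
            nullPhylogenyPool(v, pool)
          }
          nullStats[r, s] <- statOf(nv)
        }
      }
    }

    rows <- lapply(samples, function(s) {
      rich <- sum(m[, s] > 0)
      base <- data.frame(sample = s, guild = guildLabel,
                         null_model = nullModel, pool_scope = poolScope,
                         weighting = weighting, n_null = nNull,
                         richness = rich)
      if (rich < 2 || !is.finite(obs[s])) {
        return(cbind(base, obs_mpd = NA_real_, null_mean = NA_real_,
                     null_sd = NA_real_, ses = NA_real_, rank = NA_real_,
                     p_low = NA_real_, p_high = NA_real_,
                     call = "undefined"))
      }
      nulls <- nullStats[, s]
      nulls <- nulls[is.finite(nulls)]
      rs <- .rankStats(obs[s], nulls, length(nulls), alpha)
      cbind(base, obs_mpd = obs[s], null_mean = rs$nullMean,
            null_sd = rs$nullSd, ses = rs$ses, rank = rs$rank,
            p_low = rs$pLow, p_high = rs$pHigh, call = rs$call)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default functional guild definitions
#'
#' Three guilds of the mat system, matched against lineage strings:
#' oxygenic phototrophs (phylum Cyanobacteria), purple sulfur bacteria
#' (order Chromatiales) and anaerobic sulfate reducers (orders
#' Desulfobacterales, Desulfovibrionales, Syntrophobacterales,
#' Clostridiales).
#'
#' @return named list of lineage-substring vectors.
#' @export
guildDefinitions <- function() {
  list(cyanobacteria = "Cyanobacteria",
       purple_sulfur = "Chromatiales",
       sulfate_reducers = c("Desulfobacterales", "Desulfovibrionales",
                            "Syntrophobacterales", "Clostridiales"))
}

#' Guild-level phylogenetic dispersion
#'
#' Restricts the table and tree to each guild's member taxa (selected by
#' lineage substring match), rebuilds the scoped taxa pool within the guild,
#' and delegates to \code{\link{sesMPD}}. A guild that selects fewer than 2
#' taxa is skipped with a message.
#'
#' @param comm a \linkS4class{MatCommunity} with tree and lineage taxonomy.
#' @param guilds named list of lineage-substring vectors
#'   (default \code{\link{guildDefinitions}}).
#' @param ... passed to \code{\link{sesMPD}}.
#' @param seed optional integer seed.
#' @return row-bound data.frame of \code{\link{sesMPD}} results, one block
#'   per guild.
#' @export
guildDispersion <- function(comm, guilds = guildDefinitions(), seed = NULL,
                            ...) {
  lin <- taxonomyLineage(comm)
  if (is.null(lin)) stop("guild dispersion needs lineage taxonomy")
  tree <- communityTree(comm)
  withSeed(seed, {
    out <- lapply(names(guilds), function(g) {
      pat <- guilds[[g]]
      hit <- Reduce(`|`, lapply(pat, function(p) grepl(p, lin, fixed = TRUE)))
      members <- names(lin)[hit]
      if (length(members) < 2) {
        message("guild '", g, "' selects fewer than 2 taxa; skipped")
        return(NULL)
      }
      sub <- MatCommunity(counts(comm)[members, , drop = FALSE],
                          sampleData(comm),
                          lineage = lin[members],
                          tree = pruneToTips(tree, members))
      sesMPD(sub, guildLabel = g, ...)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Which taxa belong to each guild
#'
#' @param lineage named lineage vector.
#' @param guilds named list of substring vectors.
#' @return named list of taxon-id vectors.
#' @export
guildMembers <- function(lineage, guilds = guildDefinitions()) {
  lapply(guilds, function(pat) {
    hit <- Reduce(`|`,
                  lapply(pat, function(p) grepl(p, lineage, fixed = TRUE)))
    names(lineage)[hit]
  })
}
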