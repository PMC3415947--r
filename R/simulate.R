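## Synthetic-data generator: birth-death trees, Brownian tip traits,
## communities assembled under filtering / neutral / competition regimes,
## sequencing-depth count sampling, and ortholog trait tables. The generator
## gives every downstream stage data with known structure ("truth") so the
## dispersion and trait tests can be calibrated and power-checked without
## external sequence data.

## Forward (Gillespie) birth-death simulation, stopped the first time the
## extant lineage count reaches n; the present is then pushed forward by a
## fresh Exp(n(b+d)) waiting time so every pendant branch is strictly
## positive. Returns NULL on extinction (caller retries).
.simulateBD <- function(n, b, d) {
  parent <- c(0L, 0L)
  tBirth <- c(0, 0)
  tEvent <- c(NA_real_, NA_real_)
  hasChild <- c(FALSE, FALSE)
  died <- c(FALSE, FALSE)
  alive <- c(1L, 2L)
  t <- 0
  while (length(alive) < n) {
    if (!length(alive)) return(NULL)
    t <- t + rexp(1, length(alive) * (b + d))
    k <- alive[sample.int(length(alive), 1L)]
    alive <- alive[alive != k]
    tEvent[k] <- t
    if (d == 0 || runif(1) < b / (b + d)) {
      hasChild[k] <- TRUE
      m <- length(parent)
      parent <- c(parent, k, k)
      tBirth <- c(tBirth, t, t)
      tEvent <- c(tEvent, NA_real_, NA_real_)
      hasChild <- c(hasChild, FALSE, FALSE)
      died <- c(died, FALSE, FALSE)
      alive <- c(alive, m + 1L, m + 2L)
    } else {
      died[k] <- TRUE
    }
  }
  present <- t + rexp(1, n * (b + d))
  tEvent[is.na(tEvent)] <- present
  list(parent = parent, tBirth = tBirth, tEnd = tEvent,
       hasChild = hasChild, died = died)
}

.bdToPhylo <- function(sim) {
  ## prune extinct lineages first, contracting single-child chains, so the
  ## edge table stays small even when extinction is near-critical
  len <- sim$tEnd - sim$tBirth
  nLin <- length(sim$parent)
  surviving <- !sim$died & !sim$hasChild   # extant tips
  keep <- surviving
  ## mark ancestors of extant tips (parents listed before children)
  for (i in nLin:1) if (keep[i] && sim$parent[i] > 0)
    keep[sim$parent[i]] <- TRUE
  nKeptChildren <- integer(nLin)
  for (i in seq_len(nLin)) if (keep[i] && sim$parent[i] > 0)
    nKeptChildren[sim$parent[i]] <- nKeptChildren[sim$parent[i]] + 1L
  ## node roles among kept lineages: tip (extant), split (2 kept children),
  ## or pass-through (1 kept child; contracted into the child's edge)
  isSplit <- keep & nKeptChildren == 2L
  ## effective parent: nearest kept ancestor that is a split (or the root 0)
  effParent <- integer(nLin)
  effLen <- numeric(nLin)
  for (i in seq_len(nLin)) {
    if (!keep[i] || (!surviving[i] && !isSplit[i])) next
    p <- sim$parent[i]
    l <- len[i]
    while (p > 0 && !isSplit[p]) {
      l <- l + len[p]
      p <- sim$parent[p]
    }
    effParent[i] <- p
    effLen[i] <- l
  }
  nodes <- which(surviving | isSplit)
  tipNodes <- nodes[surviving[nodes]]
  splitNodes <- nodes[!surviving[nodes]]
  ntip <- length(tipNodes)
  ## root handling: if the virtual root (0) has two kept subtrees it is the
  ## phylo root; if only one, the topmost split is
  rootKids <- sum(effParent[nodes] == 0)
  id <- integer(nLin)
  id[tipNodes] <- seq_len(ntip)
  if (rootKids == 2L) {
    nnode <- length(splitNodes) + 1L
    id[splitNodes] <- ntip + 1L + seq_along(splitNodes)
    rootId <- ntip + 1L
  } else {
    nnode <- length(splitNodes)
    topSplit <- splitNodes[effParent[splitNodes] == 0]
    others <- setdiff(splitNodes, topSplit)
    id[topSplit] <- ntip + 1L
    id[others] <- ntip + 1L + seq_along(others)
    rootId <- NA_integer_
  }
  edgeNodes <- nodes[!(rootKids == 1L & effParent[nodes] == 0)]
  pIdx <- effParent[edgeNodes]
  pId <- ifelse(pIdx == 0, rootId, id[pmax(pIdx, 1L)])
  edge <- cbind(pId, id[edgeNodes])
  dimnames(edge) <- NULL
  tr <- structure(list(edge = edge, edge.length = effLen[edgeNodes],
                       tip.label = paste0("t", seq_len(ntip)),
                       Nnode = nnode),
                  class = "phylo")
  ape::reorder.phylo(tr)
}

#' Simulate a rooted birth-death tree with support labels
#'
#' Forward birth-death simulation conditioned to stop the first time `nTips`
#' lineages are simultaneously extant; the present is extended by one further
#' exponential waiting time so all pendant branches are positive. Extinct
#' lineages (when `deathRate > 0`) are pruned, leaving exactly `nTips` extant
#' tips. Internal nodes receive bootstrap-like support values drawn uniformly
#' on [0, 100], emulating the support-annotated trees produced by maximum-
#' likelihood tree builders.
#'
#' @param nTips number of extant tips (>= 2).
#' @param birthRate per-lineage speciation rate (> 0).
#' @param deathRate per-lineage extinction rate (>= 0; 0 gives a pure-birth
#'   Yule tree and is the default elsewhere in the package).
#' @param seed optional integer seed; the result is a pure function of
#'   (arguments, seed).
#' @return a rooted binary `ape::phylo` with `nTips` tips labelled
#'   `t1..tN`, positive branch lengths, and numeric node labels.
#' @export
simulateTree <- function(nTips, birthRate = 1, deathRate = 0, seed = NULL) {
  if (nTips < 2) stop("nTips must be at least 2")
  stopifnot(birthRate > 0, deathRate >= 0)
  withSeed(seed, {
    repeat {
      sim <- .simulateBD(nTips, birthRate, deathRate)
      if (!is.null(sim)) break
    }
    tr <- .bdToPhylo(sim)
    tr$tip.label <- sprintf("t%d", seq_len(ape::Ntip(tr)))
    tr$node.label <- sprintf("%.1f", runif(tr$Nnode, 0, 100))
    tr
  })
}

#' Evolve a continuous trait along a tree by Brownian motion
#'
#' Starting from a root value of 0, each branch adds a Gaussian increment
#' with variance `traitSigma^2 * branch length`, so a tip's variance equals
#' `traitSigma^2` times its root-to-tip depth. This instantiates the
#' phylogenetic niche conservatism that makes trait-based habitat filtering
#' leave a phylogenetic-clustering signature.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param traitSigma Brownian-motion rate (> 0).
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolveTrait <- function(tree, traitSigma = 1, seed = NULL) {
  if (traitSigma <= 0) stop("traitSigma must be positive")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  withSeed(seed,
    ape::rTraitCont(tree, model = "BM", sigma = traitSigma, root.value = 0))
}

#' Assemble a community of taxa under a specified ecological regime
#'
#' \describe{
#'   \item{filtering}{an environmental optimum is set to the trait value of a
#'     randomly chosen seed taxon; taxa are then drawn without replacement
#'     with weight `exp(-strength * (trait - optimum)^2)`. With conserved
#'     traits this concentrates the community in one part of the tree
#'     (phylogenetic clustering). The optimum is chosen per call, so distinct
#'     samples are filtered toward different clades.}
#'   \item{neutral}{uniform sampling without replacement.}
#'   \item{competition}{greedy maximin selection on cophenetic distance from
#'     a random start: at each step the taxon farthest (in minimum distance)
#'     from the current set is taken with probability
#'     `strength / (1 + strength)`, otherwise a uniform draw, so strength 0
#'     is exactly neutral and large strength approaches pure limiting
#'     similarity (overdispersion).}
#' }
#' At `regimeStrength = 0` all three regimes reduce to uniform sampling.
#'
#' @param tree an `ape::phylo`.
#' @param traits named tip-trait vector (required for filtering).
#' @param regime one of "neutral", "filtering", "competition".
#' @param regimeStrength non-negative selection strength.
#' @param targetRichness community size (<= number of tips).
#' @param seed optional integer seed.
#' @param distMatrix optional precomputed cophenetic matrix (competition).
#' @return sorted character vector of `targetRichness` tip labels.
#' @export
assembleCommunity <- function(tree, traits = NULL,
                              regime = c("neutral", "filtering",
                                         "competition"),
                              regimeStrength = 0, targetRichness,
                              seed = NULL, distMatrix = NULL) {
  regime <- match.arg(regime)
  stopifnot(regimeStrength >= 0)
  tips <- tree$tip.label
  if (targetRichness > length(tips))
    stop("targetRichness exceeds the number of tips")
  if (targetRichness < 1) stop("targetRichness must be at least 1")
  withSeed(seed, {
    sel <- switch(regime,
      neutral = .sampleFrom(tips, targetRichness),
      filtering = {
        if (regimeStrength == 0) .sampleFrom(tips, targetRichness)
        else {
          if (is.null(traits)) stop("filtering requires tip traits")
          tr <- traits[tips]
          opt <- tr[[.sampleFrom(seq_along(tips), 1L)]]
          w <- exp(-regimeStrength * (tr - opt)^2)
          w <- pmax(w, 1e-300)
          .sampleFrom(tips, targetRichness, prob = w)
        }
      },
      competition = {
        if (regimeStrength == 0) .sampleFrom(tips, targetRichness)
        else {
          D <- if (is.null(distMatrix)) copheneticDistances(tree)
               else distMatrix[tips, tips]
          pGreedy <- regimeStrength / (1 + regimeStrength)
          sel <- .sampleFrom(tips, 1L)
          remaining <- setdiff(tips, sel)
          minDist <- D[remaining, sel]
          while (length(sel) < targetRichness) {
            pick <- if (runif(1) < pGreedy) {
              cand <- remaining[minDist >= max(minDist) - 1e-12]
              if (length(cand) > 1L) .sampleFrom(cand, 1L) else cand
            } else {
              .sampleFrom(remaining, 1L)
            }
            sel <- c(sel, pick)
            keep <- remaining != pick
            minDist <- pmin(minDist[keep], D[remaining[keep], pick])
            remaining <- remaining[keep]
          }
          sel
        }
      })
    sort(sel)
  })
}

#' Draw sequencing counts for a community
#'
#' Per-taxon relative abundances are drawn from a lognormal(0, shape)
#' rank-abundance distribution, normalized, and a multinomial of size `depth`
#' is drawn, emulating an amplicon library of `depth` reads.
#'
#' @param taxa non-empty character vector of community members.
#' @param abundanceShape lognormal sigma of the abundance distribution.
#' @param depth library size (>= 1); counts sum exactly to `depth`.
#' @param seed optional integer seed.
#' @return named integer vector over `taxa`.
#' @export
sampleCounts <- function(taxa, abundanceShape = 1, depth, seed = NULL) {
  if (!length(taxa)) stop("taxon set must be non-empty")
  stopifnot(depth >= 1, abundanceShape >= 0)
  withSeed(seed, {
    ab <- rlnorm(length(taxa), 0, abundanceShape)
    cts <- rmultinom(1L, depth, ab / sum(ab))[, 1L]
    setNames(as.integer(cts), taxa)
  })
}

#' Simulate an ortholog-group trait table
#'
#' Each sample draws `perSampleInstances` gene instances from a shared pool
#' of `poolSize` ortholog groups under a sample-specific multinomial. Base
#' weights are uniform over the groups in a sample's accessible pool, so with
#' no enrichment a category's expected instance share equals its share of the
#' pool. A single category may be enriched by a factor >= 1, and a sample's
#' accessible pool may be restricted to a random fraction of the groups
#' (`poolFraction`), which produces trait-depleted samples.
#'
#' @param nSamples number of samples.
#' @param poolSize number of ortholog groups in the shared pool (>= number of
#'   categories).
#' @param categoryMap data.frame with columns `group`, `category`; NULL
#'   builds a default map cycling five functional categories over the groups
#'   and adding every group to `total_metabolism`.
#' @param perSampleInstances gene instances per sample (>= 1).
#' @param enrichment multiplicative weight (>= 1) on `enrichCategory`.
#' @param enrichCategory category to enrich; default the first category when
#'   `enrichment > 1`.
#' @param enrichSamples sample indices to enrich (default all).
#' @param poolFraction fraction (0, 1] of groups accessible per sample,
#'   recycled over samples; groups outside a sample's random subset get zero
#'   weight.
#' @param namespace ortholog namespace tag.
#' @param seed optional integer seed.
#' @return a \linkS4class{TraitExperiment} (groups x samples).
#' @export
simulateTraitTable <- function(nSamples, poolSize, categoryMap = NULL,
                               perSampleInstances, enrichment = 1,
                               enrichCategory = NULL, enrichSamples = NULL,
                               poolFraction = 1, namespace = "KO",
                               seed = NULL) {
  if (enrichment < 1) stop("enrichment must be at least 1")
  stopifnot(perSampleInstances >= 1, nSamples >= 1,
            all(poolFraction > 0), all(poolFraction <= 1))
  groups <- sprintf("%s%05d", tolower(namespace), seq_len(poolSize))
  if (is.null(categoryMap)) {
    cats <- c("photosynthesis", "sulfur_metabolism", "carbohydrate_metabolism",
              "abc_transporters", "oxidative_phosphorylation")
    categoryMap <- rbind(
      data.frame(group = groups,
                 category = rep_len(cats, poolSize)),
      data.frame(group = groups, category = "total_metabolism"))
  }
  if (poolSize < length(unique(categoryMap$category)))
    stop("poolSize must be at least the number of categories")
  if (enrichment > 1 && is.null(enrichCategory))
    enrichCategory <- categoryMap$category[1L]
  if (is.null(enrichSamples)) enrichSamples <- seq_len(nSamples)
  poolFraction <- rep_len(poolFraction, nSamples)
  withSeed(seed, {
    m <- matrix(0L, poolSize, nSamples,
                dimnames = list(groups, sprintf("S%d", seq_len(nSamples))))
    enriched <- groups %in% categoryMap$group[categoryMap$category %in%
                                              enrichCategory]
    for (s in seq_len(nSamples)) {
      w <- rep(1, poolSize)
      if (poolFraction[s] < 1) {
        nacc <- max(1L, round(poolFraction[s] * poolSize))
        acc <- sample.int(poolSize, nacc)
        w[-acc] <- 0
      }
      if (enrichment > 1 && s %in% enrichSamples)
        w[enriched] <- w[enriched] * enrichment
      m[, s] <- rmultinom(1L, perSampleInstances, w / sum(w))[, 1L]
    }
    TraitExperiment(m, categoryMap = categoryMap, namespace = namespace)
  })
}

## per-node descendant-tip sets and children lists (node-id space)
.nodeTipSets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  e <- tree$edge
  for (k in seq_len(nrow(e)))
    sets[[e[k, 1L]]] <- c(sets[[e[k, 1L]]], sets[[e[k, 2L]]])
  children <- split(e[, 2L], e[, 1L])
  list(tree = tree, sets = sets, children = children, ntip = n)
}

## split the tip set into at most k clades by repeatedly splitting the
## largest current clade at its root
.splitClades <- function(tree, k) {
  ns <- .nodeTipSets(tree)
  nodes <- ns$ntip + 1L  # root
  sizes <- length(ns$sets[[nodes]])
  while (length(nodes) < k) {
    splittable <- nodes > ns$ntip
    if (!any(splittable)) break
    i <- which(splittable)[which.max(sizes[splittable])]
    ch <- ns$children[[as.character(nodes[i])]]
    nodes <- c(nodes[-i], ch)
    sizes <- c(sizes[-i], lengths(ns$sets[ch]))
  }
  lapply(nodes, function(v) ns$tree$tip.label[ns$sets[[v]]])
}

#' Synthesize a clade-consistent taxonomy for a simulated tree
#'
#' Assigns phylum and order names from a fixed bacterial catalogue to the
#' major clades of the tree, so that lineage-substring guild definitions
#' (e.g. "Chromatiales") select monophyletic groups. The lineage format is
#' `Bacteria;<Phylum>;<Class>;<Order>`.
#'
#' @param tree an `ape::phylo`.
#' @return named character vector of lineage strings over the tips.
#' @export
synthesizeTaxonomy <- function(tree) {
  catalogue <- list(
    Cyanobacteria = c("Oscillatoriales", "Chroococcales"),
    Proteobacteria = c("Chromatiales", "Desulfobacterales",
                       "Desulfovibrionales", "Syntrophobacterales",
                       "Rhodospirillales"),
    Firmicutes = c("Clostridiales", "Bacillales"),
    Bacteroidetes = c("Bacteroidales", "Flavobacteriales"),
    Chloroflexi = c("Anaerolineales"),
    Planctomycetes = c("Planctomycetales"))
  phyClades <- .splitClades(tree, length(catalogue))
  ## biggest clades get the phyla with the most orders
  ord <- order(lengths(phyClades), decreasing = TRUE)
  lineage <- setNames(character(ape::Ntip(tree)), tree$tip.label)
  for (i in seq_along(phyClades)) {
    phy <- names(catalogue)[min(i, length(catalogue))]
    orders <- catalogue[[phy]]
    clade <- phyClades[[ord[i]]]
    sub <- pruneToTips(tree, clade)
    ordClades <- if (length(clade) > 1L) .splitClades(sub, length(orders))
                 else list(clade)
    for (j in seq_along(ordClades)) {
      o <- orders[min(j, length(orders))]
      lineage[ordClades[[j]]] <-
        paste("Bacteria", phy, paste0(phy, "_class"), o, sep = ";")
    }
  }
  lineage
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of \code{\link{simulateDataset}}.
#' `regime` and `regimeStrength` are recycled over samples, so layered
#' designs (e.g. competition at the surface, increasingly strong filtering
#' with depth) are expressed directly. A strength of 0 makes every regime
#' collapse to neutral sampling.
#'
#' @param nTips tips in the regional tree (>= 4).
#' @param birthRate,deathRate birth-death rates (birth > 0, death >= 0).
#' @param traitSigma Brownian trait rate (> 0).
#' @param regime per-sample regime(s): "filtering", "neutral", "competition".
#' @param regimeStrength per-sample non-negative strength(s).
#' @param nSamples number of samples.
#' @param targetRichness taxa per sample (<= nTips).
#' @param sequencingDepths per-sample library sizes, recycled.
#' @param abundanceShape lognormal sigma of the rank-abundance distribution.
#' @param traitPoolSize,traitInstances,traitPoolFraction trait-table shape:
#'   ortholog pool size, instances per sample, accessible pool fraction.
#' @param seed integer seed driving the whole dataset.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(nTips = 200, birthRate = 1, deathRate = 0,
                             traitSigma = 1, regime = "filtering",
                             regimeStrength = 10, nSamples = 5,
                             targetRichness = 30,
                             sequencingDepths = 2000, abundanceShape = 1,
                             traitPoolSize = 1500, traitInstances = 1200,
                             traitPoolFraction = 1, seed = 1) {
  stopifnot(nTips >= 4, targetRichness <= nTips, targetRichness >= 1,
            birthRate > 0, deathRate >= 0, traitSigma > 0,
            all(regimeStrength >= 0), nSamples >= 1,
            all(sequencingDepths >= 1))
  regime <- rep_len(regime, nSamples)
  bad <- setdiff(unique(regime), c("filtering", "neutral", "competition"))
  if (length(bad))
    stop("unknown regime(s): ", paste(bad, collapse = ", "))
  cfg <- list(nTips = nTips, birthRate = birthRate, deathRate = deathRate,
              traitSigma = traitSigma,
              regime = rep_len(regime, nSamples),
              regimeStrength = rep_len(regimeStrength, nSamples),
              nSamples = nSamples, targetRichness = targetRichness,
              sequencingDepths = rep_len(sequencingDepths, nSamples),
              abundanceShape = abundanceShape,
              traitPoolSize = traitPoolSize, traitInstances = traitInstances,
              traitPoolFraction = traitPoolFraction, seed = seed)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a complete dataset
#'
#' Generates, under one seed: a support-annotated tree, Brownian tip traits,
#' a clade-consistent taxonomy, per-sample communities assembled under the
#' configured regimes, sequencing counts at the configured depths, an
#' ortholog trait table, and the per-sample truth (regime and strength).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param sampleData optional per-sample metadata data.frame (rownames =
#'   sample ids); defaults to one core of consecutive 2 mm layers.
#' @return a list of class "SimulatedDataset": `community`
#'   (\linkS4class{MatCommunity} with tree and taxonomy), `traits` (tip trait
#'   vector), `traitTable` (\linkS4class{TraitExperiment}), `truth`
#'   (data.frame sample/regime/strength), `config`.
#' @export
simulateDataset <- function(config, sampleData = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    tree <- simulateTree(config$nTips, config$birthRate, config$deathRate)
    tree$tip.label <- sprintf("OTU%04d", seq_len(ape::Ntip(tree)))
    traits <- evolveTrait(tree, config$traitSigma)
    lineage <- synthesizeTaxonomy(tree)
    D <- copheneticDistances(tree)
    ids <- if (!is.null(sampleData)) rownames(sampleData)
           else sprintf("S%d", seq_len(config$nSamples))
    m <- matrix(0L, ape::Ntip(tree), config$nSamples,
                dimnames = list(tree$tip.label, ids))
    for (s in seq_len(config$nSamples)) {
      taxa <- assembleCommunity(tree, traits, config$regime[s],
                                config$regimeStrength[s],
                                config$targetRichness, distMatrix = D)
      m[taxa, s] <- sampleCounts(taxa, config$abundanceShape,
                                 config$sequencingDepths[s])
    }
    if (is.null(sampleData)) {
      sampleData <- data.frame(
        row.names = ids, core = "C1", year = 2010L,
        layer = sprintf("L%d", seq_len(config$nSamples)),
        depth_top_mm = 2 * (seq_len(config$nSamples) - 1),
        depth_bottom_mm = 2 * seq_len(config$nSamples))
    }
    community <- MatCommunity(m, sampleData, lineage = lineage, tree = tree)
    traitTable <- simulateTraitTable(
      nSamples = config$nSamples, poolSize = config$traitPoolSize,
      perSampleInstances = config$traitInstances,
      poolFraction = config$traitPoolFraction)
    colnames(traitTable) <- ids
    truth <- data.frame(sample = ids, regime = config$regime,
                        strength = config$regimeStrength)
    structure(list(community = community, traits = traits,
                   traitTable = traitTable, truth = truth, config = config),
              class = "SimulatedDataset")
  })
}

#' Write a miniature study-shaped fixture set
#'
#' Emits a complete synthetic study to `dir`: three cores (YM-10 and OM-10
#' collected in 2010, OM-11 in 2011) of five depth layers each, with weak
#' competition at the surface and filtering of increasing strength with
#' depth; uneven sequencing depths whose minimum is 1071 reads; an ortholog
#' trait table over the OM-10 layers whose accessible gene pool shrinks with
#' depth; and the matching tree, taxonomy, metadata and truth tables. All
#' tabular files are TSV, the tree is newick with supports as node labels.
#' The data are synthetic stand-ins with study-like structure, not a
#' reconstruction of any real survey.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the fixture is a pure function of it.
#' @param nTips tree size.
#' @param targetRichness taxa per layer community.
#' @return invisibly, a list with the file paths and the in-memory dataset.
#' @export
writeFixtureSet <- function(dir, seed = 1, nTips = 150, targetRichness = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cores <- data.frame(core = rep(c("YM-10", "OM-10", "OM-11"), each = 5),
                      year = rep(c(2010L, 2010L, 2011L), each = 5))
  layers <- data.frame(layer = c("green", "pink", "brown", "gray", "black"),
                       depth_top_mm = c(0, 2, 5, 10, 15),
                       depth_bottom_mm = c(2, 5, 10, 15, 20))
  md <- cbind(cores, layers[rep(seq_len(5), 3), ])
  rownames(md) <- sprintf("%s_%g-%gmm", md$core, md$depth_top_mm,
                          md$depth_bottom_mm)
  regime <- rep(c("competition", "filtering", "filtering", "filtering",
                  "filtering"), 3)
  strength <- rep(c(3, 4, 6, 8, 10), 3)
  depths <- withSeed(seed, {
    d <- sample(1071:2600, 15)
    d[which.min(d)] <- 1071L  # smallest library pinned at the design minimum
    d
  })
  cfg <- simulationConfig(nTips = nTips, regime = regime,
                          regimeStrength = strength, nSamples = 15,
                          targetRichness = targetRichness,
                          sequencingDepths = depths,
                          traitPoolSize = 1200, traitInstances = 1800,
                          seed = seed)
  ds <- simulateDataset(cfg, sampleData = md)
  ## trait table: the five OM-10 layers, pool shrinking with depth
  tt <- withSeed(seed + 1L, simulateTraitTable(
    nSamples = 5, poolSize = 1200, perSampleInstances = 1800,
    poolFraction = c(1, 0.8, 0.65, 0.5, 0.4)))
  colnames(tt) <- rownames(md)[md$core == "OM-10"]
  ds$traitTable <- tt

  comm <- ds$community
  paths <- list(
    table = file.path(dir, "otu_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    traits = file.path(dir, "trait_table.tsv"),
    categories = file.path(dir, "trait_categories.tsv"),
    truth = file.path(dir, "truth.tsv"))
  .writeTSVMatrix(counts(comm), "otu_id", paths$table)
  write.table(cbind(sample = rownames(sampleData(comm)), sampleData(comm)),
              paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  writeNewick(communityTree(comm), paths$tree)
  write.table(data.frame(otu_id = names(taxonomyLineage(comm)),
                         lineage = unname(taxonomyLineage(comm))),
              paths$taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeTSVMatrix(counts(tt), "group_id", paths$traits)
  write.table(categoryMap(tt), paths$categories, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ds$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(paths = paths, dataset = ds))
}

.writeTSVMatrix <- function(m, idCol, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
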