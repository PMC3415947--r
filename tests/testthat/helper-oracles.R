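## Independent oracles used to check the package implementations. These are
## deliberately naive re-implementations (parent-walks, brute-force path
## enumeration, depths-only re-simulation) that share no code with the
## package's own algorithms.

## depths-only re-simulation of the forward birth-death process with
## taxa-stop conditioning and the Exp(n(b+d)) present-extension; returns the
## mean root-to-tip depth of the extant tree (present - MRCA birth time)
oracleBDDepth <- function(n, b, d) {
  repeat {
    parent <- c(0L, 0L)
    tBirth <- c(0, 0)
    alive <- c(1L, 2L)
    t <- 0
    extinct <- FALSE
    while (length(alive) < n) {
      if (!length(alive)) { extinct <- TRUE; break }
      t <- t + rexp(1, length(alive) * (b + d))
      k <- alive[sample.int(length(alive), 1L)]
      alive <- alive[alive != k]
      if (d == 0 || runif(1) < b / (b + d)) {
        m <- length(parent)
        parent <- c(parent, k, k)
        tBirth <- c(tBirth, t, t)
        alive <- c(alive, m + 1L, m + 2L)
      }
    }
    if (!extinct) break
  }
  present <- t + rexp(1, n * (b + d))
  ## MRCA of the extant set: common ancestor with the latest birth time
  anc <- function(i) {
    out <- i
    while (parent[i] > 0L) { i <- parent[i]; out <- c(out, i) }
    out
  }
  common <- Reduce(intersect, lapply(alive, anc))
  tMRCA <- if (length(common)) {
    ## the MRCA node sits where the deepest common lineage splits, i.e. at
    ## the birth of its children
    k <- common[which.max(tBirth[common])]
    min(tBirth[parent == k])
  } else 0
  present - tMRCA
}

## brute-force cophenetic distance via parent-walks on the edge table
oracleCophenetic <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  pathUp <- function(v) {
    nodes <- v; depth <- 0; depths <- 0
    while (parent[v] > 0) {
      depth <- depth + plen[v]
      v <- parent[v]
      nodes <- c(nodes, v)
      depths <- c(depths, depth)
    }
    setNames(depths, nodes)
  }
  paths <- lapply(seq_len(n), pathUp)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- intersect(names(paths[[i]]), names(paths[[j]]))
      dij <- min(paths[[i]][shared] + paths[[j]][shared])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

## per-tip root-to-tip depth via parent-walk (independent of tipDepths)
oracleTipDepths <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  vapply(seq_len(n), function(v) {
    depth <- 0
    while (parent[v] > 0) { depth <- depth + plen[v]; v <- parent[v] }
    depth
  }, numeric(1)) |> setNames(tree$tip.label)
}

## ultrametric branch-formula oracle for the phylogenetic Hill number:
## D = (sum_b (l_b / T) a_b^q)^(1/(1-q)), a_b accumulated by tip-to-root
## walks, T the common tip depth
oraclePhyloHill <- function(tree, p, q) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  a <- numeric(n + tree$Nnode)   # abundance below the branch above node v
  for (tip in seq_len(n)) {
    pi <- p[tree$tip.label[tip]]
    if (is.na(pi) || pi == 0) next
    v <- tip
    while (v > 0) { a[v] <- a[v] + pi; v <- parent[v] }
  }
  depths <- oracleTipDepths(tree)
  T <- depths[[1]]
  stopifnot(diff(range(depths)) < 1e-8)
  hasEdge <- parent > 0 & a > 0
  w <- plen[hasEdge] / T
  ab <- a[hasEdge]
  if (is.infinite(q)) return(1 / max(ab))
  if (abs(q - 1) < 1e-9) return(exp(-sum(w * ab * log(ab))))
  sum(w * ab^q)^(1 / (1 - q))
}

## random ultrametric tree + abundances for oracle comparisons
randomUltrametricCase <- function(maxTips = 100) {
  n <- sample(5:maxTips, 1)
  tr <- ape::rcoal(n)
  k <- sample(2:n, 1)
  taxa <- sample(tr$tip.label, k)
  w <- rexp(k)
  list(tree = tr, p = setNames(w / sum(w), taxa))
}

## tiny fixed tree used across files
fixtureTree <- function() readNewick("((A:1,B:1)90:1,C:2);")

## small simulated community table wrapped in a MatCommunity
simSmallCommunity <- function(seed = 1, nTips = 60, nSamples = 6,
                              richness = 15, depth = 500,
                              regime = "neutral", strength = 0) {
  cfg <- simulationConfig(nTips = nTips, nSamples = nSamples,
                          targetRichness = richness,
                          sequencingDepths = depth, regime = regime,
                          regimeStrength = strength, seed = seed)
  simulateDataset(cfg)
}

binom99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - 2.5758 * se, p + 2.5758 * se)
}
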