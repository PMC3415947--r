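test_that("simulated trees are valid, reproducible and sized exactly", {
  expect_error(simulateTree(1), "at least 2")
  t2 <- simulateTree(2, 1, 0, seed = 7)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)
  expect_true(all(t2$edge.length > 0))

  a <- simulateTree(50, 1, 0, seed = 7)
  b <- simulateTree(50, 1, 0, seed = 7)
  expect_identical(writeNewick(a), writeNewick(b))

  for (seed in 1:4) {
    tr <- simulateTree(40, 1, 0.5, seed = seed)
    expect_equal(ape::Ntip(tr), 40)
    expect_true(ape::is.rooted(tr))
    expect_true(all(tr$edge.length > 0))
    expect_true(ape::is.binary(tr))
    sup <- nodeSupports(tr)
    expect_true(all(sup >= 0 & sup <= 100))
    ## taxa-stop time trees are ultrametric before any rate perturbation
    expect_lt(diff(range(tipDepths(tr))), 1e-8)
  }
})

test_that("mean root-to-tip depth matches a brute-force re-simulation", {
  ## package trees vs. an independent depths-only simulation of the same
  ## process, pure birth and birth-death
  for (par in list(c(1, 0), c(1, 0.5))) {
    set.seed(20 + par[2] * 10)
    simDepth <- vapply(1:120, function(i) {
      mean(tipDepths(simulateTree(60, par[1], par[2])))
    }, numeric(1))
    oraDepth <- vapply(1:1000, function(i)
      oracleBDDepth(60, par[1], par[2]), numeric(1))
    se <- sqrt(var(simDepth) / length(simDepth) +
               var(oraDepth) / length(oraDepth))
    expect_lt(abs(mean(simDepth) - mean(oraDepth)), 3 * se)
  }
})

test_that("Brownian traits have the prescribed variance structure", {
  star <- ape::stree(1000, "star")
  star$edge.length <- rep(1, 1000)
  x <- evolveTrait(star, 1, seed = 5)
  expect_gt(var(x), 0.85)
  expect_lt(var(x), 1.15)

  sisters <- readNewick("((A:0,B:0):1,C:2);")
  y <- evolveTrait(sisters, 1, seed = 6)
  expect_identical(y[["A"]], y[["B"]])

  tr <- simulateTree(30, seed = 8)
  expect_identical(evolveTrait(tr, 2, seed = 9), evolveTrait(tr, 2, seed = 9))
  expect_error(evolveTrait(tr, 0), "positive")
})

test_that("community assembly respects size, regime and strength-zero limits", {
  tr <- simulateTree(40, seed = 10)
  traits <- evolveTrait(tr, 1, seed = 11)
  full <- assembleCommunity(tr, traits, "neutral", 0, 40, seed = 12)
  expect_setequal(full, tr$tip.label)
  expect_error(assembleCommunity(tr, traits, "anarchy", 0, 5),
               "arg")

  ## strength 0 collapses filtering and competition to uniform sampling
  set.seed(13)
  nDraw <- 2000
  for (regime in c("filtering", "competition")) {
    hits <- table(factor(unlist(lapply(seq_len(nDraw), function(i)
      assembleCommunity(tr, traits, regime, 0, 8))), levels = tr$tip.label))
    bounds <- binom99(8 / 40, nDraw)
    freq <- as.numeric(hits) / nDraw
    ## allow the prescribed binomial band, with a tiny slack for the
    ## 40 simultaneous comparisons
    expect_true(all(freq > bounds[1] - 0.01 & freq < bounds[2] + 0.01))
  }
})

test_that("regimes are calibrated: filtering clusters, competition disperses", {
  set.seed(14)
  nrep <- 100
  dF <- dC <- dN <- numeric(nrep)
  for (i in seq_len(nrep)) {
    tr <- simulateTree(200, 1, 0)
    traits <- evolveTrait(tr, 1)
    D <- copheneticDistances(tr)
    dF[i] <- mpd(assembleCommunity(tr, traits, "filtering", 10, 30,
                                   distMatrix = D), D)
    dC[i] <- mpd(assembleCommunity(tr, traits, "competition", 10, 30,
                                   distMatrix = D), D)
    dN[i] <- mpd(assembleCommunity(tr, traits, "neutral", 0, 30), D) -
      mean(replicate(30, mpd(sample(tr$tip.label, 30), D)))
    dF[i] <- dF[i] - mean(replicate(30, mpd(sample(tr$tip.label, 30), D)))
    dC[i] <- dC[i] - mean(replicate(30, mpd(sample(tr$tip.label, 30), D)))
  }
  expect_lt(mean(dF), 0)                        # filtering below uniform
  expect_gt(mean(dC), 0)                        # competition above uniform
  expect_lt(abs(mean(dN)) / (sd(dN) / sqrt(nrep)), 2)  # neutral within 2 SE
})

test_that("count sampling conserves depth and matches multinomial expectation", {
  expect_equal(sampleCounts("A", 1, 500, seed = 1), c(A = 500L))
  expect_error(sampleCounts(character(), 1, 10), "non-empty")
  cts <- sampleCounts(letters[1:10], 1, 2000, seed = 2)
  expect_equal(sum(cts), 2000)
  expect_identical(cts, sampleCounts(letters[1:10], 1, 2000, seed = 2))

  ## degenerate lognormal (shape 0) gives equal underlying probabilities:
  ## at large depth every observed frequency sits within 3 binomial SEs
  x <- sampleCounts(letters[1:20], 0, 1e6, seed = 3)
  se <- sqrt(0.05 * 0.95 / 1e6)
  expect_true(all(abs(x / 1e6 - 0.05) < 4 * se))
})

test_that("trait tables share the pool and honour enrichment bounds", {
  expect_error(simulateTraitTable(3, 50, perSampleInstances = 100,
                                  enrichment = 0.5), "at least 1")
  tt <- simulateTraitTable(4, 1, perSampleInstances = 50, categoryMap =
    data.frame(group = "ko00001", category = "photosynthesis"), seed = 4)
  expect_true(all(colSums(counts(tt) > 0) == 1))  # single-group pool
  expect_identical(counts(simulateTraitTable(3, 30, perSampleInstances = 99,
                                             seed = 5)),
                   counts(simulateTraitTable(3, 30, perSampleInstances = 99,
                                             seed = 5)))
  expect_true(all(colSums(counts(tt)) == 50))

  ## with no enrichment, a category's expected instance share equals its
  ## share of the pool (500 replicate tables)
  set.seed(6)
  share <- vapply(1:500, function(i) {
    t1 <- simulateTraitTable(1, 50, perSampleInstances = 40)
    cm <- categoryMap(t1)
    ph <- cm$group[cm$category == "photosynthesis"]
    sum(counts(t1)[ph, 1]) / 40
  }, numeric(1))
  poolShare <- 10 / 50
  expect_lt(abs(mean(share) - poolShare),
            3 * sd(share) / sqrt(length(share)))
})

test_that("simulated datasets are coherent and deterministic", {
  ds <- simSmallCommunity(seed = 21)
  m <- counts(ds$community)
  expect_equal(unname(colSums(m)), rep(500, 6))
  expect_true(all(colSums(m > 0) <= 15))
  expect_true(all(rownames(m) %in% communityTree(ds$community)$tip.label))
  expect_equal(nrow(ds$truth), 6)
  lin <- taxonomyLineage(ds$community)
  expect_true(all(grepl("^Bacteria;", lin)))

  ds2 <- simSmallCommunity(seed = 21)
  expect_identical(counts(ds$community), counts(ds2$community))
  expect_identical(writeNewick(communityTree(ds$community)),
                   writeNewick(communityTree(ds2$community)))
})
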