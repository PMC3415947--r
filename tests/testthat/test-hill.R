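test_that("naive Hill numbers hit their closed forms", {
  expect_equal(naiveHill(c(0.5, 0.5), 0), 2)
  expect_equal(naiveHill(c(0.75, 0.25), Inf), 1 / 0.75)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(naiveHill(p, 1), exp(-sum(p * log(p))))
  for (q in c(0, 0.5, 1, 2, 5, Inf))
    expect_equal(naiveHill(c(1, 0, 0, 0), q), 1)
  ## q = 0 equals the count of positive-abundance taxa, exactly
  set.seed(2)
  for (r in 1:20) {
    k <- sample(1:30, 1)
    p <- rexp(k); p <- p / sum(p)
    expect_identical(naiveHill(c(p, rep(0, 5)), 0), as.numeric(k))
  }
})

test_that("similarity-sensitive diversity generalizes the naive case", {
  set.seed(3)
  for (r in 1:10) {
    k <- sample(2:15, 1)
    p <- rexp(k); p <- p / sum(p)
    for (q in c(0, 0.5, 1, 2, 5, Inf))
      expect_equal(similarityHill(p, diag(k), q), naiveHill(p, q),
                   tolerance = 1e-12)
    ## complete similarity: one effective taxon
    expect_equal(similarityHill(p, matrix(1, k, k), 2), 1, tolerance = 1e-12)
  }
  ## two fully similar blocks of equal abundance: 2 effective taxa at all q
  Z <- kronecker(diag(2), matrix(1, 2, 2))
  p <- rep(0.25, 4)
  for (q in c(0, 0.7, 1, 2, 5, Inf))
    expect_equal(similarityHill(p, Z, q), 2, tolerance = 1e-12)
})

test_that("phylogenetic Hill equals naive on equal-branch star trees", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1.5, 8)
  star$tip.label <- paste0("s", 1:8)
  set.seed(4)
  p <- rexp(8); p <- setNames(p / sum(p), star$tip.label)
  for (q in c(seq(0, 5, by = 0.5), Inf))
    expect_equal(phyloHill(star, p, q), naiveHill(unname(p), q),
                 tolerance = 1e-9)
  ## two-tip symmetric tree, even abundances: 2 effective lineages
  expect_equal(phyloHill(readNewick("(A:1,B:1);"), c(A = .5, B = .5), 0), 2)
})

test_that("phylogenetic Hill matches the ultrametric branch-formula oracle", {
  set.seed(6)
  for (r in 1:15) {
    cs <- randomUltrametricCase(60)
    for (q in c(0, 0.5, 1, 2, 5))
      expect_equal(phyloHill(cs$tree, cs$p, q),
                   oraclePhyloHill(cs$tree, cs$p, q), tolerance = 1e-9)
  }
})

test_that("diversity is continuous at q = 1", {
  set.seed(8)
  cs <- randomUltrametricCase(40)
  v1 <- phyloHill(cs$tree, cs$p, 1)
  lo <- phyloHill(cs$tree, cs$p, 1 - 1e-4)
  hi <- phyloHill(cs$tree, cs$p, 1 + 1e-4)
  expect_true(hi <= v1 + 1e-3 * v1 && lo >= v1 - 1e-3 * v1)
  expect_lt(abs(lo - v1) / v1, 1e-3)
  expect_lt(abs(hi - v1) / v1, 1e-3)
})

test_that("profiles are non-increasing in q for all variants", {
  qGrid <- seq(0, 5, by = 0.25)
  set.seed(9)
  for (r in 1:15) {
    k <- sample(2:20, 1)
    p <- rexp(k); p <- p / sum(p)
    naive <- vapply(qGrid, function(q) naiveHill(p, q), numeric(1))
    expect_true(all(diff(naive) <= 1e-10))
    Z <- matrix(runif(k * k, 0, 1), k, k)
    Z <- (Z + t(Z)) / 2; diag(Z) <- 1
    sim <- vapply(qGrid, function(q) similarityHill(p, Z, q), numeric(1))
    expect_true(all(diff(sim) <= 1e-10))
    cs <- randomUltrametricCase(40)
    phy <- vapply(qGrid, function(q) phyloHill(cs$tree, cs$p, q), numeric(1))
    expect_true(all(diff(phy) <= 1e-10))
  }
})

test_that("rarefaction subsamples exactly and matches the hypergeometric mean", {
  cts <- c(A = 12L, B = 5L, C = 0L, D = 3L)
  expect_identical(rarefyCounts(cts, 20), cts)
  one <- rarefyCounts(cts, 1, seed = 4)
  expect_equal(sum(one), 1)
  expect_equal(sum(one > 0), 1)
  expect_error(rarefyCounts(cts, 21), "exceeds")
  expect_identical(rarefyCounts(cts, 7, seed = 9), rarefyCounts(cts, 7, seed = 9))

  big <- c(A = 900L, B = 100L)
  set.seed(10)
  draws <- vapply(1:1000, function(i) rarefyCounts(big, 100)[["A"]],
                  numeric(1))
  ## hypergeometric mean 90, variance n*p*(1-p)*(N-n)/(N-1)
  se <- sqrt(100 * 0.9 * 0.1 * 900 / 999) / sqrt(1000)
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("rarefied profiles average correctly and degrade gracefully", {
  cts <- c(A = 30L, B = 20L, C = 10L)
  tr <- fixtureTree()
  ## no subsampling, one rep: equals the unrarefied profile
  pr <- rarefiedProfile(cts, tree = tr, qGrid = c(0, 1, 2), depth = 60,
                        nReps = 1, seed = 1)
  p <- cts / sum(cts)
  expect_equal(pr$value,
               vapply(c(0, 1, 2), function(q) phyloHill(tr, p, q),
                      numeric(1)), tolerance = 1e-12)
  ## single-taxon sample: flat at 1
  flat <- rarefiedProfile(c(X = 50L), qGrid = seq(0, 5, 1), depth = 10,
                          nReps = 3, seed = 2)
  expect_true(all(flat$value == 1))
  expect_identical(unique(flat$variant), "naive")
  ## averaged profiles remain non-increasing
  pr2 <- rarefiedProfile(cts, tree = tr, qGrid = seq(0, 5, 0.5), depth = 20,
                         nReps = 10, seed = 3)
  expect_true(all(diff(pr2$value) <= 1e-10))
})
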