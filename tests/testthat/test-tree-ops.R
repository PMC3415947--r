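test_that("newick round trip preserves topology, lengths and supports", {
  tr <- readNewick("((A:1,B:1)90:1,C:2);")
  expect_equal(ape::Ntip(tr), 3)
  expect_true("90" %in% tr$node.label)
  txt1 <- writeNewick(tr)
  txt2 <- writeNewick(readNewick(txt1))
  expect_identical(txt1, txt2)

  sim <- simulateTree(40, seed = 3)
  rt <- readNewick(writeNewick(sim))
  expect_setequal(rt$tip.label, sim$tip.label)
  d1 <- copheneticDistances(sim)
  d2 <- copheneticDistances(rt)[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("newick reader rejects bad input", {
  expect_error(readNewick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(readNewick("((A:1,B:1"), "malformed")
  unrooted <- ape::unroot(ape::rtree(5))
  expect_error(readNewick(ape::write.tree(unrooted)), "unrooted")
})

test_that("cophenetic distances equal hand sums and a brute-force oracle", {
  d <- copheneticDistances(fixtureTree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)

  star <- ape::stree(5, "star")
  star$edge.length <- rep(1, 5)
  ds <- copheneticDistances(star)
  expect_true(all(ds[upper.tri(ds)] == 2))

  set.seed(7)
  tr <- simulateTree(50, 1, 0.3)
  expect_equal(copheneticDistances(tr),
               oracleCophenetic(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)
})

test_that("support-threshold collapsing makes polytomies and preserves depths", {
  tr <- readNewick("((A:1,B:1)40:2,C:3);")
  expect_identical(writeNewick(collapseLowSupport(tr, 0)), writeNewick(tr))
  col <- collapseLowSupport(tr, 50)
  expect_equal(ape::Ntip(col), 3)
  expect_equal(col$Nnode, 1)           # single polytomy
  expect_equal(unname(tipDepths(col)[c("A", "B", "C")]), c(3, 3, 3))

  for (seed in 1:3) {
    sim <- simulateTree(80, 1, 0.2, seed = seed)
    for (thr in c(30, 50, 80, 100)) {
      col <- collapseLowSupport(sim, thr)
      expect_equal(tipDepths(col)[sim$tip.label], tipDepths(sim),
                   tolerance = 1e-9)
      expect_true(all(nodeSupports(col)[-1] >= thr))
    }
  }
})

test_that("pruning keeps pairwise distances among retained tips", {
  tr <- fixtureTree()
  expect_equal(copheneticDistances(pruneToTips(tr, c("A", "B", "C"))),
               copheneticDistances(tr))
  pr <- pruneToTips(tr, c("A", "C"))
  expect_equal(copheneticDistances(pr)["A", "C"], 4)
  expect_error(pruneToTips(tr, c("A", "Z")), "Z")

  set.seed(11)
  for (r in 1:5) {
    sim <- simulateTree(60, 1, 0)
    keep <- sample(sim$tip.label, sample(3:30, 1))
    expect_equal(copheneticDistances(pruneToTips(sim, keep))[keep, keep],
                 copheneticDistances(sim)[keep, keep], tolerance = 1e-9)
  }
})

test_that("historical decomposition normalizes and matches hand cases", {
  two <- readNewick("(A:1,B:1);")
  hd <- decomposeHistorical(two, c(A = 0.5, B = 0.5))
  expect_equal(sort(unname(hd@branchMass)), c(0.5, 0.5))
  expect_equal(sort(unname(hd@branchAbundance)), c(0.5, 0.5))

  tr <- fixtureTree()
  hd <- decomposeHistorical(tr, c(A = 0.25, B = 0.25, C = 0.5))
  ## the stem of (A, B) carries the summed clade abundance
  stem <- which(vapply(hd@branchTips, length, 1L) == 2)
  expect_equal(hd@branchAbundance[stem], 0.5)
  expect_equal(sum(hd@branchMass), 1, tolerance = 1e-12)

  pi <- historicalAbundance(hd)
  expect_equal(sum(pi$pi), 1, tolerance = 1e-12)
  expect_true(all(pi$pi > 0))

  set.seed(5)
  for (r in 1:10) {
    cs <- randomUltrametricCase(50)
    hd <- decomposeHistorical(cs$tree, cs$p)
    expect_equal(sum(hd@branchMass), 1, tolerance = 1e-12)
  }
})

test_that("degenerate and invalid abundances are rejected", {
  tr <- fixtureTree()
  expect_error(decomposeHistorical(tr, c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(decomposeHistorical(tr, c(A = 0.5, Z = 0.5)), "absent")
  zero <- readNewick("(A:0,B:1);")
  expect_error(decomposeHistorical(zero, c(A = 0.5, B = 0.5)),
               "degenerate")
})
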