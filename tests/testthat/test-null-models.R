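test_that("independent swap flips the only checkerboard and stalls otherwise", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  out <- nullIndependentSwap(m, 1, seed = 1)
  expect_equal(unclass(out)[, ], matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)
  expect_warning(res <- nullIndependentSwap(matrix(1, 2, 2), 1, seed = 2,
                                            maxAttempts = 500),
                 "swappable")
  expect_equal(unclass(res)[, ], matrix(1, 2, 2), ignore_attr = TRUE)
  expect_true(attr(res, "exhausted"))
})

test_that("independent swap preserves occupancy margins and count multiset", {
  set.seed(3)
  for (r in 1:100) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    m <- matrix(rpois(nr * nc, 0.8), nr, nc)
    out <- suppressWarnings(nullIndependentSwap(m, 50))
    expect_equal(rowSums(out > 0), rowSums(m > 0), ignore_attr = TRUE)
    expect_equal(colSums(out > 0), colSums(m > 0), ignore_attr = TRUE)
    expect_equal(sort(as.vector(out)), sort(as.vector(m)))
    ## count totals per row travel with the swap
    expect_equal(rowSums(out), rowSums(m), ignore_attr = TRUE)
  }
})

test_that("taxa-label shuffling permutes labels but not distances", {
  set.seed(4)
  tr <- simulateTree(12)
  d <- copheneticDistances(tr)
  out <- nullTaxaLabels(d, seed = 5)
  expect_setequal(rownames(out), rownames(d))
  expect_equal(sort(out[upper.tri(out)]), sort(d[upper.tri(d)]))
  expect_error(nullTaxaLabels(d, pool = "t1"), "at least 2")

  ## pool of size 2: identity or the single transposition
  two <- nullTaxaLabels(d, pool = c("t1", "t2"), seed = 6)
  expect_true(identical(rownames(two), rownames(d)) ||
              identical(match(c("t1", "t2"), rownames(two)),
                        match(c("t2", "t1"), rownames(d))))
})

test_that("taxa-label permutations are uniform over a 4-label pool", {
  d <- copheneticDistances(simulateTree(4, seed = 7))
  pool <- rownames(d)
  set.seed(8)
  perms <- vapply(1:24000, function(i) {
    paste(rownames(nullTaxaLabels(d, pool)), collapse = "")
  }, character(1))
  freq <- table(perms) / length(perms)
  expect_equal(length(freq), 24)
  bounds <- binom99(1 / 24, 24000)
  expect_true(all(freq > bounds[1] - 0.003 & freq < bounds[2] + 0.003))
})

test_that("phylogeny-pool draws are uniform and size-preserving", {
  pool <- paste0("t", 1:12)
  expect_setequal(nullPhylogenyPool(pool, pool, seed = 9), pool)
  expect_error(nullPhylogenyPool(pool, pool[1:3]), "exceeds")
  expect_identical(nullPhylogenyPool(c("a", "b"), pool, seed = 10),
                   nullPhylogenyPool(c("a", "b"), pool, seed = 10))

  set.seed(11)
  draws <- vapply(1:10000, function(i)
    nullPhylogenyPool("x", pool), character(1))
  freq <- table(factor(draws, levels = pool)) / 10000
  bounds <- binom99(1 / 12, 10000)
  expect_true(all(freq > bounds[1] - 0.004 & freq < bounds[2] + 0.004))

  ## abundances are carried onto the drawn taxa
  ab <- c(a = 5, b = 3, c = 2)
  drawn <- nullPhylogenyPool(ab, pool, seed = 12)
  expect_equal(sort(unname(drawn)), c(2, 3, 5))
  expect_true(all(names(drawn) %in% pool))
})
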