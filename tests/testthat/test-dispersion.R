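test_that("MPD matches hand cases, algebraic identities and picante", {
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  expect_equal(mpd(c("A", "B"), d2), 2)
  d3 <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  expect_equal(mpd(letters[1:3], d3), 5)
  expect_equal(mpd(c(a = 2, b = 1, c = 7), d3, "proportional"), 5)
  expect_error(mpd("A", d2), "fewer than 2")

  set.seed(1)
  tr <- simulateTree(30)
  D <- copheneticDistances(tr)
  for (r in 1:10) {
    taxa <- sample(tr$tip.label, 20)
    ## equal abundances: proportional equals presence exactly
    expect_equal(mpd(setNames(rep(2, 20), taxa), D, "proportional"),
                 mpd(taxa, D), tolerance = 1e-12)
  }
  ## independent implementation agreement on presence MPD
  comm <- matrix(0, 2, 30, dimnames = list(c("s1", "s2"), tr$tip.label))
  comm["s1", sample(tr$tip.label, 12)] <- 1
  comm["s2", sample(tr$tip.label, 7)] <- 1
  pic <- picante::mpd(comm, D)
  expect_equal(mpd(colnames(comm)[comm["s1", ] > 0], D), pic[1],
               tolerance = 1e-9)
  expect_equal(mpd(colnames(comm)[comm["s2", ] > 0], D), pic[2],
               tolerance = 1e-9)
})

test_that("rank and p conventions place the observed among its nulls", {
  ## a community whose MPD is forced to known rank via constructed nulls
  obs <- 5; nulls <- c(1:4, 6:100)
  rs <- matdiversity:::.rankStats(obs, nulls, length(nulls), 0.05)
  expect_equal(rs$rank, 5)
  expect_equal(rs$pLow, 5 / 100)
  expect_equal(rs$pHigh, (100 + 1 - 5) / 100)
  expect_identical(rs$call, "clustered")
  ## ties get mid-ranks
  rsT <- matdiversity:::.rankStats(5, c(5, 5, rep(10, 97)),
                                   99, 0.05)
  expect_equal(rsT$rank, 2)
})

test_that("sesMPD flags shuffle-invariant samples as degenerate", {
  tr <- simulateTree(10, seed = 2)
  m <- matrix(1L, 10, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  comm <- MatCommunity(m, data.frame(row.names = c("s1", "s2"),
                                     core = c("C", "C"),
                                     year = c(2010L, 2010L)), tree = tr)
  res <- sesMPD(comm, "taxa.labels", nNull = 99, seed = 3)
  expect_true(all(res$call == "degenerate"))
  expect_true(all(is.na(res$ses)))
})

test_that("taxa pools nest from core through year to the full table", {
  ds <- simSmallCommunity(seed = 30, nSamples = 9)
  comm <- ds$community
  sd <- sampleData(comm)
  sd$core <- rep(c("C1", "C2", "C3"), each = 3)
  sd$year <- rep(c(2010L, 2010L, 2011L), each = 3)
  comm2 <- MatCommunity(counts(comm), sd, tree = communityTree(comm))
  pAll <- taxaPools(comm2, "all")
  pYear <- taxaPools(comm2, "year")
  pCore <- taxaPools(comm2, "core")
  m <- counts(comm2)
  for (s in colnames(m)) {
    observed <- rownames(m)[m[, s] > 0]
    expect_true(all(observed %in% pCore[[s]]))
    expect_true(all(pCore[[s]] %in% pYear[[s]]))
    expect_true(all(pYear[[s]] %in% pAll[[s]]))
  }
})

test_that("sesMPD detects filtering and is deterministic under a seed", {
  set.seed(31)
  tr <- simulateTree(150)
  traits <- evolveTrait(tr, 1)
  D <- copheneticDistances(tr)
  taxa <- assembleCommunity(tr, traits, "filtering", 12, 25)
  m <- matrix(0L, 150, 1, dimnames = list(tr$tip.label, "s1"))
  m[taxa, 1] <- sampleCounts(taxa, 1, 800)
  comm <- MatCommunity(m, data.frame(row.names = "s1", core = "C",
                                     year = 2010), tree = tr)
  r1 <- sesMPD(comm, "taxa.labels", nNull = 199, pool = tr$tip.label,
               distMatrix = D, seed = 32)
  r2 <- sesMPD(comm, "taxa.labels", nNull = 199, pool = tr$tip.label,
               distMatrix = D, seed = 32)
  expect_identical(r1, r2)
  expect_true(is.finite(r1$ses))
  expect_gte(r1$rank, 1)
  expect_lte(r1$rank, 200)
  ## rarefaction-averaged observed statistic stays reproducible
  r3 <- sesMPD(comm, "phylogeny.pool", nNull = 99, pool = tr$tip.label,
               distMatrix = D, rarefyDepth = 400, nRarefactions = 5,
               seed = 33)
  expect_true(is.finite(r3$obs_mpd))
})

test_that("guild dispersion delegates, partitions and recenters", {
  ds <- simSmallCommunity(seed = 34, nTips = 80, nSamples = 4,
                          richness = 40, regime = "neutral")
  comm <- ds$community
  lin <- taxonomyLineage(comm)
  ## disjoint phylum guilds partition the taxa
  phyla <- unique(vapply(strsplit(lin, ";"), `[`, character(1), 2))
  guilds <- setNames(lapply(phyla, function(p) paste0(";", p, ";")), phyla)
  members <- guildMembers(lin, guilds)
  expect_setequal(unlist(members), names(lin))
  expect_equal(sum(lengths(members)), length(lin))

  ## the trivial guild selecting everything equals plain sesMPD
  all_guild <- list(everything = "Bacteria")
  g <- suppressMessages(
    guildDispersion(comm, all_guild, nNull = 99, seed = 35))
  direct <- sesMPD(comm, "taxa.labels", nNull = 99, seed = 35,
                   guildLabel = "everything")
  expect_equal(g$obs_mpd, direct$obs_mpd, tolerance = 1e-9)
  expect_equal(g$ses, direct$ses, tolerance = 1e-9)

  ## a guild with fewer than 2 taxa is skipped with a message
  expect_message(
    out <- guildDispersion(comm, list(ghost = "NoSuchLineage"),
                           nNull = 99, seed = 36),
    "skipped")
  expect_null(out)
})

test_that("filtering inside one clade leaves guild-level dispersion random", {
  ## domain-level clustering that dissolves when the test is restricted to
  ## the guild the filter acted within
  set.seed(37)
  nrep <- 60
  sesDomain <- sesGuild <- rep(NA_real_, nrep)
  for (i in seq_len(nrep)) {
    tr <- simulateTree(120)
    D <- copheneticDistances(tr)
    ## guild = one deep clade of ~half the tips; community = uniform draw
    ## within the guild (filtering whose optimum clade is the guild)
    sets <- matdiversity:::.splitClades(tr, 2)
    guild <- sets[[which.max(lengths(sets))]]
    if (length(guild) < 40) next
    taxa <- sample(guild, 20)
    sesDomain[i] <- {
      nulls <- replicate(199, mpd(sample(tr$tip.label, 20), D))
      (mpd(taxa, D) - mean(nulls)) / sd(nulls)
    }
    sesGuild[i] <- {
      nulls <- replicate(199, mpd(sample(guild, 20), D))
      (mpd(taxa, D) - mean(nulls)) / sd(nulls)
    }
  }
  expect_lt(mean(sesDomain, na.rm = TRUE), -1)
  expect_lt(abs(mean(sesGuild, na.rm = TRUE)),
            abs(mean(sesDomain, na.rm = TRUE)) / 2)
})
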