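# Partition-function accessibilities against brute-force enumeration.

test_that("an unstructured sequence is fully accessible", {
  expect_equal(unpairedProbability(strrep("A", 12), c(3, 8)), 1)
})

test_that("engine probabilities match enumeration, free and constrained", {
  set.seed(501)
  for (k in 1:12) {
    n <- sample(15:24, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    iv <- sort(sample(n, 2))
    fb <- if (k %% 2) sample(setdiff(seq_len(n), iv[1]:iv[2]),
                             min(3, n - diff(iv) - 1)) else integer(0)
    expect_equal(unpairedProbability(s, iv, fb),
                 bruteForceUnpairedProbability(s, iv, fb),
                 tolerance = 1e-9)
  }
})

test_that("freeing a stem's partner strand raises the other arm's accessibility", {
  hp <- "GGGGAAAACCCC"
  p0 <- unpairedProbability(hp, c(9, 12))
  p1 <- unpairedProbability(hp, c(9, 12), forbiddenBases = 1:4)
  expect_gt(p1, p0)
  expect_equal(p1, bruteForceUnpairedProbability(hp, c(9, 12), 1:4),
               tolerance = 1e-9)
  # constraining bases inside the queried interval never decreases P_u
  set.seed(502)
  for (k in 1:6) {
    s <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
    iv <- c(8, 13)
    expect_gte(unpairedProbability(s, iv, forbiddenBases = 9:11) -
               unpairedProbability(s, iv), -1e-12)
  }
})

test_that("opening energies and probabilities round-trip", {
  RT <- 1.9872e-3 * 310.15
  expect_equal(openingEnergyToProbability(0), 1)
  expect_equal(openingEnergyToProbability(RT * log(2)), 0.5)
  # the published shiA-scale probability inverts and round-trips
  dE <- probabilityToOpeningEnergy(1.2e-5)
  expect_equal(dE, -RT * log(1.2e-5))
  expect_equal(openingEnergyToProbability(dE), 1.2e-5, tolerance = 1e-12)
  # deep round-trip across magnitudes, incl. the 60 kcal/mol regime
  for (e in c(0.1, 1, 5, 20, 40, 60)) {
    expect_equal(probabilityToOpeningEnergy(openingEnergyToProbability(e)), e,
                 tolerance = 1e-12)
  }
  expect_error(openingEnergyToProbability(-0.1), "negative")
  expect_error(probabilityToOpeningEnergy(0), "in \\(0, 1\\]")
})

test_that("rdsExposure reports P_EF and site-constrained P_ES coherently", {
  tr <- plantedTranscript()
  be <- nnBackend()
  rds <- findRRS(tr, be)
  free <- rdsExposure(tr, rds, NULL, be)
  expect_s4_class(free, "AccessibilityResult")
  expect_false(free@constrained)
  expect_true(free@probability > 0 && free@probability <= 1)
  expect_equal(free@probability,
               openingEnergyToProbability(free@openingEnergy),
               tolerance = 1e-9)
  expect_equal(free@kOpen, free@probability / (1 - free@probability),
               tolerance = 1e-9)
  # a site entirely inside the RDS can only free it further
  inside <- mkSite(-5, 6, -12)
  con <- rdsExposure(tr, rds, inside, be)
  expect_true(con@constrained)
  expect_gte(con@probability, free@probability - 1e-12)
})

test_that("a hairpin over the RDS is opened by blocking its partner arm", {
  # the activation fixture realises this mechanism end to end
  sc <- getFixtureSet()$activation
  be <- nnBackend()
  rds <- findRRS(sc@transcript, be)
  sites <- findSrnaSites(sc@srna, sc@transcript, be)
  site <- sites[[which.min(vapply(sites, deltaGS, numeric(1)))]]
  pEF <- rdsExposure(sc@transcript, rds, NULL, be)
  pES <- rdsExposure(sc@transcript, rds, site, be)
  expect_gt(probability(pES), probability(pEF))
})
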