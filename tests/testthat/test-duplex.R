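# Ribosome site search, sRNA site enumeration, overlap and filter semantics.

test_that("start-codon bonus matches the published values", {
  expect_equal(startCodonBonus("AUG"), -1.19)
  expect_equal(startCodonBonus("GUG"), -0.075)
  expect_equal(startCodonBonus("UUG"), 0)
  expect_equal(startCodonBonus("CUG"), 0)
  expect_error(startCodonBonus("ANG"), "RNA")
})

test_that("findRRS locates a planted motif and adds the codon bonus", {
  tr <- plantedTranscript()
  be <- nnBackend()
  rds <- findRRS(tr, be)
  expect_s4_class(rds, "RibosomeSite")
  expect_identical(rds@rrsRelStart, -12L)
  expect_identical(rds@rrsRelEnd, -3L)
  expect_identical(rds@rdsRelStart, -12L)
  expect_identical(rds@rdsRelEnd, 18L)
  expect_identical(relWidth(rdsInterval(rds)), 30L)
  # the energy equals the closed-form perfect-helix energy plus the AUG bonus
  expected <- perfectHelixEnergy("UCACCUCCUU") + startCodonBonus("AUG")
  expect_equal(deltaGR(rds), expected, tolerance = 1e-12)
})

test_that("poly-A transcripts have no RRS", {
  tr <- Transcript("polyA", strrep("A", 100), startPos = 61)
  expect_null(findRRS(tr, nnBackend()))
})

test_that("duplex DP equals exhaustive alignment enumeration on small cases", {
  p <- energyParams()
  p$dup_gap_cap <- 2L
  be <- nnBackend(params = p)
  set.seed(11)
  for (k in 1:10) {
    target <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    query <- paste(sample(c("A", "C", "G", "U"), 6, TRUE), collapse = "")
    hit <- duplexBest(be, target, query, cutoff = 1e9)
    dp <- if (is.null(hit)) Inf else hit$energy
    expect_equal(dp, bruteForceDuplexEnergy(target, query, p, gapCap = 2),
                 tolerance = 1e-9)
  }
})

test_that("a planted perfect complement is recovered as a binding site", {
  tr <- plantedTranscript(utr = 120, cds = 60)
  # distinctive 14-nt site centred near -60 (abs 55..68) so the repetitive
  # background offers no competing complementarity
  v <- strsplit(transcriptSeq(tr), "")[[1]]
  v[55:68] <- strsplit("GCAUCGAUCCGGUA", "")[[1]]
  tr <- Transcript("toy", paste(v, collapse = ""), startPos = 121)
  seg <- substr(transcriptSeq(tr), 55, 68)
  srna <- rnaReverseComplement(seg)
  sites <- findSrnaSites(srna, tr, nnBackend())
  expect_gte(length(sites), 1L)
  s <- sites[[1L]]
  expect_lte(s@mrnaRelStart, absoluteToRelative(tr, 55L))
  expect_gte(s@mrnaRelEnd, absoluteToRelative(tr, 68L))
  expect_lte(deltaGS(s), -7)
  expect_gte(s@lengthNt, 10L)
})

test_that("overlap detection counts shared nucleotides inclusively", {
  rds <- new("RibosomeSite", rrsRelStart = -15L, rrsRelEnd = -6L,
             rdsRelStart = -15L, rdsRelEnd = 15L, deltaGR = -10,
             duplexEnergy = -10, codonBonus = 0)
  expect_true(overlapsRDS(rds, mkSite(-12, 18, -10)))
  expect_false(overlapsRDS(rds, mkSite(-133, -94, -10)))
  expect_true(overlapsRDS(rds, mkSite(15, 30, -10)))    # single shared base
  expect_false(overlapsRDS(rds, mkSite(16, 30, -10)))
})

test_that("filter boundaries are exact and filters are monotone", {
  w <- relativeInterval(-150, 20)
  sites <- list(
    mkSite(-60, -47, -6.9),          # energy above cutoff: out
    mkSite(-60, -47, -7.0),          # exactly at cutoff: in
    mkSite(-30, -22, -12, lenNt = 9),  # 9 nt: out
    mkSite(-30, -21, -12, lenNt = 10), # exactly 10 nt: in
    mkSite(-151, -140, -12),         # leaks past -150: out
    mkSite(-150, -139, -12),         # starts exactly at -150: in
    mkSite(10, 21, -12),             # leaks past +20: out
    mkSite(9, 20, -12)               # ends exactly at +20: in
  )
  kept <- filterSites(sites, w)
  expect_identical(vapply(kept, function(s) s@mrnaRelStart, integer(1)),
                   c(-60L, -30L, -150L, 9L))
  # relaxing the cutoff or the length threshold never removes a site
  relaxedE <- filterSites(sites, w, energyCutoff = -5)
  expect_true(all(vapply(kept, function(s) any(vapply(relaxedE, identical,
    logical(1), s)), logical(1))))
  relaxedL <- filterSites(sites, w, minLen = 8)
  expect_true(all(vapply(kept, function(s) any(vapply(relaxedL, identical,
    logical(1), s)), logical(1))))
})
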