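# Per-site evaluation, whole-set screening, reporting, determinism.

test_that("classification is a pure threshold function of alpha", {
  expect_identical(classifyAlpha(c(-2.9, -2, -1.99, 1, 1.99, 2, 13.5)),
                   c("repressed", "repressed", "no_effect", "no_effect",
                     "no_effect", "activated", "activated"))
  expect_identical(classifyAlpha(-1.5, threshold = 1.2), "repressed")
})

test_that("evaluateSite fills a complete record for both topologies", {
  set <- getFixtureSet()
  be <- nnBackend()
  cfg <- screenConfig()
  conc <- concentrationSet(60, 40, availableRibosomes(), 20)
  for (lab in c("repression", "activation")) {
    sc <- set[[lab]]
    rds <- findRRS(sc@transcript, be)
    sites <- findSrnaSites(sc@srna, sc@transcript, be)
    s <- sites[[which.min(vapply(sites, deltaGS, numeric(1)))]]
    rec <- evaluateSite(sc@transcript, sc@srna, s, rds, conc, cfg, be)
    expect_identical(rec$call, sc@expectedCall)
    expect_identical(rec$topology, sc@expectedTopology)
    expect_true(abs(rec$alpha) >= 2)
    expect_true(rec$P_EF > 0 && rec$P_EF <= 1)
    if (rec$topology == "nonoverlap") expect_false(is.na(rec$P_ES))
    expect_equal(rec$alpha, foldChange(rec$m_TA_with, rec$m_TA_without))
  }
})

test_that("an sT = 0 override yields alpha = +1 and no effect", {
  sc <- getFixtureSet()$repression
  be <- nnBackend()
  rds <- findRRS(sc@transcript, be)
  s <- findSrnaSites(sc@srna, sc@transcript, be)[[1]]
  conc <- concentrationSet(60, 0, availableRibosomes(), 20)
  rec <- evaluateSite(sc@transcript, sc@srna, s, rds, conc, screenConfig(), be)
  expect_identical(rec$alpha, 1)
  expect_identical(rec$call, "no_effect")
})

test_that("screen flags exactly the planted genes and skips with reasons", {
  set <- getFixtureSet()
  trs <- getFixtureTranscripts()
  expr <- fixtureExpression(set)
  for (lab in c("repression", "activation", "upstream_weak")) {
    res <- screen(set[[lab]]@srna, trs, expr)
    expect_identical(flaggedGenes(res),
                     transcriptId(set[[lab]]@transcript))
  }
  # a poly-A sRNA finds no sites anywhere and flags nothing
  resA <- screen(strrep("A", 30), trs, expr)
  expect_length(flaggedGenes(resA), 0L)
  # missing expression and zero expression become skipped records
  expr2 <- expr[expr$gene_id != "fix_null", ]
  expr2$copies_per_cell[expr2$gene_id == "fix_activation"] <- 0
  res2 <- screen(set$repression@srna, trs, expr2)
  expect_identical(res2$reason[res2$gene_id == "fix_null"],
                   "no expression data")
  expect_identical(res2$reason[res2$gene_id == "fix_activation"],
                   "no transcription")
})

test_that("the effective site can be weaker than the best-energy site", {
  set <- getFixtureSet()
  sc <- set$upstream_weak
  res <- screen(sc@srna, list(sc@transcript),
                fixtureExpression(set["upstream_weak"]))
  ok <- res[!is.na(res$alpha), ]
  expect_gte(nrow(ok), 2L)
  best <- ok[which.min(ok$delta_G_S), ]   # energetically best site
  expect_identical(best$call, "no_effect")
  expect_identical(best$topology, "nonoverlap")
  eff <- ok[ok$call == "repressed", ]
  expect_gte(nrow(eff), 1L)
  expect_true(all(eff$delta_G_S > best$delta_G_S))
  expect_true(all(eff$topology == "overlap"))
})

test_that("results write with a config header and re-write byte-identically", {
  set <- getFixtureSet()
  res <- screen(set$repression@srna, getFixtureTranscripts(),
                fixtureExpression(set))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  writeScreenResults(res, p1)
  hdr <- attr(readScreenResults(p1), "config_lines")
  expect_true(any(grepl("^anti_rrs=UCACCUCCUU$", hdr)))
  expect_true(any(grepl("^energy_cutoff=-7$", hdr)))
  back <- readScreenResults(p1)
  expect_identical(nrow(back), nrow(res))
  writeScreenResults(back, p2, config = hdr)
  expect_identical(readLines(p1), readLines(p2))
  # empty record sets produce a header-only file
  p3 <- file.path(dir, "empty.tsv")
  writeScreenResults(res[0, ], p3, config = attr(res, "config"))
  expect_identical(nrow(readScreenResults(p3)), 0L)
})

test_that("screening is deterministic", {
  set <- getFixtureSet()
  trs <- getFixtureTranscripts()
  expr <- fixtureExpression(set)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.tsv"); p2 <- file.path(dir, "r2.tsv")
  writeScreenResults(screen(set$repression@srna, trs, expr), p1)
  writeScreenResults(screen(set$repression@srna, trs, expr), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reclassification under a changed threshold needs no recomputation", {
  set <- getFixtureSet()
  res <- screen(set$repression@srna, getFixtureTranscripts(),
                fixtureExpression(set))
  a <- res$alpha[!is.na(res$alpha)]
  expect_identical(classifyAlpha(a, threshold = 1e9),
                   rep("no_effect", length(a)))
  strict <- flaggedGenes(res, threshold = 1e9)
  expect_length(strict, 0L)
})
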