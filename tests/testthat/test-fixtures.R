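# Fixture generators: determinism, planted geometry, self-verification.

test_that("fixture generation is deterministic in the seed", {
  a <- makeNullFixture(3)
  b <- makeNullFixture(3)
  expect_identical(transcriptSeq(a@transcript), transcriptSeq(b@transcript))
  expect_identical(a@srna, b@srna)
  expect_identical(a@seed, 3L)
})

test_that("planted scenarios carry their advertised geometry", {
  set <- getFixtureSet()
  r <- set$repression
  expect_identical(r@expectedTopology, "overlap")
  expect_identical(startCodon(r@transcript), "AUG")
  # the anti-RRS complement sits at (-12)..(-3)
  a <- relativeToAbsolute(r@transcript, -12L)
  expect_identical(substr(transcriptSeq(r@transcript), a, a + 9L),
                   rnaReverseComplement("UCACCUCCUU"))
  act <- set$activation
  expect_identical(act@expectedTopology, "nonoverlap")
  expect_false(overlapsRDS(findRRS(act@transcript, nnBackend()),
                           mkSite(relStart(act@plantedSite),
                                  relEnd(act@plantedSite), -10)))
})

test_that("the null scenario yields no sites end to end", {
  sc <- getFixtureSet()$null
  sites <- findSrnaSites(sc@srna, sc@transcript, nnBackend())
  expect_length(sites, 0L)
  res <- screen(sc@srna, list(sc@transcript),
                data.frame(gene_id = transcriptId(sc@transcript),
                           copies_per_cell = sc@mT))
  expect_identical(nrow(res), 0L)
  expect_length(flaggedGenes(res), 0L)
})

test_that("every scenario reproduces its expected call under default config", {
  set <- getFixtureSet()
  trs <- getFixtureTranscripts()
  expr <- fixtureExpression(set)
  for (sc in set) {
    res <- screen(sc@srna, trs, expr)
    gid <- transcriptId(sc@transcript)
    if (sc@expectedCall == "no_sites") {
      expect_false(gid %in% res$gene_id)
    } else {
      expect_true(sc@expectedCall %in% res$call[res$gene_id == gid])
      expect_identical(flaggedGenes(res), gid)
    }
  }
})

test_that("a written fixture set reloads into an equivalent screen input", {
  dir <- withr::local_tempdir()
  writeFixtureSet(dir, seed = 1)
  trs <- loadTranscripts(file.path(dir, "transcripts.fa"),
                         file.path(dir, "starts.tsv"))
  expect_length(trs, 4L)
  counts <- readCountsTable(file.path(dir, "counts.tsv"))
  expr <- computeExpression(counts, totalMapped = 1e6, rrnaIds = "rrsA_16S")
  got <- expr$copies_per_cell[match("fix_repression", expr$gene_id)]
  expect_equal(got, 60, tolerance = 1e-9)
  set <- getFixtureSet()
  expect_identical(transcriptSeq(trs$fix_activation),
                   transcriptSeq(set$activation@transcript))
  srnas <- Biostrings::readBStringSet(file.path(dir, "srnas.fa"))
  expect_identical(as.character(srnas[["srna_null"]]), set$null@srna)
  expected <- utils::read.delim(file.path(dir, "expected.tsv"))
  expect_identical(expected$expected_call,
                   c("repressed", "activated", "no_sites", "repressed"))
})
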