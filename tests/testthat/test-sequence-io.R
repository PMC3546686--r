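# Coordinate conventions, FASTA/annotation loading, window extraction.

test_that("transcripts are constructed, normalised and validated", {
  tr <- Transcript("toy", "AAAATGGCT", startPos = 4)
  expect_s4_class(tr, "Transcript")
  expect_identical(transcriptSeq(tr), "AAAAUGGCU")  # DNA mapped to RNA
  expect_identical(startCodon(tr), "AUG")
  expect_error(Transcript("bad", "AANAUGGCU", startPos = 5), "non-RNA")
  expect_error(Transcript("bad", "AUG", startPos = 2), "startPos")
  # a non-start codon is retained but flagged
  odd <- Transcript("odd", "AAACCCGGG", startPos = 4)
  expect_false(odd@startValid)
})

test_that("relative/absolute conversion is a bijection with no position 0", {
  tr <- Transcript("toy", strrep("A", 200), startPos = 101)
  expect_identical(relativeToAbsolute(tr, 1L), 101L)
  expect_identical(relativeToAbsolute(tr, -1L), 100L)
  expect_identical(relativeToAbsolute(tr, 4L), 104L)
  expect_error(relativeToAbsolute(tr, 0L), "no position 0")
  rels <- c(-100:-1, 1:100)
  expect_identical(absoluteToRelative(tr, relativeToAbsolute(tr, rels)), rels)
  abss <- 1:200
  expect_identical(relativeToAbsolute(tr, absoluteToRelative(tr, abss)), abss)
  # strict monotonicity across the 0 gap
  expect_true(all(diff(relativeToAbsolute(tr, rels)) == 1L))
})

test_that("window extraction clips with flags and matches direct slicing", {
  tr <- Transcript("toy", paste0(strrep("A", 150), "AUG", strrep("C", 20)),
                   startPos = 151)
  w <- extractWindow(tr, relativeInterval(-150, 20))
  expect_identical(nchar(w$seq), 170L)
  expect_false(w$clipped5 || w$clipped3)
  short <- Transcript("short", paste0(strrep("A", 10), "AUG", strrep("C", 20)),
                      startPos = 11)
  ws <- extractWindow(short, relativeInterval(-150, 20))
  expect_identical(nchar(ws$seq), 30L)
  expect_true(ws$clipped5)
  expect_false(ws$clipped3)
  codon <- extractWindow(tr, relativeInterval(1, 3))
  expect_identical(codon$seq, "AUG")
  # single-position lookups concatenate to the window slice
  rels <- setdiff(-5:5, 0)
  pieces <- vapply(rels, function(r) {
    substr(transcriptSeq(tr), relativeToAbsolute(tr, r),
           relativeToAbsolute(tr, r))
  }, character(1))
  expect_identical(paste(pieces, collapse = ""),
                   extractWindow(tr, relativeInterval(-5, 5))$seq)
  # fully outside -> empty and flagged, not an error
  off <- extractWindow(short, relativeInterval(-200, -150))
  expect_identical(off$seq, "")
  expect_true(off$clipped5)
})

test_that("FASTA + annotation round-trips and missing records are named", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fa"); ann <- file.path(dir, "t.tsv")
  t1 <- Transcript("geneA", paste0(strrep("A", 30), "AUG", strrep("C", 30)),
                   startPos = 31)
  t2 <- Transcript("geneB", paste0(strrep("G", 10), "GUG", strrep("U", 12)),
                   startPos = 11)
  writeTranscripts(list(t1, t2), fa, ann)
  back <- loadTranscripts(fa, ann)
  expect_named(back, c("geneA", "geneB"))
  expect_identical(transcriptSeq(back$geneA), transcriptSeq(t1))
  expect_identical(startPos(back$geneB), 11L)
  # annotation covering only one record errors naming the other
  writeLines("geneA\t30", file.path(dir, "partial.tsv"))
  expect_error(loadTranscripts(fa, file.path(dir, "partial.tsv")), "geneB")
})

test_that("relative intervals reject position 0 and count widths correctly", {
  expect_error(relativeInterval(0, 5), "no position 0")
  expect_error(relativeInterval(-3, 0), "no position 0")
  expect_identical(relWidth(relativeInterval(-12, 18)), 30L)  # spans the gap
  expect_identical(relWidth(relativeInterval(1, 3)), 3L)
  expect_identical(relWidth(relativeInterval(-10, -1)), 10L)
})
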