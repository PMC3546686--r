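# RPKM, 16S-scale copy numbers and concentration defaults.

test_that("rpkm computes reads per kilobase per million and validates input", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(50, 2000, 5e6), 5)
  expect_equal(rpkm(2.5, 1000, 1e6), 2.5)   # fractional multimapper weights
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 100, 0), "mapped")
})

test_that("copies are linear on the 16S scale", {
  expect_equal(copiesFromRpkm(50, 50), 57000)
  expect_equal(copiesFromRpkm(0, 50), 0)
  expect_equal(copiesFromRpkm(50 / 57000, 50), 1)
  expect_equal(copiesFromRpkm(7, 50), 7 * copiesFromRpkm(1, 50))
  expect_error(copiesFromRpkm(1, 0), "rrnaRpkmSum")
})

test_that("ribosome availability and sRNA defaults use the stated constants", {
  expect_identical(availableRibosomes(), 11400)
  expect_equal(availableRibosomes(57000, 0), 57000)
  expect_equal(availableRibosomes(1000, 0.5), 500)
  expect_error(availableRibosomes(57000, 1), "busyFraction")
  expect_equal(defaultSrnaCopies(300), 200)
  expect_equal(defaultSrnaCopies(0), 0)
  expect_equal(defaultSrnaCopies(60, 0.84), 50.4)  # empirical ratio variant
  expect_error(defaultSrnaCopies(10, -1), "ratio")
})

test_that("the expression table is scale-invariant and recomputable", {
  counts <- data.frame(gene_id = c("a", "b", "rrs1", "rrs2"),
                       length_nt = c(900, 1500, 1542, 1542),
                       count = c(120, 40.5, 800, 700))
  e1 <- computeExpression(counts, rrnaIds = c("rrs1", "rrs2"))
  expect_equal(e1$rpkm,
               rpkm(counts$count, counts$length_nt, sum(counts$count)))
  expect_equal(e1$copies_per_cell[1],
               copiesFromRpkm(e1$rpkm[1], attr(e1, "rrna_rpkm_sum")))
  # doubling all counts and the library size changes nothing
  counts2 <- counts; counts2$count <- counts2$count * 2
  e2 <- computeExpression(counts2, rrnaIds = c("rrs1", "rrs2"))
  expect_equal(e2$rpkm, e1$rpkm)
  expect_equal(e2$copies_per_cell, e1$copies_per_cell)
  expect_error(computeExpression(counts), "rrnaIds or rrnaRpkmSum")
})

test_that("counts tables round-trip through the TSV reader", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = c("x", "y"), length_nt = c(100, 200),
                   count = c(5, 2.5))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readCountsTable(path)
  expect_equal(back$count, df$count)
  expect_equal(back$length_nt, df$length_nt)
  # headerless files are detected too
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  expect_equal(readCountsTable(path)$count, df$count)
})
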