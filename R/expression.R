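## Read counts -> RPKM -> per-cell copy numbers on the 16S rRNA scale.

#' Reads per kilobase per million mapped reads
#'
#' `count / ((length_nt/1000) * (total_mapped/1e6))`.  Fractional counts are
#' accepted so that multi-mapping reads weighted `1/n` at mapping time are
#' representable.
#'
#' @param count mapped reads assigned to the gene (possibly fractional).
#' @param lengthNt gene length in nucleotides (> 0).
#' @param totalMapped total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 1000, 1e6)
#' @export
rpkm <- function(count, lengthNt, totalMapped) {
  if (any(lengthNt <= 0)) stop("gene length must be > 0")
  if (any(totalMapped <= 0)) stop("total mapped reads must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  count / ((lengthNt / 1000) * (totalMapped / 1e6))
}

#' Copies per cell from RPKM on the 16S scale
#'
#' Normalises a gene's RPKM by the summed RPKM of the 16S rRNA genes and
#' scales by the total number of 16S rRNA molecules per cell (57,000 by
#' default), yielding the copy-number estimate the equilibrium model uses.
#'
#' @param geneRpkm gene RPKM value(s).
#' @param rrnaRpkmSum summed 16S rRNA RPKM (> 0).
#' @param total16S total 16S rRNA copies per cell.
#' @return copies per cell.
#' @examples
#' copiesFromRpkm(50, 50)      # the 16S scale itself
#' @export
copiesFromRpkm <- function(geneRpkm, rrnaRpkmSum, total16S = 57000) {
  if (rrnaRpkmSum <= 0) stop("rrnaRpkmSum must be > 0")
  geneRpkm / rrnaRpkmSum * total16S
}

#' Ribosomes available for initiation
#'
#' Most ribosomes are engaged in elongation at any moment; only the idle
#' fraction is available for new initiation events:
#' `(1 - busyFraction) * total16S`.
#'
#' @param total16S total ribosome (16S rRNA) copies per cell.
#' @param busyFraction fraction actively translating, in [0, 1).
#' @return available ribosome copies (`r_T`).
#' @examples
#' availableRibosomes()        # 11400
#' @export
availableRibosomes <- function(total16S = 57000, busyFraction = 0.80) {
  if (busyFraction < 0 || busyFraction >= 1)
    stop("busyFraction must be in [0, 1)")
  # subtracting the busy pool keeps round copy numbers exact (0.2 * 57000
  # is not representable, 57000 - 0.8 * 57000 is)
  total16S - busyFraction * total16S
}

#' Default sRNA copy number
#'
#' When the sRNA is not expressed in the underlying experiment, its active
#' concentration is estimated as a fixed ratio of the target mRNA
#' (`2/3` by default).
#'
#' @param mT target mRNA copies per cell.
#' @param ratio sRNA/mRNA copy ratio (>= 0).
#' @return sRNA copies per cell (`s_T`).
#' @examples
#' defaultSrnaCopies(300)
#' @export
defaultSrnaCopies <- function(mT, ratio = 2 / 3) {
  if (ratio < 0) stop("ratio must be >= 0")
  if (any(mT < 0)) stop("mT must be >= 0")
  ratio * mT
}

#' Read a counts table
#'
#' Three-column TSV: `gene_id <tab> length_nt <tab> count` (header optional,
#' detected; counts may be fractional).
#'
#' @param path file path.
#' @return a data.frame with columns `gene_id`, `length_nt`, `count`.
#' @export
readCountsTable <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\S+\t[0-9.]+\t[0-9.eE+-]+$", first) ||
    grepl("gene", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("counts table needs >= 3 columns")
  df <- df[, 1:3]
  names(df) <- c("gene_id", "length_nt", "count")
  df$length_nt <- as.numeric(df$length_nt)
  df$count <- as.numeric(df$count)
  df
}

#' Compute the expression table
#'
#' Adds RPKM and per-cell copy numbers to a counts table.  The 16S scale is
#' fixed either by naming the rRNA rows (`rrnaIds`) whose RPKM values are
#' summed, or by passing `rrnaRpkmSum` directly.  Genes with zero counts get
#' zero copies; the screening stage skips them (the fold change is undefined
#' at `m_T = 0`).
#'
#' @param counts data.frame with `gene_id`, `length_nt`, `count`.
#' @param totalMapped total mapped reads; defaults to `sum(count)`.
#' @param rrnaIds gene ids of the 16S rRNA rows.
#' @param rrnaRpkmSum summed 16S RPKM, overrides `rrnaIds`.
#' @param total16S total 16S copies per cell.
#' @return the input data.frame with `rpkm` and `copies_per_cell` columns and
#'   attributes `total_mapped_reads`, `rrna_rpkm_sum`, `scale_total_16s`.
#' @export
computeExpression <- function(counts, totalMapped = NULL, rrnaIds = NULL,
                              rrnaRpkmSum = NULL, total16S = 57000) {
  if (is.null(totalMapped)) totalMapped <- sum(counts$count)
  counts$rpkm <- rpkm(counts$count, counts$length_nt, totalMapped)
  if (is.null(rrnaRpkmSum)) {
    if (is.null(rrnaIds))
      stop("provide rrnaIds or rrnaRpkmSum to fix the 16S scale")
    rows <- counts$gene_id %in% rrnaIds
    if (!any(rows)) stop("none of the rrnaIds found in the counts table")
    rrnaRpkmSum <- sum(counts$rpkm[rows])
  }
  counts$copies_per_cell <- copiesFromRpkm(counts$rpkm, rrnaRpkmSum, total16S)
  attr(counts, "total_mapped_reads") <- totalMapped
  attr(counts, "rrna_rpkm_sum") <- rrnaRpkmSum
  attr(counts, "scale_total_16s") <- total16S
  counts
}
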