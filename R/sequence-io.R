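## FASTA + annotation loading and the relative coordinate convention.

#' Convert between relative and absolute coordinates
#'
#' Relative coordinates have no position 0: +1 is the first base of the start
#' codon and -1 the base immediately upstream.  Absolute coordinates are
#' 1-based indices into the transcript sequence, so
#' `relativeToAbsolute(t, +1) == startPos(t)`.
#'
#' @param t a [Transcript-class].
#' @param rel relative position(s); must not be 0.
#' @param abs absolute position(s), 1-based.
#' @return integer positions in the other convention.
#' @examples
#' tr <- Transcript("toy", strrep("A", 50), startPos = 21)
#' relativeToAbsolute(tr, c(-1, 1, 4))
#' absoluteToRelative(tr, 21)
#' @export
relativeToAbsolute <- function(t, rel) {
  rel <- as.integer(rel)
  if (any(rel == 0L)) stop("the relative convention has no position 0")
  ifelse(rel > 0L, startPos(t) + rel - 1L, startPos(t) + rel)
}

#' @rdname relativeToAbsolute
#' @export
absoluteToRelative <- function(t, abs) {
  abs <- as.integer(abs)
  d <- abs - startPos(t)
  ifelse(d >= 0L, d + 1L, d)
}

#' Load transcripts from FASTA plus a start annotation
#'
#' Reads a (possibly multi-record) FASTA file, normalises DNA to RNA
#' (`T` mapped to `U`) and attaches the translation start of each record.
#' The annotation is either the path to a two/three-column TSV
#' (`id <tab> start_offset_0based`, extra columns ignored) or a named integer
#' vector of 0-based start offsets.  Every record must be annotated.
#' Records whose annotated codon is not a standard start codon are retained
#' but flagged (see [Transcript()]).
#'
#' @param fasta path to a FASTA file.
#' @param annotation path to the annotation TSV, or a named integer vector of
#'   0-based start offsets.
#' @return a named list of [Transcript-class] objects.
#' @export
loadTranscripts <- function(fasta, annotation) {
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) stop("no records in ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", fasta)
  if (is.character(annotation) && length(annotation) == 1L) {
    ann <- utils::read.delim(annotation, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    offsets <- stats::setNames(as.integer(ann[[2L]]), as.character(ann[[1L]]))
  } else {
    if (is.null(names(annotation)))
      stop("annotation vector must be named by record id")
    offsets <- stats::setNames(as.integer(annotation), names(annotation))
  }
  missing <- setdiff(ids, names(offsets))
  if (length(missing))
    stop("no start annotation for record(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_along(ids), function(i) {
    Transcript(ids[i], as.character(seqs[[i]]),
               startPos = offsets[[ids[i]]] + 1L, source = fasta)
  })
  stats::setNames(out, ids)
}

#' Extract a window around the translation start
#'
#' Returns the subsequence covered by a relative interval, clipped to the
#' transcript bounds.  Clipping is flagged, not an error: a window entirely
#' outside the transcript yields an empty sequence with both flags set as
#' appropriate.
#'
#' @param t a [Transcript-class].
#' @param w a [RelativeInterval-class].
#' @return a list with elements `seq` (the clipped subsequence), `absStart`,
#'   `absEnd` (1-based bounds; `NA` when empty), `clipped5`, `clipped3`.
#' @examples
#' tr <- Transcript("toy", paste0(strrep("A", 20), "AUGGCU"), startPos = 21)
#' extractWindow(tr, relativeInterval(1, 3))$seq   # the start codon
#' @export
extractWindow <- function(t, w) {
  n <- nchar(transcriptSeq(t))
  a <- relativeToAbsolute(t, relStart(w))
  b <- relativeToAbsolute(t, relEnd(w))
  clipped5 <- a < 1L
  clipped3 <- b > n
  a2 <- max(a, 1L)
  b2 <- min(b, n)
  if (a2 > b2) {
    return(list(seq = "", absStart = NA_integer_, absEnd = NA_integer_,
                clipped5 = clipped5, clipped3 = clipped3))
  }
  list(seq = substr(transcriptSeq(t), a2, b2),
       absStart = a2, absEnd = b2, clipped5 = clipped5, clipped3 = clipped3)
}

#' Write transcripts and annotation
#'
#' Inverse of [loadTranscripts()]: writes a wrapped FASTA plus the
#' two-column 0-based start-offset TSV.
#'
#' @param transcripts a list of [Transcript-class] objects.
#' @param fasta,annotation output paths.
#' @return invisibly, the two paths.
#' @export
writeTranscripts <- function(transcripts, fasta, annotation) {
  con <- file(fasta, "w")
  on.exit(close(con))
  for (t in transcripts) {
    writeLines(paste0(">", transcriptId(t)), con)
    s <- transcriptSeq(t)
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  ann <- data.frame(id = vapply(transcripts, transcriptId, character(1)),
                    offset = vapply(transcripts, startPos, integer(1)) - 1L)
  utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta, annotation))
}
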