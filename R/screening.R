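## Per-site evaluation, whole-input screening, reporting.

#' Classify a fold change
#'
#' Pure function of the fold change and the threshold: `repressed` when
#' `alpha <= -threshold`, `activated` when `alpha >= threshold`, otherwise
#' `no_effect`.
#'
#' @param alpha signed fold change(s).
#' @param threshold positive classification threshold (default 2).
#' @return character vector of calls.
#' @examples
#' classifyAlpha(c(-2.9, 1.0007, 13.5))
#' @export
classifyAlpha <- function(alpha, threshold = 2) {
  ifelse(alpha <= -threshold, "repressed",
         ifelse(alpha >= threshold, "activated", "no_effect"))
}

.emptyRecord <- function(geneId, reason = NA_character_) {
  tmpl <- data.frame(gene_id = NA_character_,
             site_rel_start = NA_integer_, site_rel_end = NA_integer_,
             srna_start = NA_integer_, srna_end = NA_integer_,
             site_len = NA_integer_, topology = NA_character_,
             delta_G_R = NA_real_, delta_G_S = NA_real_,
             hybrid_energy = NA_real_, P_EF = NA_real_, P_ES = NA_real_,
             m_T = NA_real_, s_T = NA_real_, r_T = NA_real_, n = NA_real_,
             m_TA_with = NA_real_, m_TA_without = NA_real_,
             alpha = NA_real_, call = "skipped", reason = NA_character_,
             stringsAsFactors = FALSE)
  out <- tmpl[rep(1L, length(geneId)), , drop = FALSE]
  rownames(out) <- NULL
  out$gene_id <- geneId
  out$reason <- rep_len(reason, length(geneId))
  out
}

#' Evaluate one binding site
#'
#' Runs the full model for a single sRNA binding site: decides the topology
#' from the overlap with the ribosome docking site, computes the exposure
#' probabilities (`P_ES` only for the non-overlap topology), converts the
#' hybridisation energies into binding constants, solves the matching
#' equilibrium with and without sRNA and classifies the signed fold change.
#' Failures become `skipped` records with a reason, never errors.
#'
#' @param t a [Transcript-class].
#' @param srna sRNA sequence.
#' @param site a [BindingSite-class] on `t`.
#' @param rds the transcript's [RibosomeSite-class].
#' @param conc a [ConcentrationSet-class].
#' @param config a [ScreenConfig-class].
#' @param backend an energy backend.
#' @param pEF optionally a precomputed unconstrained
#'   [AccessibilityResult-class] (cached across sites of one transcript).
#' @return a one-row data.frame (one ScreenRecord).
#' @export
evaluateSite <- function(t, srna, site, rds, conc, config = screenConfig(),
                         backend = nnBackend(config@temperature),
                         pEF = NULL) {
  rec <- .emptyRecord(transcriptId(t))
  rec$site_rel_start <- site@mrnaRelStart
  rec$site_rel_end <- site@mrnaRelEnd
  rec$srna_start <- site@srnaStart
  rec$srna_end <- site@srnaEnd
  rec$site_len <- site@lengthNt
  rec$delta_G_R <- deltaGR(rds)
  rec$delta_G_S <- deltaGS(site)
  rec$hybrid_energy <- site@hybridEnergy
  rec$m_T <- conc@mT; rec$s_T <- conc@sT; rec$r_T <- conc@rT; rec$n <- conc@n
  out <- tryCatch({
    if (is.null(pEF)) pEF <- rdsExposure(t, rds, NULL, backend, config@flank)
    topo <- if (overlapsRDS(rds, site)) "overlap" else "nonoverlap"
    rec$topology <- topo
    rec$P_EF <- probability(pEF)
    if (rec$P_EF <= 0) stop("untranslatable baseline")
    kR <- energyToConstant(deltaGR(rds), config@temperature)
    kS <- energyToConstant(deltaGS(site), config@temperature)
    base <- solveNoSrna(kR, rec$P_EF, conc@mT, conc@rT, conc@n)
    if (base <= 0) stop("untranslatable baseline")
    pES <- NA_real_
    if (topo == "nonoverlap") {
      pES <- probability(rdsExposure(t, rds, site, backend, config@flank))
      rec$P_ES <- pES
    }
    p <- equilibriumParams(kR = kR, kS = kS, pEF = rec$P_EF, pES = pES,
                           mT = conc@mT, sT = conc@sT, rT = conc@rT,
                           n = conc@n, topology = topo)
    withS <- activeMrna(solveEquilibrium(p))
    rec$m_TA_without <- base
    rec$m_TA_with <- withS
    rec$alpha <- foldChange(withS, base)
    rec$call <- classifyAlpha(rec$alpha, config@alphaThreshold)
    rec$reason <- NA_character_
    rec
  }, error = function(e) {
    rec$call <- "skipped"
    rec$reason <- conditionMessage(e)
    rec$alpha <- NA_real_
    rec
  })
  out
}

#' Screen an sRNA against a set of transcripts
#'
#' For every transcript: locate the ribosome recognition site, enumerate the
#' filtered sRNA binding sites and evaluate **every** surviving site
#' independently (the energetically best site is not always the effective
#' one).  Genes without expression, without transcription or without an RRS
#' yield `skipped` records; genes with an RRS but no surviving site yield no
#' records.  The result is deterministic: identical inputs and configuration
#' produce identical tables.
#'
#' @param srna sRNA sequence.
#' @param transcripts list of [Transcript-class] objects.
#' @param expression expression table from [computeExpression()], or a data
#'   frame with `gene_id` and `copies_per_cell`.
#' @param config a [ScreenConfig-class].
#' @param backend energy backend; defaults to the builtin model at the
#'   configured temperature.
#' @param srnaId optional id of the sRNA in the expression table; used for
#'   the measured copy number when `config@useMeasuredSrna` is set.
#' @return a data.frame of ScreenRecords, sorted by gene then `delta_G_S`,
#'   with the configuration attached as attribute `config`.
#' @export
screen <- function(srna, transcripts, expression, config = screenConfig(),
                   backend = nnBackend(config@temperature), srnaId = NULL) {
  srna <- toupper(chartr("Tt", "Uu", srna))
  rT <- availableRibosomes(config@total16S, config@busyFraction)
  recs <- list()
  for (t in transcripts) {
    gid <- transcriptId(t)
    row <- match(gid, expression$gene_id)
    if (is.na(row)) {
      recs[[length(recs) + 1L]] <- .emptyRecord(gid, "no expression data")
      next
    }
    mT <- expression$copies_per_cell[row]
    if (mT <= 0) {
      recs[[length(recs) + 1L]] <- .emptyRecord(gid, "no transcription")
      next
    }
    sT <- defaultSrnaCopies(mT, config@ratio)
    if (config@useMeasuredSrna && !is.null(srnaId)) {
      srow <- match(srnaId, expression$gene_id)
      if (!is.na(srow)) sT <- expression$copies_per_cell[srow]
    }
    rds <- findRRS(t, backend, config@antiRRS, config@rrsWindow)
    if (is.null(rds)) {
      recs[[length(recs) + 1L]] <- .emptyRecord(gid, "no RRS")
      next
    }
    sites <- findSrnaSites(srna, t, backend, config@window,
                           config@energyCutoff, config@minLen,
                           config@siteContext, config@maxPairSpan)
    if (length(sites) == 0L) next
    pEF <- rdsExposure(t, rds, NULL, backend, config@flank)
    conc <- concentrationSet(mT, sT, rT, config@n)
    for (s in sites) {
      recs[[length(recs) + 1L]] <-
        evaluateSite(t, srna, s, rds, conc, config, backend, pEF)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else .emptyRecord(character(0))
  out <- out[order(out$gene_id, out$delta_G_S, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Genes flagged as putatively regulated
#'
#' Per-gene verdict: a gene is flagged when **any** of its evaluated sites
#' reaches the fold-change threshold.
#'
#' @param records a ScreenRecord data.frame from [screen()].
#' @param threshold |alpha| threshold (default 2).
#' @return sorted character vector of flagged gene ids.
#' @export
flaggedGenes <- function(records, threshold = 2) {
  hit <- !is.na(records$alpha) & abs(records$alpha) >= threshold
  sort(unique(records$gene_id[hit]))
}

#' @rdname screenConfig
#' @param config a [ScreenConfig-class].
#' @return `configAsStrings`: `key=value` strings describing the full
#'   configuration.
#' @export
configAsStrings <- function(config) {
  c(sprintf("window=%d..%d", relStart(config@window), relEnd(config@window)),
    sprintf("energy_cutoff=%g", config@energyCutoff),
    sprintf("min_len=%d", config@minLen),
    sprintf("rrs_window=%d..%d", relStart(config@rrsWindow),
            relEnd(config@rrsWindow)),
    sprintf("anti_rrs=%s", config@antiRRS),
    sprintf("flank=%d", config@flank),
    sprintf("temperature=%g", config@temperature),
    sprintf("n=%g", config@n),
    sprintf("ratio=%g", config@ratio),
    sprintf("total_16s=%g", config@total16S),
    sprintf("busy_fraction=%g", config@busyFraction),
    sprintf("alpha_threshold=%g", config@alphaThreshold),
    sprintf("site_context=%d", config@siteContext),
    sprintf("max_pair_span=%d", config@maxPairSpan),
    sprintf("backend=%s", config@backendName),
    sprintf("use_measured_srna=%s", config@useMeasuredSrna),
    sprintf("seed=%d", config@seed))
}

#' Write and read screening results
#'
#' Writes a TSV with a `#`-prefixed header block echoing the full run
#' configuration, one row per ScreenRecord.  Fold changes are reported to
#' two decimals; energies to three; probabilities in scientific notation.
#' `readScreenResults()` parses the table back (the configuration header is
#' returned as a character attribute `config_lines`), and writing the parsed
#' table again reproduces the file byte for byte.
#'
#' @param records ScreenRecord data.frame.
#' @param path output path.
#' @param config the [ScreenConfig-class] to echo; defaults to the one
#'   attached to `records`.
#' @return invisibly, `path`.
#' @export
writeScreenResults <- function(records, path,
                               config = attr(records, "config")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    if (is(config, "ScreenConfig")) config <- configAsStrings(config)
    writeLines(paste0("# ", config), con)
  }
  fmt <- function(x, f) ifelse(is.na(x), "NA", sprintf(f, x))
  df <- data.frame(
    gene_id = records$gene_id,
    site_rel_start = fmt(records$site_rel_start, "%d"),
    site_rel_end = fmt(records$site_rel_end, "%d"),
    srna_start = fmt(records$srna_start, "%d"),
    srna_end = fmt(records$srna_end, "%d"),
    site_len = fmt(records$site_len, "%d"),
    topology = ifelse(is.na(records$topology), "NA", records$topology),
    delta_G_R = fmt(records$delta_G_R, "%.3f"),
    delta_G_S = fmt(records$delta_G_S, "%.3f"),
    hybrid_energy = fmt(records$hybrid_energy, "%.3f"),
    P_EF = fmt(records$P_EF, "%.6e"),
    P_ES = fmt(records$P_ES, "%.6e"),
    m_T = fmt(records$m_T, "%.4f"),
    s_T = fmt(records$s_T, "%.4f"),
    r_T = fmt(records$r_T, "%.4f"),
    n = fmt(records$n, "%g"),
    m_TA_with = fmt(records$m_TA_with, "%.6e"),
    m_TA_without = fmt(records$m_TA_without, "%.6e"),
    alpha = fmt(records$alpha, "%.2f"),
    call = records$call,
    reason = ifelse(is.na(records$reason), "", records$reason),
    stringsAsFactors = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' @rdname writeScreenResults
#' @export
readScreenResults <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  tab <- lines[!hdr]
  df <- utils::read.delim(text = paste(tab, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "config_lines") <- sub("^# ", "", lines[hdr])
  df
}
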