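## Ribosome recognition site search and sRNA binding-site enumeration.

#' Start-codon bonus energy
#'
#' Stabilising contribution of the start-codon--anticodon interaction added
#' to the ribosome hybridisation energy: -1.19 kcal/mol for AUG,
#' -0.075 kcal/mol for GUG and 0 for every other codon.
#'
#' @param codon a 3-letter RNA string.
#' @return kcal/mol (<= 0).
#' @examples
#' startCodonBonus("AUG")
#' @export
startCodonBonus <- function(codon) {
  codon <- toupper(chartr("Tt", "Uu", codon))
  if (nchar(codon) != 3L || !is.null(.checkRNAString(codon, "codon")))
    stop("codon must be a 3-letter RNA string")
  switch(codon, AUG = -1.19, GUG = -0.075, 0)
}

# map a relative position to a gapless integer scale (no hole at 0)
.relLinear <- function(rel) ifelse(rel > 0L, rel - 1L, rel)

#' Locate the ribosome recognition site
#'
#' Finds the energetically most favourable duplex of the anti-RRS (the 3'
#' terminal 10 nt of the 16S rRNA, \code{"UCACCUCCUU"} by default) within the
#' search window around the translation start, ignoring intramolecular
#' structure.  The ribosome energy `deltaGR` is the duplex energy plus the
#' start-codon bonus; the 30-nt ribosome docking site starts at the RRS
#' start.  Ties in energy are broken towards the most upstream (5') site.
#'
#' @param t a [Transcript-class].
#' @param backend an energy backend, see [nnBackend()].
#' @param antiRRS anti-RRS sequence.
#' @param searchWindow relative search window (default (-30)..(+3)).
#' @return a [RibosomeSite-class], or `NULL` when no duplex with negative
#'   energy exists in the window (the transcript is then skipped downstream).
#' @examples
#' tr <- Transcript("toy",
#'   paste0(strrep("A", 20), "AAGGAGGUGA", "AAAAAAA", "AUG", strrep("C", 30)),
#'   startPos = 38)
#' findRRS(tr, nnBackend())
#' @export
findRRS <- function(t, backend, antiRRS = "UCACCUCCUU",
                    searchWindow = relativeInterval(-30, 3)) {
  antiRRS <- toupper(chartr("Tt", "Uu", antiRRS))
  win <- extractWindow(t, searchWindow)
  if (nchar(win$seq) == 0L) return(NULL)
  hit <- duplexBest(backend, win$seq, antiRRS, cutoff = 0)
  if (is.null(hit) || hit$energy >= 0) return(NULL)
  rrsAbsStart <- win$absStart + hit$tStart - 1L
  rrsAbsEnd <- win$absStart + hit$tEnd - 1L
  bonus <- startCodonBonus(startCodon(t))
  new("RibosomeSite",
      rrsRelStart = absoluteToRelative(t, rrsAbsStart),
      rrsRelEnd = absoluteToRelative(t, rrsAbsEnd),
      rdsRelStart = absoluteToRelative(t, rrsAbsStart),
      rdsRelEnd = absoluteToRelative(t, rrsAbsStart + 29L),
      deltaGR = hit$energy + bonus, duplexEnergy = hit$energy,
      codonBonus = bonus)
}

#' Do a docking site and a binding site overlap?
#'
#' `TRUE` when the sRNA site shares at least one nucleotide with the 30-nt
#' ribosome docking site, in which case simultaneous binding of ribosome and
#' sRNA is sterically impossible (overlap topology).
#'
#' @param rds a [RibosomeSite-class].
#' @param site a [BindingSite-class].
#' @return logical.
#' @examples
#' # a site touching the RDS at a single position overlaps
#' @export
overlapsRDS <- function(rds, site) {
  a1 <- .relLinear(rds@rdsRelStart); a2 <- .relLinear(rds@rdsRelEnd)
  b1 <- .relLinear(site@mrnaRelStart); b2 <- .relLinear(site@mrnaRelEnd)
  max(a1, b1) <= min(a2, b2)
}

# >50% reciprocal-style overlap used for sub-optimal site deduplication
.spanOverlapFrac <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  ov / min(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Enumerate filtered sRNA binding sites on an mRNA
#'
#' Scans the search window around the translation start for sub-optimal
#' sRNA-mRNA duplexes, corrects each candidate's energy for the cost of
#' opening the interacting regions on both molecules, deduplicates heavily
#' overlapping candidates (same site = mRNA spans overlapping by more than
#' 50% and sharing the sRNA region; the lower-energy one is kept) and applies
#' the standard filters: corrected energy at most `energyCutoff`, mRNA span
#' at least `minLen` nucleotides (interior unpaired bases included), site
#' fully inside the window.  Results are sorted by corrected energy.
#'
#' Accessibility corrections are computed from span-capped partition
#' functions over a local context of `siteContext/2` nt on each side of the
#' site, mirroring windowed accessibility profiles.
#'
#' @param srna sRNA sequence (string).
#' @param t a [Transcript-class].
#' @param backend an energy backend.
#' @param window relative search window (default (-150)..(+20)).
#' @param energyCutoff kcal/mol (default -7).
#' @param minLen minimum mRNA span (default 10 nt).
#' @param siteContext accessibility context width (nt, default 200).
#' @param maxPairSpan maximal intramolecular pair span in the context
#'   (default 150).
#' @return a list of [BindingSite-class] objects (possibly empty), sorted by
#'   `deltaGS`.
#' @export
findSrnaSites <- function(srna, t, backend,
                          window = relativeInterval(-150, 20),
                          energyCutoff = -7, minLen = 10,
                          siteContext = 200, maxPairSpan = 150) {
  srna <- toupper(chartr("Tt", "Uu", srna))
  if (nchar(srna) == 0L) stop("sRNA sequence is empty")
  win <- extractWindow(t, window)
  if (nchar(win$seq) == 0L) return(list())
  raw <- duplexSubopt(backend, win$seq, srna, cutoff = energyCutoff)
  if (length(raw) == 0L) return(list())
  # absolute mRNA coordinates
  for (i in seq_along(raw)) {
    raw[[i]]$absStart <- win$absStart + raw[[i]]$tStart - 1L
    raw[[i]]$absEnd <- win$absStart + raw[[i]]$tEnd - 1L
  }
  # deduplicate on hybrid energy, best first
  raw <- raw[order(vapply(raw, `[[`, numeric(1), "energy"))]
  kept <- list()
  for (cand in raw) {
    dup <- FALSE
    for (k in kept) {
      fm <- .spanOverlapFrac(cand$absStart, cand$absEnd, k$absStart, k$absEnd)
      fs <- .spanOverlapFrac(cand$qStart, cand$qEnd, k$qStart, k$qEnd)
      if (fm > 0.5 && fs > 0.5) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cand
  }
  n <- nchar(transcriptSeq(t))
  flank <- as.integer(siteContext) %/% 2L
  sites <- lapply(kept, function(cand) {
    ctx <- c(max(1L, cand$absStart - flank), min(n, cand$absEnd + flank))
    mOpen <- backendUnpairedProb(backend, substr(transcriptSeq(t), ctx[1], ctx[2]),
                                 interval = c(cand$absStart, cand$absEnd) - ctx[1] + 1L,
                                 maxspan = maxPairSpan)
    sOpen <- backendUnpairedProb(backend, srna,
                                 interval = c(cand$qStart, cand$qEnd),
                                 maxspan = maxPairSpan)
    RT <- backend@params$RT
    dG <- cand$energy - RT * (mOpen$log_prob + sOpen$log_prob)
    new("BindingSite",
        mrnaRelStart = absoluteToRelative(t, cand$absStart),
        mrnaRelEnd = absoluteToRelative(t, cand$absEnd),
        srnaStart = as.integer(cand$qStart), srnaEnd = as.integer(cand$qEnd),
        deltaGS = dG, hybridEnergy = cand$energy,
        lengthNt = cand$absEnd - cand$absStart + 1L,
        srnaSpan = as.integer(cand$qEnd - cand$qStart + 1L),
        pairsMrnaAbs = as.integer(cand$pairsT + win$absStart - 1L),
        pairsSrna = as.integer(cand$pairsQ))
  })
  sites <- filterSites(sites, window, energyCutoff, minLen)
  ord <- order(vapply(sites, deltaGS, numeric(1)),
               vapply(sites, function(s) s@mrnaRelStart, integer(1)))
  sites[ord]
}

#' Apply the standard site filters
#'
#' Pure filter over a list of binding sites: keeps sites with
#' `deltaGS <= energyCutoff`, `lengthNt >= minLen` and both endpoints inside
#' the window (inclusive).  Boundary values pass: a site at exactly the
#' cutoff energy, exactly `minLen` long or ending exactly on a window
#' endpoint is kept.
#'
#' @param sites list of [BindingSite-class] objects.
#' @param window a [RelativeInterval-class].
#' @param energyCutoff kcal/mol.
#' @param minLen nucleotides.
#' @return the filtered list.
#' @export
filterSites <- function(sites, window = relativeInterval(-150, 20),
                        energyCutoff = -7, minLen = 10) {
  keep <- vapply(sites, function(s) {
    s@deltaGS <= energyCutoff &&
      s@lengthNt >= minLen &&
      .relLinear(s@mrnaRelStart) >= .relLinear(relStart(window)) &&
      .relLinear(s@mrnaRelEnd) <= .relLinear(relEnd(window))
  }, logical(1))
  sites[keep]
}
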