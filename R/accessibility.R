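## RDS accessibility: probability that the docking site is entirely unpaired.

#' Interval-unpaired probability
#'
#' Probability that every base of `interval` is unpaired, computed as the
#' ratio `Z_u / Z` of constrained partition functions over all nested
#' secondary structures (minimum hairpin loop 3).  Positions listed in
#' `forbiddenBases` are barred from intramolecular pairing in **both**
#' partition functions; this is how the footprint of a bound sRNA is
#' modelled.
#'
#' @param seq RNA string.
#' @param interval `c(start, end)`, 1-based inclusive; must be non-empty and
#'   inside the sequence.
#' @param forbiddenBases integer positions barred from pairing.
#' @param backend an energy backend (default the bundled model).
#' @param maxspan maximal base-pair span, `0` = unlimited.
#' @return the probability (in `(0, 1]`).
#' @examples
#' unpairedProbability(strrep("A", 10), c(3, 6))   # no structure: 1
#' @export
unpairedProbability <- function(seq, interval, forbiddenBases = integer(0),
                                backend = nnBackend(), maxspan = 0L) {
  seq <- toupper(chartr("Tt", "Uu", seq))
  res <- backendUnpairedProb(backend, seq, interval, forbiddenBases, maxspan)
  res$prob
}

#' Convert between opening energies and exposure probabilities
#'
#' `P = exp(-deltaE / (R T))` with the gas constant
#' `R = 1.9872e-3 kcal/(mol K)`.  The inverse recovers the opening energy
#' from a probability.  Opening energies are free-energy costs and must be
#' non-negative.  The pair inverts to machine precision as long as the
#' probability does not saturate at 1 in double precision (energies down to
#' ~0.01 kcal/mol); deep openings (P as small as `exp(-60/RT)`) are handled
#' without underflow.
#'
#' @param deltaE opening energy, kcal/mol (>= 0).
#' @param p probability in (0, 1].
#' @param temperature kelvin.
#' @return a probability, resp. an energy in kcal/mol.
#' @examples
#' openingEnergyToProbability(0)
#' probabilityToOpeningEnergy(0.5) / log(2)   # = RT
#' @export
openingEnergyToProbability <- function(deltaE, temperature = DEFAULT_TEMPERATURE) {
  if (any(deltaE < 0)) stop("an opening energy cannot be negative")
  exp(-deltaE / (GAS_CONSTANT * temperature))
}

#' @rdname openingEnergyToProbability
#' @export
probabilityToOpeningEnergy <- function(p, temperature = DEFAULT_TEMPERATURE) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  -GAS_CONSTANT * temperature * log(p)
}

#' RDS exposure probability, with or without a bound sRNA
#'
#' Computes the probability that the complete ribosome docking site is
#' unpaired, over a sequence stretch of `flank` nucleotides on each side of
#' the RDS (clipped at the transcript ends, no recentering).  Without a
#' binding site this is `P_EF`; with one, the site's mRNA bases are barred
#' from intramolecular pairing (the footprint of the hybridised sRNA) and the
#' result is `P_ES`.
#'
#' @param t a [Transcript-class].
#' @param rds a [RibosomeSite-class] for `t`.
#' @param site optionally a [BindingSite-class]; its mRNA span becomes the
#'   set of forbidden bases.
#' @param backend an energy backend.
#' @param flank half-width of the folding window (default 250 nt).
#' @return an [AccessibilityResult-class].
#' @export
rdsExposure <- function(t, rds, site = NULL, backend = nnBackend(),
                        flank = 250) {
  n <- nchar(transcriptSeq(t))
  rdsAbs <- c(relativeToAbsolute(t, rds@rdsRelStart),
              min(n, relativeToAbsolute(t, rds@rdsRelStart) + 29L))
  w <- c(max(1L, rdsAbs[1L] - as.integer(flank)),
         min(n, rdsAbs[2L] + as.integer(flank)))
  forbidden <- integer(0)
  if (!is.null(site)) {
    a <- relativeToAbsolute(t, site@mrnaRelStart)
    b <- relativeToAbsolute(t, site@mrnaRelEnd)
    forbidden <- seq.int(max(1L, a), min(n, b)) - w[1L] + 1L
    forbidden <- forbidden[forbidden >= 1L & forbidden <= w[2L] - w[1L] + 1L]
  }
  res <- backendUnpairedProb(backend, substr(transcriptSeq(t), w[1L], w[2L]),
                             interval = rdsAbs - w[1L] + 1L,
                             forbidden = forbidden)
  RT <- backend@params$RT
  p <- res$prob
  dE <- max(0, -RT * res$log_prob)
  new("AccessibilityResult",
      interval = rdsInterval(rds), openingEnergy = dE, probability = p,
      constrained = !is.null(site), windowAbs = as.integer(w),
      kOpen = if (p < 1) p / (1 - p) else Inf)
}
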