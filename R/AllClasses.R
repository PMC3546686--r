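## Central S4 classes.  Coordinates follow the biologist convention used
## throughout the package: relative positions have no 0, +1 is the first base
## of the start codon and -1 the base immediately upstream; absolute positions
## are 1-based indices into the transcript sequence.

RNA_ALPHABET <- c("A", "C", "G", "U")

.checkRNAString <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    return(sprintf("%s must be a single non-empty string", what))
  bad <- setdiff(unique(strsplit(x, "")[[1L]]), RNA_ALPHABET)
  if (length(bad))
    return(sprintf("%s contains non-RNA characters: %s", what,
                   paste(bad, collapse = ", ")))
  NULL
}

#' Transcript: an mRNA with an annotated translation start
#'
#' Holds the (RNA-normalised) sequence of one transcript together with the
#' 1-based position of the first base of its start codon.  Records whose
#' annotated codon is not a recognised start codon (AUG/GUG/UUG/AUU/AUA/CUG)
#' are retained but flagged via `startValid`.
#'
#' @slot id record identifier.
#' @slot sequence RNA string over A/C/G/U.
#' @slot startPos 1-based index of the first start-codon base.
#' @slot source optional provenance string.
#' @slot startValid whether the annotated codon looks like a start codon.
#' @export
setClass("Transcript",
  representation(id = "character", sequence = "character",
                 startPos = "integer", source = "character",
                 startValid = "logical"))

setValidity("Transcript", function(object) {
  msg <- .checkRNAString(object@sequence)
  if (!is.null(msg)) return(msg)
  n <- nchar(object@sequence)
  if (length(object@startPos) != 1L || is.na(object@startPos))
    return("startPos must be a single integer")
  if (object@startPos < 1L || object@startPos > n - 2L)
    return(sprintf("startPos %d outside [1, %d]", object@startPos, n - 2L))
  TRUE
})

START_CODONS <- c("AUG", "GUG", "UUG", "AUU", "AUA", "CUG")

#' Construct a Transcript
#'
#' @param id record identifier.
#' @param sequence nucleotide string; DNA is accepted and normalised to RNA
#'   (`T`/`t` mapped to `U`), case-insensitively.
#' @param startPos 1-based position of the first base of the start codon.
#' @param source optional provenance string.
#' @return a [Transcript-class] object.
#' @examples
#' tr <- Transcript("toy", "AAAATGGCT", startPos = 4)
#' startCodon(tr)
#' @export
Transcript <- function(id, sequence, startPos, source = "") {
  seq <- chartr("Tt", "Uu", as.character(sequence))
  seq <- toupper(seq)
  msg <- .checkRNAString(seq, sprintf("sequence of '%s'", id))
  if (!is.null(msg)) stop(msg, call. = FALSE)
  startPos <- as.integer(startPos)
  codon <- substr(seq, startPos, startPos + 2L)
  new("Transcript", id = as.character(id), sequence = seq,
      startPos = startPos, source = as.character(source),
      startValid = codon %in% START_CODONS)
}

#' @rdname Transcript
#' @param x a `Transcript`.
#' @export
setMethod("transcriptId", "Transcript", function(x) x@id)
#' @rdname Transcript
#' @export
setMethod("transcriptSeq", "Transcript", function(x) x@sequence)
#' @rdname Transcript
#' @export
setMethod("startPos", "Transcript", function(x) x@startPos)
#' @rdname Transcript
#' @export
setMethod("startCodon", "Transcript", function(x)
  substr(x@sequence, x@startPos, x@startPos + 2L))

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript '%s': %d nt, start codon %s at %d%s\n",
              object@id, nchar(object@sequence), startCodon(object),
              object@startPos,
              if (object@startValid) "" else " [non-standard]"))
})

#' Relative interval around the translation start
#'
#' Closed interval in start-codon-relative coordinates.  There is no position
#' 0: +1 is the first base of the start codon, -1 the base immediately
#' upstream, so an interval such as (-12)..(+18) spans 30 nucleotides.
#'
#' @slot relStart,relEnd interval endpoints (inclusive), never 0.
#' @export
setClass("RelativeInterval",
  representation(relStart = "integer", relEnd = "integer"))

setValidity("RelativeInterval", function(object) {
  s <- object@relStart; e <- object@relEnd
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e))
    return("endpoints must be single integers")
  if (s == 0L || e == 0L) return("relative coordinates have no position 0")
  if (s > e) return("relStart must not exceed relEnd")
  TRUE
})

#' @rdname RelativeInterval-class
#' @param relStart,relEnd inclusive endpoints (no 0).
#' @return a `RelativeInterval`.
#' @examples
#' relativeInterval(-150, 20)
#' @export
relativeInterval <- function(relStart, relEnd) {
  new("RelativeInterval", relStart = as.integer(relStart),
      relEnd = as.integer(relEnd))
}

#' @rdname RelativeInterval-class
#' @param x a `RelativeInterval`.
#' @export
setMethod("relStart", "RelativeInterval", function(x) x@relStart)
#' @rdname RelativeInterval-class
#' @export
setMethod("relEnd", "RelativeInterval", function(x) x@relEnd)

#' @rdname RelativeInterval-class
#' @export
relWidth <- function(x) {
  w <- x@relEnd - x@relStart + 1L
  if (x@relStart < 0L && x@relEnd > 0L) w <- w - 1L  # no position 0
  w
}

setMethod("show", "RelativeInterval", function(object) {
  cat(sprintf("(%+d)..(%+d) [%d nt]\n", object@relStart, object@relEnd,
              relWidth(object)))
})

#' Ribosome recognition and docking site
#'
#' The RRS is the energetically best duplex of the anti-RRS (3' end of the 16S
#' rRNA) within the search window upstream of the start codon; the RDS is the
#' 30-nt stretch occupied by the initiating 30S subunit, starting at the RRS
#' start.  `deltaGR` is the duplex hybridisation energy plus the
#' start-codon bonus.
#'
#' @slot rrsRelStart,rrsRelEnd RRS endpoints, relative coordinates.
#' @slot rdsRelStart,rdsRelEnd RDS endpoints (30 nt), relative coordinates.
#' @slot deltaGR total ribosome hybridisation energy (kcal/mol, <= 0).
#' @slot duplexEnergy anti-RRS duplex energy without the codon bonus.
#' @slot codonBonus start-codon contribution (kcal/mol).
#' @export
setClass("RibosomeSite",
  representation(rrsRelStart = "integer", rrsRelEnd = "integer",
                 rdsRelStart = "integer", rdsRelEnd = "integer",
                 deltaGR = "numeric", duplexEnergy = "numeric",
                 codonBonus = "numeric"))

setValidity("RibosomeSite", function(object) {
  if (object@rdsRelStart != object@rrsRelStart)
    return("RDS must start at the RRS start")
  rds <- relativeInterval(object@rdsRelStart, object@rdsRelEnd)
  if (relWidth(rds) != 30L) return("RDS span must be exactly 30 nt")
  if (object@deltaGR > 0) return("deltaGR must be <= 0")
  TRUE
})

#' @rdname RibosomeSite-class
#' @param x a `RibosomeSite`.
#' @export
setMethod("deltaGR", "RibosomeSite", function(x) x@deltaGR)

#' @rdname RibosomeSite-class
#' @export
rdsInterval <- function(x) relativeInterval(x@rdsRelStart, x@rdsRelEnd)
#' @rdname RibosomeSite-class
#' @export
rrsInterval <- function(x) relativeInterval(x@rrsRelStart, x@rrsRelEnd)

setMethod("show", "RibosomeSite", function(object) {
  cat(sprintf(
    "RibosomeSite: RRS (%+d)..(%+d), RDS (%+d)..(%+d), dG_R = %.2f kcal/mol\n",
    object@rrsRelStart, object@rrsRelEnd, object@rdsRelStart,
    object@rdsRelEnd, object@deltaGR))
})

#' An sRNA binding site on an mRNA
#'
#' One candidate sRNA-mRNA interaction site.  `deltaGS` is the
#' accessibility-corrected interaction energy: the hybridisation energy plus
#' the opening energies of the paired regions on both partners.  `lengthNt`
#' is the site span on the mRNA including interior unpaired bases.
#'
#' @slot mrnaRelStart,mrnaRelEnd site span on the mRNA, relative coordinates.
#' @slot srnaStart,srnaEnd site span on the sRNA, 1-based.
#' @slot deltaGS accessibility-corrected energy (kcal/mol).
#' @slot hybridEnergy raw duplex energy (kcal/mol).
#' @slot lengthNt mRNA span in nt.
#' @slot srnaSpan sRNA span in nt.
#' @slot pairsMrnaAbs,pairsSrna paired positions (absolute mRNA / sRNA).
#' @export
setClass("BindingSite",
  representation(mrnaRelStart = "integer", mrnaRelEnd = "integer",
                 srnaStart = "integer", srnaEnd = "integer",
                 deltaGS = "numeric", hybridEnergy = "numeric",
                 lengthNt = "integer", srnaSpan = "integer",
                 pairsMrnaAbs = "integer", pairsSrna = "integer"))

setValidity("BindingSite", function(object) {
  if (object@mrnaRelStart == 0L || object@mrnaRelEnd == 0L)
    return("relative coordinates have no position 0")
  if (object@srnaStart > object@srnaEnd) return("invalid sRNA span")
  if (object@lengthNt < 1L) return("lengthNt must be positive")
  TRUE
})

#' @rdname BindingSite-class
#' @param x a `BindingSite`.
#' @export
setMethod("deltaGS", "BindingSite", function(x) x@deltaGS)

#' @rdname BindingSite-class
#' @export
siteInterval <- function(x) relativeInterval(x@mrnaRelStart, x@mrnaRelEnd)

setMethod("show", "BindingSite", function(object) {
  cat(sprintf(
    "BindingSite: mRNA (%+d)..(%+d) [%d nt], sRNA %d..%d, dG_S = %.2f (hybrid %.2f) kcal/mol\n",
    object@mrnaRelStart, object@mrnaRelEnd, object@lengthNt,
    object@srnaStart, object@srnaEnd, object@deltaGS, object@hybridEnergy))
})

#' RDS accessibility result
#'
#' The probability that the ribosome docking site is entirely unpaired,
#' together with the equivalent opening energy `deltaE = -RT log(P)` and the
#' opening equilibrium constant `K = P/(1-P)`.
#'
#' @slot interval the RDS in relative coordinates.
#' @slot openingEnergy kcal/mol (>= 0).
#' @slot probability in (0, 1].
#' @slot constrained whether sRNA-site bases were barred from pairing.
#' @slot windowAbs absolute window used (1-based, length 2).
#' @slot kOpen opening equilibrium constant.
#' @export
setClass("AccessibilityResult",
  representation(interval = "RelativeInterval", openingEnergy = "numeric",
                 probability = "numeric", constrained = "logical",
                 windowAbs = "integer", kOpen = "numeric"))

setValidity("AccessibilityResult", function(object) {
  p <- object@probability
  if (!(p > 0 && p <= 1)) return("probability must be in (0, 1]")
  if (object@openingEnergy < -1e-9) return("opening energy must be >= 0")
  TRUE
})

#' @rdname AccessibilityResult-class
#' @param x an `AccessibilityResult`.
#' @export
probability <- function(x) x@probability
#' @rdname AccessibilityResult-class
#' @export
openingEnergy <- function(x) x@openingEnergy

setMethod("show", "AccessibilityResult", function(object) {
  cat(sprintf(
    "AccessibilityResult (%s): P = %.4g, deltaE = %.3f kcal/mol, window %d..%d\n",
    if (object@constrained) "constrained" else "free",
    object@probability, object@openingEnergy,
    object@windowAbs[1L], object@windowAbs[2L]))
})

#' Mass-action equilibrium parameters
#'
#' Inputs of the translation-initiation equilibrium: binding constants,
#' RDS exposure probabilities, copy numbers and the ribosome occupancy `n`.
#' Copy numbers per cell are treated as dimensionless activities, exactly as
#' in the model this package implements.
#'
#' @slot kR,kS ribosome / sRNA binding constants (dimensionless, > 0).
#' @slot pEF RDS exposure probability of free mRNA.
#' @slot pES RDS exposure probability with bound sRNA (non-overlap only;
#'   `NA` for the overlap topology).
#' @slot mT,sT,rT total mRNA, sRNA and initiation-available ribosomes.
#' @slot n ribosome occupancy (>= 1).
#' @slot topology `"overlap"` or `"nonoverlap"`.
#' @export
setClass("EquilibriumParams",
  representation(kR = "numeric", kS = "numeric", pEF = "numeric",
                 pES = "numeric", mT = "numeric", sT = "numeric",
                 rT = "numeric", n = "numeric", topology = "character"))

setValidity("EquilibriumParams", function(object) {
  if (!object@topology %in% c("overlap", "nonoverlap"))
    return("topology must be 'overlap' or 'nonoverlap'")
  if (object@kR <= 0 || object@kS < 0) return("kR must be > 0, kS >= 0")
  if (!(object@pEF > 0 && object@pEF <= 1))
    return("pEF must be in (0, 1]")
  if (object@topology == "nonoverlap" &&
      !(isTRUE(object@pES > 0) && isTRUE(object@pES <= 1)))
    return("pES must be in (0, 1] for the non-overlap topology")
  if (object@mT < 0 || object@sT < 0 || object@rT < 0)
    return("copy numbers must be >= 0")
  if (object@n < 1) return("ribosome occupancy n must be >= 1")
  TRUE
})

#' @rdname EquilibriumParams-class
#' @param kR,kS,pEF,pES,mT,sT,rT,n,topology see slot documentation.
#' @return an `EquilibriumParams` object.
#' @examples
#' equilibriumParams(kR = 1e3, kS = 1e6, pEF = 1e-2,
#'                   mT = 100, sT = 66, rT = 11400, n = 20,
#'                   topology = "overlap")
#' @export
equilibriumParams <- function(kR, kS, pEF, pES = NA_real_, mT, sT, rT,
                              n = 20, topology = c("overlap", "nonoverlap")) {
  topology <- match.arg(topology)
  new("EquilibriumParams", kR = as.numeric(kR), kS = as.numeric(kS),
      pEF = as.numeric(pEF), pES = as.numeric(pES), mT = as.numeric(mT),
      sT = as.numeric(sT), rT = as.numeric(rT), n = as.numeric(n),
      topology = topology)
}

setMethod("show", "EquilibriumParams", function(object) {
  cat(sprintf(
    "EquilibriumParams [%s]: K_R = %.4g, K_S = %.4g, P_EF = %.4g, P_ES = %s\n",
    object@topology, object@kR, object@kS, object@pEF,
    if (is.na(object@pES)) "NA" else sprintf("%.4g", object@pES)))
  cat(sprintf("  m_T = %g, s_T = %g, r_T = %g, n = %g\n",
              object@mT, object@sT, object@rT, object@n))
})

#' Solved equilibrium species
#'
#' Species copy numbers at mass-action equilibrium.  `mTA` is the
#' translationally active mRNA: `mR` for the overlap topology, `mR + mSR`
#' for the non-overlap topology.
#'
#' @slot mF,mS,mR,mSR,sF,rF species copy numbers.
#' @slot mTA translationally active mRNA.
#' @slot residuals absolute residuals of the three conservation balances.
#' @slot params the solved [EquilibriumParams-class].
#' @export
setClass("EquilibriumResult",
  representation(mF = "numeric", mS = "numeric", mR = "numeric",
                 mSR = "numeric", sF = "numeric", rF = "numeric",
                 mTA = "numeric", residuals = "numeric",
                 params = "EquilibriumParams"))

#' @rdname EquilibriumResult-class
#' @param x an `EquilibriumResult`.
#' @export
species <- function(x) c(mF = x@mF, mS = x@mS, mR = x@mR, mSR = x@mSR,
                         sF = x@sF, rF = x@rF)
#' @rdname EquilibriumResult-class
#' @export
activeMrna <- function(x) x@mTA

setMethod("show", "EquilibriumResult", function(object) {
  sp <- species(object)
  cat(sprintf("EquilibriumResult [%s]: m_TA = %.6g\n",
              object@params@topology, object@mTA))
  cat("  ", paste(sprintf("%s = %.4g", names(sp), sp), collapse = ", "), "\n")
  cat(sprintf("  max balance residual: %.3g\n", max(abs(object@residuals))))
})

#' Concentration inputs for one screened gene
#'
#' @slot mT,sT,rT copy numbers per cell; `n` ribosome occupancy.
#' @export
setClass("ConcentrationSet",
  representation(mT = "numeric", sT = "numeric", rT = "numeric",
                 n = "numeric"))

setValidity("ConcentrationSet", function(object) {
  if (any(c(object@mT, object@sT, object@rT) < 0))
    return("copy numbers must be >= 0")
  if (object@n < 1) return("n must be >= 1")
  TRUE
})

#' @rdname ConcentrationSet-class
#' @param mT,sT,rT,n copy numbers and ribosome occupancy.
#' @export
concentrationSet <- function(mT, sT, rT, n = 20) {
  new("ConcentrationSet", mT = as.numeric(mT), sT = as.numeric(sT),
      rT = as.numeric(rT), n = as.numeric(n))
}

setMethod("show", "ConcentrationSet", function(object) {
  cat(sprintf("ConcentrationSet: m_T = %g, s_T = %g, r_T = %g, n = %g\n",
              object@mT, object@sT, object@rT, object@n))
})

#' Screening run configuration
#'
#' All tunable parameters of the screening pipeline, with the model's
#' standard defaults: site search window (-150)..(+20), energy cutoff
#' -7 kcal/mol, minimum site length 10 nt, RRS search window (-30)..(+3),
#' anti-RRS "UCACCUCCUU", accessibility flank 250 nt, 37 C, ribosome
#' occupancy 20, sRNA/mRNA ratio 2/3, |alpha| threshold 2.
#'
#' @slot window sRNA site search window (relative).
#' @slot energyCutoff max accessibility-corrected site energy (kcal/mol).
#' @slot minLen minimum site length on the mRNA (nt).
#' @slot rrsWindow RRS search window (relative).
#' @slot antiRRS anti-RRS sequence (3' end of the 16S rRNA).
#' @slot flank half-width of the RDS accessibility window (nt).
#' @slot temperature kelvin.
#' @slot n ribosome occupancy.
#' @slot ratio default sRNA/mRNA copy ratio.
#' @slot total16S total 16S rRNA copies per cell.
#' @slot busyFraction fraction of ribosomes engaged in elongation.
#' @slot alphaThreshold classification threshold on |alpha|.
#' @slot siteContext context half-width for site accessibility (nt).
#' @slot maxPairSpan max intramolecular pair span for site accessibility.
#' @slot backendName energy backend selector (currently `"builtin"`).
#' @slot useMeasuredSrna take s_T from the expression table when present.
#' @slot seed seed echoed into outputs (no randomness in the screen itself).
#' @export
setClass("ScreenConfig",
  representation(window = "RelativeInterval", energyCutoff = "numeric",
                 minLen = "integer", rrsWindow = "RelativeInterval",
                 antiRRS = "character", flank = "integer",
                 temperature = "numeric", n = "numeric", ratio = "numeric",
                 total16S = "numeric", busyFraction = "numeric",
                 alphaThreshold = "numeric", siteContext = "integer",
                 maxPairSpan = "integer", backendName = "character",
                 useMeasuredSrna = "logical", seed = "integer"))

#' @rdname ScreenConfig-class
#' @param window,energyCutoff,minLen,rrsWindow,antiRRS,flank,temperature,n
#'   see slot documentation.
#' @param ratio,total16S,busyFraction,alphaThreshold,siteContext,maxPairSpan
#'   see slot documentation.
#' @param backendName,useMeasuredSrna,seed see slot documentation.
#' @return a `ScreenConfig`.
#' @examples
#' screenConfig(n = 20, ratio = 2/3)
#' @export
screenConfig <- function(window = relativeInterval(-150, 20),
                         energyCutoff = -7, minLen = 10,
                         rrsWindow = relativeInterval(-30, 3),
                         antiRRS = "UCACCUCCUU", flank = 250,
                         temperature = 310.15, n = 20, ratio = 2 / 3,
                         total16S = 57000, busyFraction = 0.80,
                         alphaThreshold = 2, siteContext = 200,
                         maxPairSpan = 150, backendName = "builtin",
                         useMeasuredSrna = FALSE, seed = 1) {
  new("ScreenConfig", window = window, energyCutoff = as.numeric(energyCutoff),
      minLen = as.integer(minLen), rrsWindow = rrsWindow,
      antiRRS = toupper(chartr("Tt", "Uu", antiRRS)), flank = as.integer(flank),
      temperature = as.numeric(temperature), n = as.numeric(n),
      ratio = as.numeric(ratio), total16S = as.numeric(total16S),
      busyFraction = as.numeric(busyFraction),
      alphaThreshold = as.numeric(alphaThreshold),
      siteContext = as.integer(siteContext),
      maxPairSpan = as.integer(maxPairSpan),
      backendName = backendName,
      useMeasuredSrna = isTRUE(useMeasuredSrna), seed = as.integer(seed))
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:\n")
  for (kv in configAsStrings(object)) cat("  ", kv, "\n", sep = "")
})

#' A synthetic test scenario
#'
#' A transcript/sRNA pair constructed so that the full screening pipeline is
#' expected to produce a known call.  Regenerating with the same seed yields
#' identical sequences.
#'
#' @slot label one of `repression`, `activation`, `null`, `upstream_weak`.
#' @slot transcript the synthetic [Transcript-class].
#' @slot srna the synthetic sRNA sequence.
#' @slot plantedSite intended site location (relative coordinates).
#' @slot expectedTopology `overlap`/`nonoverlap`/`none`.
#' @slot expectedCall expected per-gene verdict.
#' @slot mT,sT copy numbers the scenario is built for.
#' @slot seed generator seed.
#' @export
setClass("FixtureScenario",
  representation(label = "character", transcript = "Transcript",
                 srna = "character", plantedSite = "RelativeInterval",
                 expectedTopology = "character", expectedCall = "character",
                 mT = "numeric", sT = "numeric", seed = "integer"))

setMethod("show", "FixtureScenario", function(object) {
  cat(sprintf(
    "FixtureScenario '%s' (seed %d): expect %s via %s site at (%+d)..(%+d)\n",
    object@label, object@seed, object@expectedCall, object@expectedTopology,
    object@plantedSite@relStart, object@plantedSite@relEnd))
})
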