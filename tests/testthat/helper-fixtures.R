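# Shared test helpers: a lazily built, cached fixture set (construction is
# deterministic but takes ~20 s, so it is built once per test run) and a
# generator for random feasible equilibrium parameter sets spanning the
# model's full working range.

.testCache <- new.env(parent = emptyenv())

getFixtureSet <- function() {
  if (is.null(.testCache$set)) .testCache$set <- fixtureSet(1)
  .testCache$set
}

getFixtureTranscripts <- function() lapply(getFixtureSet(), slot, "transcript")

RT37 <- 1.9872e-3 * 310.15

randomFeasibleParams <- function(topology) {
  equilibriumParams(
    kR = exp(stats::runif(1, 0, 40) / RT37),
    kS = exp(stats::runif(1, 0, 40) / RT37),
    pEF = 10^stats::runif(1, -6, 0),
    pES = 10^stats::runif(1, -6, 0),
    mT = 10^stats::runif(1, 0, 5),
    sT = 10^stats::runif(1, 0, 5),
    rT = 10^stats::runif(1, 0, 5),
    n = sample(1:100, 1),
    topology = topology)
}

maxSpeciesRelDiff <- function(a, b) {
  sa <- species(a); sb <- species(b)
  rel <- abs(sa - sb) / pmax(abs(sb), 1e-300)
  rel[sa == 0 & sb == 0] <- 0
  max(rel)
}

# a transcript with a planted RRS complement and AUG on a fixed background
plantedTranscript <- function(id = "toy", utr = 60, cds = 40) {
  v <- rep("A", utr + cds)
  v[seq_len(utr + cds) %% 7 == 0] <- "U"   # deterministic sprinkle
  v[(utr - 11):(utr - 2)] <- strsplit(rnaReverseComplement("UCACCUCCUU"),
                                      "")[[1]]
  v[(utr + 1):(utr + 3)] <- c("A", "U", "G")
  Transcript(id, paste(v, collapse = ""), startPos = utr + 1)
}

# direct closed-form duplex energy of a perfect helix query/revcomp(query)
perfectHelixEnergy <- function(query, params = energyParams()) {
  target <- rnaReverseComplement(query)
  tv <- strsplit(target, "")[[1]]
  qv <- rev(strsplit(query, "")[[1]])   # q index decreasing along the helix
  e <- params$dup_init
  for (i in seq_len(length(tv) - 1)) {
    p1 <- paste0(tv[i], qv[i])
    p2 <- paste0(tv[i + 1], qv[i + 1])
    e <- e + params$stack[p1, p2]
  }
  e
}

# minimal BindingSite constructor for filter-semantics tests
mkSite <- function(relStart, relEnd, dG, lenNt = NULL) {
  if (is.null(lenNt)) {
    w <- relEnd - relStart + 1L
    if (relStart < 0 && relEnd > 0) w <- w - 1L
    lenNt <- w
  }
  new("BindingSite", mrnaRelStart = as.integer(relStart),
      mrnaRelEnd = as.integer(relEnd), srnaStart = 1L,
      srnaEnd = as.integer(lenNt), deltaGS = dG, hybridEnergy = dG,
      lengthNt = as.integer(lenNt), srnaSpan = as.integer(lenNt),
      pairsMrnaAbs = integer(0), pairsSrna = integer(0))
}
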