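#' @import methods
NULL

#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @export
setGeneric("transcriptSeq", function(x) standardGeneric("transcriptSeq"))
#' @export
setGeneric("startPos", function(x) standardGeneric("startPos"))
#' @export
setGeneric("startCodon", function(x) standardGeneric("startCodon"))
#' @export
setGeneric("relStart", function(x) standardGeneric("relStart"))
#' @export
setGeneric("relEnd", function(x) standardGeneric("relEnd"))
#' @export
setGeneric("deltaGR", function(x) standardGeneric("deltaGR"))
#' @export
setGeneric("deltaGS", function(x) standardGeneric("deltaGS"))

#' Backend operations
#'
#' Generics implemented by every energy backend: the optimal inter-molecular
#' duplex, per-end sub-optimal duplex candidates, and the probability that an
#' interval of a sequence is entirely unpaired under the backend's
#' intramolecular model.
#'
#' @param backend an [EnergyBackend-class] object.
#' @param target,query,seq RNA sequences as plain `A`/`C`/`G`/`U` strings.
#' @param cutoff report only duplexes with energy at or below this (kcal/mol).
#' @param interval integer vector of length 2, 1-based inclusive positions.
#' @param forbidden integer vector of positions barred from intramolecular
#'   pairing.
#' @param maxspan maximal base-pair span; `0` disables the cap.
#' @return `duplexBest`/`duplexSubopt` return a list of site records
#'   (energy, coordinates on both strands, paired positions); the probability
#'   generic returns a list with elements `prob` and `log_prob`.
#' @name backend-ops
NULL

#' @rdname backend-ops
#' @export
setGeneric("duplexBest", function(backend, target, query, cutoff = 0)
  standardGeneric("duplexBest"))
#' @rdname backend-ops
#' @export
setGeneric("duplexSubopt", function(backend, target, query, cutoff = 0)
  standardGeneric("duplexSubopt"))
#' @rdname backend-ops
#' @export
setGeneric("backendUnpairedProb",
  function(backend, seq, interval, forbidden = integer(0), maxspan = 0L)
  standardGeneric("backendUnpairedProb"))
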