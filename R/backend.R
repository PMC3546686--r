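#' Energy backends
#'
#' `EnergyBackend` is the virtual interface behind all thermodynamic
#' calculations: optimal and sub-optimal inter-molecular duplexes, and
#' constrained interval-unpaired probabilities.  The bundled concrete backend,
#' `NearestNeighborBackend`, uses the simplified nearest-neighbour model of
#' [energyParams()] through the compiled engine.  Additional backends (for
#' example an adapter around an external folding engine) can be added by
#' subclassing and implementing the three generics in [backend-ops].
#'
#' @slot name backend identifier.
#' @slot params parameter list (see [energyParams()]).
#' @aliases EnergyBackend-class
#' @export
setClass("EnergyBackend", representation("VIRTUAL", name = "character"))

#' @rdname EnergyBackend-class
#' @export
setClass("NearestNeighborBackend", contains = "EnergyBackend",
         representation(params = "list"))

#' @rdname EnergyBackend-class
#' @param temperature kelvin.
#' @param params full parameter list; overrides `temperature`.
#' @return a `NearestNeighborBackend`.
#' @examples
#' be <- nnBackend()
#' duplexBest(be, "GGGAAGGAGGUGAAAA", "UCACCUCCUU")
#' @export
nnBackend <- function(temperature = DEFAULT_TEMPERATURE,
                      params = energyParams(temperature)) {
  new("NearestNeighborBackend", name = "builtin", params = params)
}

setMethod("show", "NearestNeighborBackend", function(object) {
  cat(sprintf("NearestNeighborBackend ('%s'), T = %.2f K, RT = %.5f kcal/mol\n",
              object@name, object@params$temperature, object@params$RT))
})

.siteFromCpp <- function(s) {
  list(energy = s$energy,
       tStart = s$t_start, tEnd = s$t_end,
       qStart = s$q_start, qEnd = s$q_end,
       pairsT = s$pairs_t, pairsQ = s$pairs_q)
}

#' @rdname backend-ops
#' @export
setMethod("duplexBest", "NearestNeighborBackend",
  function(backend, target, query, cutoff = 0) {
    hits <- cpp_duplex_best(encodeRNA(target), encodeRNA(query),
                            backend@params, cutoff)
    if (length(hits) == 0L) return(NULL)
    .siteFromCpp(hits[[1L]])
  })

#' @rdname backend-ops
#' @export
setMethod("duplexSubopt", "NearestNeighborBackend",
  function(backend, target, query, cutoff = 0) {
    hits <- cpp_duplex_subopt(encodeRNA(target), encodeRNA(query),
                              backend@params, cutoff)
    lapply(hits, .siteFromCpp)
  })

#' @rdname backend-ops
#' @export
setMethod("backendUnpairedProb", "NearestNeighborBackend",
  function(backend, seq, interval, forbidden = integer(0), maxspan = 0L) {
    n <- nchar(seq)
    interval <- as.integer(interval)
    if (length(interval) != 2L || interval[1L] > interval[2L])
      stop("interval must be c(start, end) with start <= end")
    if (interval[1L] < 1L || interval[2L] > n)
      stop("interval outside the sequence")
    forbidden <- as.integer(forbidden)
    if (length(forbidden) && (min(forbidden) < 1L || max(forbidden) > n))
      stop("forbidden positions outside the sequence")
    mask <- rep(FALSE, n)
    mask[forbidden] <- TRUE
    cpp_unpaired_prob(encodeRNA(seq), mask, interval[1L] - 1L,
                      interval[2L] - 1L, backend@params, as.integer(maxspan))
  })
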