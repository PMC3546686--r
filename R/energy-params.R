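## The bundled simplified nearest-neighbour energy model.
##
## Stacking energies are a published-style Watson-Crick + GU table
## (kcal/mol at 37 C); loop contributions are deliberately simple,
## documented closed forms so that an independent brute-force oracle can
## re-evaluate any structure:
##   hairpin(L)      = hairpin_a + hairpin_b * log(L/3),  L >= 3 unpaired
##   interior(s)     = interior_a + interior_b * log(s),  s = total unpaired,
##                     prohibited for s > interior_cap
##   multiloop       = ml_a + ml_b * (#branches incl. the closing pair)
##   duplex          = sum of stacks + dup_init, inter-molecular loops
##                     dup_loop_a + dup_loop_b * (g1 + g2), per-strand gap
##                     <= dup_gap_cap
## No dangling ends and no terminal-AU penalty; exterior bases are free.

GAS_CONSTANT <- 1.9872e-3   # kcal/(mol*K)
DEFAULT_TEMPERATURE <- 310.15

PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

.stackTable <- local({
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  # rows: outer pair X..Y (X on the 5' side of the top strand);
  # columns: inner pair W..Z; energy of 5'-XW-3' / 3'-YZ-5'
  m["AU", ] <- c(-0.93, -1.10, -2.24, -2.08, -0.55, -1.36)
  m["UA", ] <- c(-1.33, -0.93, -2.35, -2.11, -1.00, -0.99)
  m["CG", ] <- c(-2.11, -2.08, -3.26, -2.36, -1.41, -2.11)
  m["GC", ] <- c(-2.35, -2.24, -3.42, -3.26, -1.53, -2.51)
  m["GU", ] <- c(-0.99, -1.36, -2.51, -2.11, -0.50,  1.29)
  m["UG", ] <- c(-1.00, -0.55, -1.53, -1.41,  0.30, -0.50)
  # a helix read from the opposite strand is the same helix: enforce the
  # corresponding symmetry E[p, q] == E[rev(q), rev(p)]
  rev_pair <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  for (p in PAIR_NAMES) for (q in PAIR_NAMES) {
    stopifnot(isTRUE(all.equal(m[p, q], m[rev_pair[q], rev_pair[p]])))
  }
  m
})

#' Parameters of the bundled energy model
#'
#' Returns the full parameter set of the simplified nearest-neighbour model:
#' the 6x6 stacking table (pair order AU, UA, CG, GC, GU, UG), hairpin,
#' interior-loop and multiloop coefficients, the inter-molecular duplex
#' initiation and loop penalties, and `RT` at the requested temperature.
#' The same parameter object drives both the compiled engine and the
#' brute-force oracles, so any structure's energy can be recomputed by hand.
#'
#' @param temperature kelvin; default 310.15 K (37 C).
#' @return a named list of model parameters.
#' @examples
#' p <- energyParams()
#' p$stack["CG", "CG"]   # CG stacked on CG
#' @export
energyParams <- function(temperature = DEFAULT_TEMPERATURE) {
  list(stack = .stackTable,
       hairpin_a = 5.4, hairpin_b = 1.08,
       interior_a = 3.2, interior_b = 1.08, interior_cap = 20L,
       ml_a = 3.4, ml_b = 0.4,
       dup_init = 4.1, dup_loop_a = 2.6, dup_loop_b = 0.4,
       dup_gap_cap = 10L,
       temperature = temperature,
       RT = GAS_CONSTANT * temperature)
}

# integer encoding shared with the compiled engine: A=0, C=1, G=2, U=3
encodeRNA <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  code <- match(v, RNA_ALPHABET) - 1L
  if (anyNA(code)) stop("non-RNA characters in sequence")
  code
}

# pair type codes matching the engine: 1..6 = AU UA CG GC GU UG, 0 = none
pairTypeCode <- function(x, y) {
  key <- paste0(x, y)
  p <- match(key, PAIR_NAMES)
  ifelse(is.na(p), 0L, p)
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick reverse complement (A<->U, C<->G) of an A/C/G/U string.
#'
#' @param seq RNA string.
#' @return the reverse complement string.
#' @examples
#' rnaReverseComplement("UCACCUCCUU")
#' @export
rnaReverseComplement <- function(seq) {
  v <- rev(strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1L]])
  paste(chartr("ACGU", "UGCA", v), collapse = "")
}
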