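## Independent verification paths.
##
## These deliberately avoid the algorithms they check: the equilibrium oracle
## iterates the un-eliminated reaction system (never the eliminated
## polynomial); the structure oracle enumerates every nested secondary
## structure explicitly and scores each one by loop decomposition; the duplex
## oracle enumerates every inter-molecular alignment.  They are exact but
## exponential, intended for small instances in tests and spot checks.

#' Equilibrium oracle: damped Newton on the un-eliminated system
#'
#' Solves the reaction network directly in the species `(m_F, s_F, r_F)`
#' (log-parametrised to preserve positivity) with a damped Newton iteration,
#' without ever forming the eliminated polynomial.  Used to cross-validate
#' [solveOverlap()] and [solveNonoverlap()].
#'
#' @param p an [EquilibriumParams-class].
#' @param start optional starting values `c(mF, sF, rF)`.
#' @param tol convergence tolerance on the scaled balance residuals.
#' @param maxit maximum Newton iterations per start.
#' @return an [EquilibriumResult-class].
#' @export
oracleSolve <- function(p, start = NULL, tol = 1e-12, maxit = 200L) {
  stopifnot(is(p, "EquilibriumParams"))
  if (p@mT == 0)
    return(.makeResult(c(mF = 0, mS = 0, mR = 0, mSR = 0, sF = p@sT,
                         rF = p@rT), p))
  A <- p@kR * p@pEF
  B <- if (p@topology == "nonoverlap") p@kR * p@pES else 0
  K <- p@kS
  hasS <- p@sT > 0 && K > 0
  scale <- pmax(1, c(p@sT, p@mT, p@rT))

  speciesOf <- function(mF, sF, rF) {
    mS <- if (hasS) K * mF * sF else 0
    mSR <- if (p@topology == "nonoverlap" && hasS) B * K * mF * sF * rF else 0
    c(mF = mF, mS = mS, mR = A * mF * rF, mSR = mSR,
      sF = if (hasS) sF else p@sT, rF = rF)
  }
  resid <- function(mF, sF, rF) {
    sp <- speciesOf(mF, sF, rF)
    r <- .residuals(sp, p)
    if (hasS) r else r[-1L]
  }
  jac <- function(mF, sF, rF) {
    nn <- p@n
    if (p@topology == "overlap") {
      J <- rbind(
        c(K * sF, 1 + K * mF, 0),
        c(1 + K * sF + A * rF, K * mF, A * mF),
        c(nn * A * rF, 0, 1 + nn * A * mF))
    } else {
      J <- rbind(
        c(K * sF + B * K * sF * rF,
          1 + K * mF + B * K * mF * rF,
          B * K * mF * sF),
        c(1 + K * sF + A * rF + B * K * sF * rF,
          K * mF + B * K * mF * rF,
          A * mF + B * K * mF * sF),
        c(nn * (A * rF + B * K * sF * rF),
          nn * B * K * mF * rF,
          1 + nn * (A * mF + B * K * mF * sF)))
    }
    if (!hasS) J <- J[-1L, -2L, drop = FALSE]
    J
  }

  run <- function(v0) {
    u <- log(v0)
    for (it in seq_len(maxit)) {
      v <- exp(u)
      if (hasS) { mF <- v[1L]; sF <- v[2L]; rF <- v[3L] }
      else { mF <- v[1L]; sF <- 0; rF <- v[2L] }
      r <- resid(mF, sF, rF)
      sc <- if (hasS) scale else scale[-1L]
      if (max(abs(r) / sc) < tol)
        return(speciesOf(mF, sF, rF))
      J <- jac(mF, sF, rF) * rep(v, each = length(r)) # chain rule to log
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      step <- pmin(pmax(step, -5), 5)
      f0 <- sum((r / sc)^2)
      lambda <- 1
      ok <- FALSE
      for (ls in 1:50) {
        u1 <- u + lambda * step
        v1 <- exp(u1)
        r1 <- if (hasS) resid(v1[1L], v1[2L], v1[3L])
              else resid(v1[1L], 0, v1[2L])
        if (all(is.finite(r1)) && sum((r1 / sc)^2) < f0) {
          u <- u1; ok <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!ok) return(NULL)
    }
    NULL
  }

  # physics-informed guesses (saturation limits of each binding reaction)
  # plus a spread of generic fractions of the totals
  informed <- list(
    c(p@mT / (1 + K * p@sT), p@sT / (1 + K * p@mT), p@rT / (1 + p@n * A * p@mT)),
    c(p@mT / (1 + A * p@rT), p@sT / 2, p@rT / (1 + p@n * A * p@mT)))
  fracs <- list(c(0.5, 0.5, 0.5), c(1e-3, 0.5, 0.5), c(0.5, 1e-3, 0.5),
                c(0.5, 0.5, 1e-3), c(1e-6, 0.9, 0.9), c(0.9, 1e-6, 0.9),
                c(0.9, 0.9, 1e-6), c(1e-3, 1e-3, 0.99), c(0.99, 0.99, 0.99),
                c(1e-9, 1e-9, 1e-9))
  starts <- if (!is.null(start)) {
    list(if (hasS) start else start[c(1L, 3L)])
  } else {
    c(lapply(informed, function(v) {
        v <- pmax(v, 1e-300)
        if (hasS) v else v[c(1L, 3L)]
      }),
      lapply(fracs, function(f) {
        v <- c(f[1L] * p@mT, f[2L] * max(p@sT, 1e-12), f[3L] * p@rT)
        if (hasS) v else v[c(1L, 3L)]
      }))
  }
  for (v0 in starts) {
    sp <- run(v0)
    if (!is.null(sp)) return(.checkResult(.makeResult(sp, p), p, tol = 1e-8))
  }
  # continuation in the binding constants: start from a weakly coupled
  # system where Newton converges easily and ramp the constants up in
  # geometric steps, reusing each solution as the next start
  if (is.null(start)) {
    steps <- 60L
    kSeq <- exp(seq(0, 1, length.out = steps))
    v <- NULL
    ok <- TRUE
    for (i in seq_len(steps)) {
      f <- (i - 1) / (steps - 1)
      pi_ <- p
      pi_@kR <- p@kR^f
      pi_@kS <- p@kS^f
      sub <- tryCatch(oracleSolve(pi_, start = v, tol = tol, maxit = maxit),
                      error = function(e) NULL)
      if (is.null(sub) && !is.null(v))
        sub <- tryCatch(oracleSolve(pi_, tol = tol, maxit = maxit),
                        error = function(e) NULL)
      if (is.null(sub)) { ok <- FALSE; break }
      spv <- species(sub)
      v <- pmax(c(spv[["mF"]], spv[["sF"]], spv[["rF"]]), 1e-300)
    }
    if (ok && !is.null(v)) {
      sp <- run(if (hasS) v else v[c(1L, 3L)])
      if (!is.null(sp))
        return(.checkResult(.makeResult(sp, p), p, tol = 1e-8))
    }
  }
  stop("oracle iteration did not converge from any starting point")
}

## ---------- secondary-structure enumeration ----------

.pairableMatrix <- function(code, forbidden = integer(0), maxspan = 0L) {
  n <- length(code)
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 4L) next
    if (maxspan > 0L && j - i + 1L > maxspan) next
    x <- RNA_ALPHABET[code[i] + 1L]; y <- RNA_ALPHABET[code[j] + 1L]
    ok[i, j] <- pairTypeCode(x, y) != 0L
  }
  if (length(forbidden)) { ok[forbidden, ] <- FALSE; ok[, forbidden] <- FALSE }
  ok
}

#' Enumerate all nested secondary structures
#'
#' Explicit recursive enumeration of every nested structure (minimum hairpin
#' loop 3, Watson-Crick + GU pairs) of a sequence, as a list of two-column
#' pair matrices (the empty structure included).  Exponential; intended for
#' sequences up to ~25 nt.
#'
#' @param seq RNA string.
#' @param forbidden positions barred from pairing.
#' @param maxspan maximal pair span, `0` = unlimited.
#' @return list of integer matrices with columns `i`, `j`.
#' @export
enumerateStructures <- function(seq, forbidden = integer(0), maxspan = 0L) {
  code <- encodeRNA(toupper(chartr("Tt", "Uu", seq)))
  ok <- .pairableMatrix(code, forbidden, maxspan)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  recur <- function(i, j) {
    if (i >= j) return(list(empty))
    out <- recur(i + 1L, j)                    # i unpaired
    for (k in seq_len(j)) {
      if (k < i + 4L || !ok[i, k]) next
      inner <- recur(i + 1L, k - 1L)
      outer <- recur(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  res <- recur(1L, length(code))
  lapply(res, function(m) {
    colnames(m) <- c("i", "j")
    m
  })
}

#' Loop-decomposition energy of one structure
#'
#' Scores a single nested structure under the bundled model by explicit loop
#' decomposition: hairpin, stack/interior/bulge and multiloop terms as
#' defined in [energyParams()].  Structures containing a loop the model
#' prohibits (interior loop above the size cap, pair span above `maxspan`)
#' get `Inf`.
#'
#' @param seq RNA string.
#' @param pairs two-column matrix of paired positions.
#' @param params model parameters.
#' @param maxspan maximal pair span, `0` = unlimited.
#' @return energy in kcal/mol.
#' @export
structureEnergy <- function(seq, pairs, params = energyParams(), maxspan = 0L) {
  if (nrow(pairs) == 0L) return(0)
  v <- strsplit(toupper(chartr("Tt", "Uu", seq)), "")[[1L]]
  pt <- function(i, j) pairTypeCode(v[i], v[j])
  if (any(pairs[, 2L] - pairs[, 1L] < 4L)) return(Inf)
  if (maxspan > 0L && any(pairs[, 2L] - pairs[, 1L] + 1L > maxspan)) return(Inf)
  if (any(vapply(seq_len(nrow(pairs)),
                 function(r) pt(pairs[r, 1L], pairs[r, 2L]) == 0L, logical(1))))
    return(Inf)
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  n <- nrow(pairs)
  # children of each pair: pairs directly inside, not nested deeper
  parent <- rep(0L, n)
  for (r in seq_len(n)) {
    best <- 0L
    for (s in seq_len(n)) {
      if (s == r) next
      if (pairs[s, 1L] < pairs[r, 1L] && pairs[s, 2L] > pairs[r, 2L]) {
        if (best == 0L || pairs[s, 1L] > pairs[best, 1L]) best <- s
      }
    }
    parent[r] <- best
  }
  E <- 0
  for (r in seq_len(n)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    ch <- which(parent == r)
    if (length(ch) == 0L) {
      L <- j - i - 1L
      if (L < 3L) return(Inf)
      E <- E + params$hairpin_a + params$hairpin_b * log(L / 3)
    } else if (length(ch) == 1L) {
      k <- pairs[ch, 1L]; l <- pairs[ch, 2L]
      g1 <- k - i - 1L; g2 <- j - l - 1L
      if (g1 == 0L && g2 == 0L) {
        E <- E + params$stack[PAIR_NAMES[pt(i, j)], PAIR_NAMES[pt(k, l)]]
      } else {
        s <- g1 + g2
        if (s > params$interior_cap) return(Inf)
        E <- E + params$interior_a + params$interior_b * log(s)
      }
    } else {
      E <- E + params$ml_a + params$ml_b * (1L + length(ch))
    }
  }
  E
}

#' Brute-force interval-unpaired probability
#'
#' Computes `Z_u / Z` by full structure enumeration and per-structure
#' Boltzmann weighting; the independent check for the partition-function
#' engine on sequences up to ~25 nt.
#'
#' @inheritParams enumerateStructures
#' @param interval `c(start, end)` 1-based inclusive.
#' @param params model parameters.
#' @return the probability.
#' @export
bruteForceUnpairedProbability <- function(seq, interval,
                                          forbidden = integer(0),
                                          params = energyParams(),
                                          maxspan = 0L) {
  structs <- enumerateStructures(seq, forbidden, maxspan)
  w <- vapply(structs, function(m) {
    E <- structureEnergy(seq, m, params, maxspan)
    if (is.finite(E)) exp(-E / params$RT) else 0
  }, numeric(1))
  touches <- vapply(structs, function(m) {
    if (nrow(m) == 0L) return(FALSE)
    any(m[, 1L] %in% interval[1L]:interval[2L] |
        m[, 2L] %in% interval[1L]:interval[2L])
  }, logical(1))
  sum(w[!touches]) / sum(w)
}

#' Brute-force optimal duplex energy
#'
#' Recursively enumerates every inter-molecular alignment (antiparallel,
#' per-strand gaps up to the model's cap, or a smaller cap for tractability)
#' and returns the minimum energy including the initiation penalty.
#' Exponential; for small sequences only.
#'
#' @param target,query RNA strings.
#' @param params model parameters.
#' @param gapCap per-strand gap cap used during enumeration (defaults to the
#'   model's `dup_gap_cap`).
#' @return minimum duplex energy in kcal/mol (`Inf` when no pair is possible).
#' @export
bruteForceDuplexEnergy <- function(target, query, params = energyParams(),
                                   gapCap = params$dup_gap_cap) {
  tv <- strsplit(toupper(chartr("Tt", "Uu", target)), "")[[1L]]
  qv <- strsplit(toupper(chartr("Tt", "Uu", query)), "")[[1L]]
  n <- length(tv); m <- length(qv)
  best <- Inf
  extend <- function(i, j, acc) {
    # acc: energy of the duplex whose 3'-most target pair is (i, j)
    if (acc < best) best <<- acc
    for (g1 in 0:gapCap) {
      ni <- i + 1L + g1
      if (ni > n) break
      for (g2 in 0:gapCap) {
        nj <- j - 1L - g2
        if (nj < 1L) break
        ptn <- pairTypeCode(tv[ni], qv[nj])
        if (ptn == 0L) next
        step <- if (g1 == 0L && g2 == 0L)
          params$stack[pairTypeCode(tv[i], qv[j]), ptn]
        else params$dup_loop_a + params$dup_loop_b * (g1 + g2)
        extend(ni, nj, acc + step)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (pairTypeCode(tv[i], qv[j]) != 0L) extend(i, j, params$dup_init)
  }
  best
}
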