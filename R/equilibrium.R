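## Mass-action equilibrium of the mRNA / sRNA / ribosome network.
##
## Overlap topology (sRNA site overlaps the docking site; no ternary complex):
##   K_R P_EF m_F r_F = m_R          ribosome binds RDS-exposing free mRNA
##   K_S m_F s_F      = m_S          sRNA binds free mRNA
##   s_F + m_S              = s_T
##   m_F + m_S + m_R        = m_T
##   r_F + n m_R            = r_T
## Active mRNA: m_TA = m_R.  Eliminating all species but m_R yields a cubic.
##
## Non-overlap topology adds the ternary complex M_SR:
##   K_R P_ES m_S r_F = m_SR
##   s_F + m_S + m_SR             = s_T
##   m_F + m_S + m_R + m_SR       = m_T
##   r_F + n (m_R + m_SR)         = r_T
## Active mRNA: m_TA = m_R + m_SR; elimination yields a quintic in m_TA.
##
## Copy numbers per cell are used directly as dimensionless activities
## against the energy-derived constants, exactly as the model defines them;
## no volume/standard-state conversion is applied.

#' Convert a binding free energy to an equilibrium constant
#'
#' `K = exp(-deltaG / (R T))`.
#'
#' @param deltaG free-energy difference, kcal/mol.
#' @param temperature kelvin.
#' @return the dimensionless constant.
#' @examples
#' energyToConstant(0)
#' @export
energyToConstant <- function(deltaG, temperature = DEFAULT_TEMPERATURE) {
  exp(-deltaG / (GAS_CONSTANT * temperature))
}

#' Convert between opening constants and exposure probabilities
#'
#' `P = K / (1 + K)` relates the equilibrium constant of the RDS unfolding
#' reaction to the probability of an exposed RDS; the inverse is
#' `K = P / (1 - P)`.  The inversion holds to machine precision while
#' `1 - P` retains full relative accuracy, i.e. for `K` up to ~1e3.
#'
#' @param K dimensionless constant (>= 0).
#' @param P probability in [0, 1).
#' @return a probability, resp. a constant.
#' @examples
#' constantToProbability(1)
#' @export
constantToProbability <- function(K) {
  if (any(K < 0)) stop("K must be >= 0")
  K / (1 + K)
}

#' @rdname constantToProbability
#' @export
probabilityToConstant <- function(P) {
  if (any(P < 0 | P >= 1)) stop("P must be in [0, 1)")
  P / (1 - P)
}

# upper bound of the physical box for the active-mRNA variable
.xMax <- function(mT, rT, n) min(mT, rT / n)

#' Baseline: ribosome-bound mRNA without sRNA
#'
#' Solves `m_R = K_R P_EF (m_T - m_R)(r_T - n m_R)` in closed form
#' (the stable root of the quadratic) on `[0, min(m_T, r_T/n)]`.
#'
#' @param kR ribosome binding constant.
#' @param pEF RDS exposure probability of the free mRNA.
#' @param mT,rT total mRNA and available ribosomes.
#' @param n ribosome occupancy.
#' @return the baseline `m_R` (equal to `m_TA(0)`).
#' @examples
#' solveNoSrna(1e3, 1e-2, mT = 100, rT = 11400, n = 20)
#' @export
solveNoSrna <- function(kR, pEF, mT, rT, n = 20) {
  A <- kR * pEF
  if (A <= 0 || mT <= 0 || rT <= 0) return(0)
  # A n x^2 - (1 + A rT + A n mT) x + A mT rT = 0
  a <- A * n
  b <- -(1 + A * rT + A * n * mT)
  cc <- A * mT * rT
  disc <- b * b - 4 * a * cc
  if (disc < 0) {
    if (disc > -1e-8 * b * b) disc <- 0
    else stop("no feasible baseline root (negative discriminant)")
  }
  q <- -(b - sqrt(disc)) / 2      # b < 0, so this is the large magnitude
  x <- cc / q                     # the smaller (feasible) root
  min(max(x, 0), .xMax(mT, rT, n))
}

# balance residuals, named; scale-aware checking is done by callers
.residuals <- function(sp, p) {
  if (p@topology == "overlap") {
    c(sBalance = sp[["sF"]] + sp[["mS"]] - p@sT,
      mBalance = sp[["mF"]] + sp[["mS"]] + sp[["mR"]] - p@mT,
      rBalance = sp[["rF"]] + p@n * sp[["mR"]] - p@rT)
  } else {
    c(sBalance = sp[["sF"]] + sp[["mS"]] + sp[["mSR"]] - p@sT,
      mBalance = sp[["mF"]] + sp[["mS"]] + sp[["mR"]] + sp[["mSR"]] - p@mT,
      rBalance = sp[["rF"]] + p@n * (sp[["mR"]] + sp[["mSR"]]) - p@rT)
  }
}

.makeResult <- function(sp, p) {
  mTA <- if (p@topology == "overlap") sp[["mR"]] else sp[["mR"]] + sp[["mSR"]]
  new("EquilibriumResult", mF = sp[["mF"]], mS = sp[["mS"]], mR = sp[["mR"]],
      mSR = sp[["mSR"]], sF = sp[["sF"]], rF = sp[["rF"]], mTA = mTA,
      residuals = .residuals(sp, p), params = p)
}

.checkResult <- function(res, p, tol = 1e-9) {
  scale <- pmax(1, c(p@sT, p@mT, p@rT))
  if (any(abs(res@residuals) > tol * scale))
    stop(sprintf("equilibrium solver did not converge (max residual %.3g)",
                 max(abs(res@residuals) / scale)))
  sp <- species(res)
  if (any(sp < -tol * max(scale)))
    stop("equilibrium solver produced a negative species")
  res
}

# simple ascending-coefficient polynomial convolution
.pconv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
.padd <- function(...) {
  ps <- list(...)
  n <- max(lengths(ps))
  Reduce(`+`, lapply(ps, function(p) c(p, numeric(n - length(p)))))
}

# real roots of an ascending-coefficient polynomial near [lo, hi] (unclamped)
.realRootsIn <- function(coef, lo, hi, rtol = 1e-6) {
  coef <- coef / max(abs(coef))
  while (length(coef) > 1L && abs(coef[length(coef)]) < 1e-300)
    coef <- coef[-length(coef)]
  if (length(coef) <= 1L) return(numeric(0))
  z <- polyroot(coef)
  re <- Re(z)[abs(Im(z)) <= rtol * (1 + abs(Re(z)))]
  span <- hi - lo
  sort(re[re >= lo - rtol * span & re <= hi + rtol * span])
}

# Consistency guard for the eliminated polynomial: the solved value must be a
# root (in the backward-error sense), and no *other* clearly interior root may
# reconstruct to a physical species set -- the equilibrium is unique, so a
# second feasible root would mean the elimination or the solver is wrong.
# Roots hugging the box edges are skipped: reconstruction there divides by a
# vanishing free-species concentration and is numerically meaningless.
.eliminationGuard <- function(coef, t, p, reconstruct) {
  pw <- t^(seq_along(coef) - 1)
  if (abs(sum(coef * pw)) > 1e-6 * (sum(abs(coef * pw)) + 1e-300))
    stop("solution is not a root of the eliminated polynomial")
  box <- .xMax(p@mT, p@rT, p@n)
  scale <- max(1, p@mT, p@sT, p@rT)
  others <- .realRootsIn(coef, 0, box)
  for (r in others) {
    if (abs(r - t) <= 1e-3 * max(abs(t), 1e-3 * box)) next
    if (r < 1e-9 * box || r > box * (1 - 1e-9)) next
    sp <- reconstruct(r)
    feasible <- all(is.finite(sp)) && all(sp > -1e-9 * scale) &&
      all(sp[c("mF", "mS", "mR", "mSR")] <= p@mT * (1 + 1e-9)) &&
      sp[["mS"]] <= p@sT * (1 + 1e-9) && sp[["sF"]] <= p@sT * (1 + 1e-9) &&
      sp[["rF"]] <= p@rT * (1 + 1e-9)
    if (feasible)
      stop("multiple feasible roots of the eliminated polynomial")
  }
  invisible(TRUE)
}

# deterministic bisection to near machine precision; f(lo) and f(hi) must
# have opposite signs
.bisect <- function(f, lo, hi, iter = 200L) {
  flo <- f(lo)
  if (flo == 0) return(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

## ---------- overlap topology ----------

.overlapSpecies <- function(x, p) {
  A <- p@kR * p@pEF
  rF <- p@rT - p@n * x
  mF <- if (x == 0) 0 else x / (A * rF)
  mS <- if (p@kS > 0 && p@sT > 0) p@kS * mF * p@sT / (1 + p@kS * mF) else 0
  c(mF = mF, mS = mS, mR = x, mSR = 0,
    sF = p@sT - mS, rF = rF)
}

# all species from the free mRNA, in cancellation-free closed forms
.overlapFromFreeMrna <- function(mF, p) {
  A <- p@kR * p@pEF
  sF <- p@sT / (1 + p@kS * mF)
  rF <- p@rT / (1 + p@n * A * mF)
  c(mF = mF, mS = p@kS * mF * sF, mR = A * mF * rF, mSR = 0,
    sF = sF, rF = rF)
}

# log-space bisection on a positive variable; h must be increasing with
# h(lo) < 0 <= h(hi)
.logBisect <- function(h, lo, hi, iter = 160L) {
  ulo <- log(lo); uhi <- log(hi)
  for (i in seq_len(iter)) {
    um <- (ulo + uhi) / 2
    if (h(exp(um)) < 0) ulo <- um else uhi <- um
  }
  exp((ulo + uhi) / 2)
}

# the eliminated cubic in x = m_R (ascending coefficients)
.overlapCubic <- function(p) {
  A <- p@kR * p@pEF; K <- p@kS
  rF <- c(p@rT, -p@n)
  ArF <- A * rF
  .padd(.pconv(c(0, 1), ArF),
        c(0, 0, K),
        K * p@sT * .pconv(c(0, 1), ArF),
        .pconv(c(-p@mT, 1), .pconv(ArF, ArF)),
        K * .pconv(.pconv(c(-p@mT, 1), c(0, 1)), ArF))
}

#' Solve the overlap-topology equilibrium
#'
#' sRNA site and ribosome docking site overlap: ribosome and sRNA compete
#' for the mRNA and no ternary complex exists (`m_SR = 0`).  The mass-action
#' system is eliminated to a single equation in `m_R`, whose unique root in
#' the physical box `[0, min(m_T, r_T/n)]` is located by monotone bisection;
#' the eliminated cubic polynomial is used as a guard that exactly one root
#' lies in the box.
#'
#' @param p an [EquilibriumParams-class] with `topology = "overlap"`.
#' @return an [EquilibriumResult-class]; `activeMrna()` gives `m_TA = m_R`.
#' @examples
#' p <- equilibriumParams(kR = 1e5, kS = 1e8, pEF = 1e-2,
#'                        mT = 100, sT = 66, rT = 11400, n = 20,
#'                        topology = "overlap")
#' activeMrna(solveOverlap(p))
#' @export
solveOverlap <- function(p) {
  stopifnot(is(p, "EquilibriumParams"), p@topology == "overlap")
  if (p@sT == 0 || p@kS == 0) {
    x <- solveNoSrna(p@kR, p@pEF, p@mT, p@rT, p@n)
    return(.checkResult(.makeResult(.overlapSpecies(x, p), p), p))
  }
  if (p@mT == 0)
    return(.makeResult(c(mF = 0, mS = 0, mR = 0, mSR = 0, sF = p@sT,
                         rF = p@rT), p))
  # eliminate onto the free mRNA: the mass balance
  #   h(mF) = mF + mS(mF) + mR(mF) - mT
  # is strictly increasing, and every species is a stable closed form of mF
  h <- function(mF) {
    sp <- .overlapFromFreeMrna(mF, p)
    sp[["mF"]] + sp[["mS"]] + sp[["mR"]] - p@mT
  }
  mF <- .logBisect(h, p@mT * 1e-300, p@mT)
  sp <- .overlapFromFreeMrna(mF, p)
  .eliminationGuard(.overlapCubic(p), sp[["mR"]], p,
                    function(r) .overlapSpecies(r, p))
  .checkResult(.makeResult(sp, p), p)
}

## ---------- non-overlap topology ----------

# species from (t = m_TA); linear solve for m_F, m_S given t
.nonoverlapSpecies <- function(t, p) {
  A <- p@kR * p@pEF; B <- p@kR * p@pES
  y <- p@rT - p@n * t
  D <- B - A
  mF <- (B * p@mT * y - (1 + B * y) * t) / (D * y)
  mS <- ((1 + A * y) * t - A * p@mT * y) / (D * y)
  c(mF = mF, mS = mS, mR = A * mF * y, mSR = B * mS * y,
    sF = p@sT - mS * (1 + B * y), rF = y)
}

# residual of the sRNA-binding equation at t, in the unexpanded (well-scaled)
# form; its zero is the quintic root
.nonoverlapResidual <- function(t, p) {
  A <- p@kR * p@pEF; B <- p@kR * p@pES; K <- p@kS
  y <- p@rT - p@n * t
  D <- B - A
  Ft <- B * p@mT * y - (1 + B * y) * t     # m_F * D * y
  Gt <- (1 + A * y) * t - A * p@mT * y     # m_S * D * y
  Gt * (D * y + K * Ft * (1 + B * y)) - K * Ft * p@sT * D * y
}

# quintic in t = m_TA, ascending coefficients
.nonoverlapQuintic <- function(p) {
  A <- p@kR * p@pEF; B <- p@kR * p@pES; K <- p@kS
  D <- B - A
  yP <- c(p@rT, -p@n)
  oneBy <- c(1 + B * p@rT, -B * p@n)
  oneAy <- c(1 + A * p@rT, -A * p@n)
  FP <- .padd(B * p@mT * yP, -.pconv(c(0, 1), oneBy))
  GP <- .padd(.pconv(c(0, 1), oneAy), -A * p@mT * yP)
  .padd(.pconv(GP, .padd(D * yP, K * .pconv(FP, oneBy))),
        -K * p@sT * D * .pconv(FP, yP))
}

# equal exposure probabilities: m_F and m_S act as one pool and the active
# mRNA equals the no-sRNA baseline exactly
.nonoverlapEqualP <- function(p) {
  t <- solveNoSrna(p@kR, p@pEF, p@mT, p@rT, p@n)
  y <- p@rT - p@n * t
  B <- p@kR * p@pES
  w <- p@mT - t
  cc <- p@kS * (1 + B * y)
  # m_F + m_S = w with m_S = K m_F s_T / (1 + c m_F):
  # c m_F^2 + (1 + K s_T - c w) m_F - w = 0  (stable quadratic branches)
  bq <- 1 + p@kS * p@sT - cc * w
  mF <- if (cc == 0) {
    w / (1 + p@kS * p@sT)
  } else if (bq >= 0) {
    2 * w / (bq + sqrt(bq * bq + 4 * cc * w))
  } else {
    (-bq + sqrt(bq * bq + 4 * cc * w)) / (2 * cc)
  }
  mF <- min(max(mF, 0), w)
  mS <- w - mF
  # split the active pool; the active total is t by construction, so set it
  # directly (m_R + m_SR re-summed in floating point can drop an ulp, which
  # would flip the sign convention of an exactly neutral fold change)
  mR <- min(p@kR * p@pEF * mF * y, t)
  mSR <- t - mR
  sp <- c(mF = mF, mS = mS, mR = mR, mSR = mSR,
          sF = p@sT - mS - mSR, rF = y)
  new("EquilibriumResult", mF = sp[["mF"]], mS = sp[["mS"]], mR = sp[["mR"]],
      mSR = sp[["mSR"]], sF = sp[["sF"]], rF = sp[["rF"]], mTA = t,
      residuals = .residuals(sp, p), params = p)
}

# stable nested elimination: inner root in r_F for fixed m_F (the ribosome
# balance is increasing in r_F), outer root in m_F (the mRNA balance); every
# species is a cancellation-free closed form of (m_F, r_F)
.nonoverlapFromFree <- function(mF, y, p) {
  A <- p@kR * p@pEF; B <- p@kR * p@pES; K <- p@kS
  den <- 1 + K * mF * (1 + B * y)
  sF <- p@sT / den
  mS <- K * mF * sF
  c(mF = mF, mS = mS, mR = A * mF * y, mSR = B * mS * y, sF = sF, rF = y)
}

.nonoverlapSolveFree <- function(p) {
  A <- p@kR * p@pEF; B <- p@kR * p@pES; K <- p@kS
  mSof <- function(mF, y) K * mF * p@sT / (1 + K * mF * (1 + B * y))
  yOf <- function(mF) {
    g <- function(y) y * (1 + p@n * (A * mF + B * mSof(mF, y))) - p@rT
    .logBisect(g, p@rT * 1e-300, p@rT)
  }
  psi <- function(mF) {
    y <- yOf(mF)
    mS <- mSof(mF, y)
    mF * (1 + A * y) + mS * (1 + B * y) - p@mT
  }
  mF <- .logBisect(psi, p@mT * 1e-300, p@mT)
  .nonoverlapFromFree(mF, yOf(mF), p)
}

#' Solve the non-overlap-topology equilibrium
#'
#' sRNA site and docking site are spatially separated, so the ternary
#' ribosome-mRNA-sRNA complex `M_SR` exists and is translationally active:
#' `m_TA = m_R + m_SR`.  The seven-equation system is eliminated to a
#' quintic polynomial in `m_TA`; its unique feasible root (every species in
#' its physical range) is selected, refined by bisection on the un-expanded
#' residual and validated against the conservation balances.  When
#' `P_ES = P_EF` the system reduces exactly to the no-sRNA baseline (sRNA
#' binding that does not change accessibility does not change activity) and
#' that reduction is used directly.
#'
#' @param p an [EquilibriumParams-class] with `topology = "nonoverlap"`.
#' @return an [EquilibriumResult-class].
#' @examples
#' p <- equilibriumParams(kR = 1e5, kS = 1e8, pEF = 1e-4, pES = 1e-2,
#'                        mT = 100, sT = 66, rT = 11400, n = 20,
#'                        topology = "nonoverlap")
#' activeMrna(solveNonoverlap(p))
#' @export
solveNonoverlap <- function(p) {
  stopifnot(is(p, "EquilibriumParams"), p@topology == "nonoverlap")
  if (p@sT == 0 || p@kS == 0) {
    x <- solveNoSrna(p@kR, p@pEF, p@mT, p@rT, p@n)
    y <- p@rT - p@n * x
    A <- p@kR * p@pEF
    sp <- c(mF = if (x == 0) 0 else x / (A * y), mS = 0, mR = x, mSR = 0,
            sF = p@sT, rF = y)
    sp[["mF"]] <- p@mT - x   # exact by the mass balance
    return(.checkResult(.makeResult(sp, p), p))
  }
  if (p@mT == 0)
    return(.makeResult(c(mF = 0, mS = 0, mR = 0, mSR = 0, sF = p@sT,
                         rF = p@rT), p))
  A <- p@kR * p@pEF; B <- p@kR * p@pES
  if (abs(B - A) <= 1e-13 * max(A, B))
    return(.checkResult(.nonoverlapEqualP(p), p))

  sp <- .nonoverlapSolveFree(p)
  res <- .makeResult(sp, p)
  # Guard against the eliminated quintic.  Near P_ES == P_EF the
  # reconstruction of species from a root divides by K_R (P_ES - P_EF) and
  # is meaningless, so the guard is skipped there.
  if (abs(B - A) > 1e-6 * max(A, B)) {
    .eliminationGuard(.nonoverlapQuintic(p), activeMrna(res), p,
                      function(r) .nonoverlapSpecies(r, p))
  }
  .checkResult(res, p)
}

#' Solve an equilibrium by topology
#'
#' Dispatches to [solveOverlap()] or [solveNonoverlap()].
#'
#' @param p an [EquilibriumParams-class].
#' @return an [EquilibriumResult-class].
#' @export
solveEquilibrium <- function(p) {
  if (p@topology == "overlap") solveOverlap(p) else solveNonoverlap(p)
}

#' Signed fold change of translational activity
#'
#' `alpha = m_with / m_without` when activity does not decrease, and
#' `alpha = -m_without / m_with` otherwise, so that `|alpha| >= 1` always
#' and the sign carries the direction (activation positive, repression
#' negative).  Equal activities give `+1`.
#'
#' @param mWith active mRNA with sRNA present.
#' @param mWithout active mRNA without sRNA (must be > 0).
#' @return the signed ratio; `-Inf` when the sRNA abolishes activity.
#' @examples
#' foldChange(10, 5)
#' foldChange(5, 10)
#' @export
foldChange <- function(mWith, mWithout) {
  if (mWithout <= 0) stop("baseline inactive: m_TA(0) must be > 0")
  if (mWith == 0) return(-Inf)
  if (mWith >= mWithout) mWith / mWithout else -mWithout / mWith
}
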