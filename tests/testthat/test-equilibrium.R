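# Mass-action solvers: constants, baselines, topologies, fold changes.

RT <- 1.9872e-3 * 310.15

test_that("energy/constant/probability conversions are exact and invert", {
  expect_equal(energyToConstant(0), 1)
  expect_equal(energyToConstant(-RT * log(10)), 10, tolerance = 1e-12)
  # a strong published-scale interaction energy gives exp(22.9/RT)
  expect_equal(energyToConstant(-22.9), exp(22.9 / RT), tolerance = 1e-12)
  expect_equal(constantToProbability(1), 0.5)
  expect_equal(constantToProbability(0), 0)
  expect_equal(constantToProbability(3), 0.75)
  # the inversion is well-conditioned while 1 - P carries full precision,
  # i.e. for K up to ~1e3; beyond that P saturates at 1 in double precision
  for (K in 10^seq(-6, 3, by = 1)) {
    expect_equal(probabilityToConstant(constantToProbability(K)), K,
                 tolerance = 1e-12)
  }
})

test_that("the no-sRNA baseline solves its quadratic and respects limits", {
  # vanishing binding -> no initiation complexes
  expect_equal(solveNoSrna(1e-30, 1e-30, 100, 11400, 20), 0, tolerance = 1e-20)
  # saturation -> the smaller of mRNA and ribosome capacity
  expect_equal(solveNoSrna(1e30, 1, 100, 11400, 20), 100, tolerance = 1e-6)
  expect_equal(solveNoSrna(1e30, 1, 1e4, 11400, 20), 11400 / 20,
               tolerance = 1e-6)
  # against a bracketed bisection oracle on the same scalar equation
  A <- 1e3 * 1e-2
  f <- function(x) A * (100 - x) * (11400 - 20 * x) - x
  lo <- 0; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(solveNoSrna(1e3, 1e-2, 100, 11400, 20), (lo + hi) / 2,
               tolerance = 1e-10)
})

test_that("both topologies agree with the un-eliminated-system oracle", {
  set.seed(77)
  for (topo in c("overlap", "nonoverlap")) {
    for (k in 1:40) {
      p <- randomFeasibleParams(topo)
      main <- solveEquilibrium(p)
      expect_lte(maxSpeciesRelDiff(main, oracleSolve(p)), 1e-8)
      # conservation balances hold to scale
      expect_lte(max(abs(main@residuals) /
                     pmax(1, c(p@sT, p@mT, p@rT))), 1e-9)
      expect_true(all(species(main) >= -1e-9 * max(1, p@mT, p@sT, p@rT)))
    }
  }
})

test_that("degenerate and limiting inputs collapse to the baseline", {
  base <- solveNoSrna(1e5, 1e-2, 100, 11400, 20)
  p0 <- equilibriumParams(kR = 1e5, kS = 1e8, pEF = 1e-2, mT = 100, sT = 0,
                          rT = 11400, n = 20, topology = "overlap")
  r0 <- solveOverlap(p0)
  expect_identical(activeMrna(r0), base)
  expect_identical(r0@mS, 0)
  expect_identical(r0@sF, 0)
  pn <- equilibriumParams(kR = 1e5, kS = 1e8, pEF = 1e-2, pES = 0.7,
                          mT = 100, sT = 0, rT = 11400, n = 20,
                          topology = "nonoverlap")
  expect_identical(activeMrna(solveNonoverlap(pn)), base)
  # total sequestration: huge K_S with excess sRNA abolishes activity
  ps <- equilibriumParams(kR = 1e5, kS = 1e25, pEF = 1e-2, mT = 100,
                          sT = 1000, rT = 11400, n = 20, topology = "overlap")
  expect_lt(activeMrna(solveOverlap(ps)), 1e-10 * base)
})

test_that("fold change is the signed ratio with |alpha| >= 1", {
  expect_equal(foldChange(10, 5), 2)
  expect_equal(foldChange(5, 10), -2)
  expect_equal(foldChange(7, 7), 1)
  expect_identical(foldChange(0, 5), -Inf)
  expect_error(foldChange(5, 0), "baseline")
})

test_that("alpha limit identities hold", {
  # s_T = 0 gives alpha = +1 exactly in both topologies
  for (topo in c("overlap", "nonoverlap")) {
    p <- equilibriumParams(kR = 3e4, kS = 1e9, pEF = 5e-3, pES = 0.4,
                           mT = 300, sT = 0, rT = 11400, n = 20,
                           topology = topo)
    a <- foldChange(activeMrna(solveEquilibrium(p)),
                    solveNoSrna(3e4, 5e-3, 300, 11400, 20))
    expect_identical(a, 1)
  }
  # P_ES = P_EF decouples binding from activity
  p <- equilibriumParams(kR = 3e4, kS = 1e9, pEF = 5e-3, pES = 5e-3,
                         mT = 300, sT = 200, rT = 11400, n = 20,
                         topology = "nonoverlap")
  a <- foldChange(activeMrna(solveNonoverlap(p)),
                  solveNoSrna(3e4, 5e-3, 300, 11400, 20))
  expect_equal(a, 1, tolerance = 1e-9)
  expect_gt(activeMrna(solveNonoverlap(p)) - 0, 0)
})

test_that("overlap alpha is monotone in s_T and K_S", {
  base <- solveNoSrna(1e4, 1e-2, 200, 11400, 20)
  alphas <- vapply(seq(0, 400, length.out = 50), function(sT) {
    p <- equilibriumParams(kR = 1e4, kS = 1e7, pEF = 1e-2, mT = 200,
                           sT = sT, rT = 11400, n = 20, topology = "overlap")
    foldChange(activeMrna(solveOverlap(p)), base)
  }, numeric(1))
  expect_equal(alphas[1], 1)
  expect_true(all(diff(alphas) <= 1e-10))
  alphasK <- vapply(10^seq(2, 12, length.out = 20), function(kS) {
    p <- equilibriumParams(kR = 1e4, kS = kS, pEF = 1e-2, mT = 200,
                           sT = 133, rT = 11400, n = 20, topology = "overlap")
    foldChange(activeMrna(solveOverlap(p)), base)
  }, numeric(1))
  expect_true(all(diff(alphasK) <= 1e-10))
})

test_that("non-overlap alpha direction follows the accessibility change", {
  for (pEF in 10^seq(-4, -1, length.out = 6)) {
    for (pES in 10^seq(-4, -1, length.out = 6)) {
      p <- equilibriumParams(kR = 1e6, kS = 1e9, pEF = pEF, pES = pES,
                             mT = 150, sT = 100, rT = 11400, n = 20,
                             topology = "nonoverlap")
      a <- foldChange(activeMrna(solveNonoverlap(p)),
                      solveNoSrna(1e6, pEF, 150, 11400, 20))
      if (pES == pEF) expect_equal(a, 1, tolerance = 1e-9)
      else expect_identical(sign(a - 1), sign(pES - pEF))
    }
  }
})

test_that("the oracle reproduces the closed-form baseline at s_T = 0", {
  p <- equilibriumParams(kR = 1e3, kS = 1e6, pEF = 1e-2, mT = 100, sT = 0,
                         rT = 11400, n = 20, topology = "overlap")
  expect_equal(activeMrna(oracleSolve(p)),
               solveNoSrna(1e3, 1e-2, 100, 11400, 20), tolerance = 1e-10)
})
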