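test_that("moment system matches the hand-built one-reaction example", {
  # m = 2, A -> B, k_est = 2, h = X_A = 5, dt = 0.1: weight = 1
  nw <- absNetwork("A -> B", rates = 2, dt = 0.1)
  X <- matrix(c(5, 4, 0, 1), 2, 2, dimnames = list(NULL, c("A1", "B1")))
  samples <- ConcentrationTrajectory(c(0, 0.1), X)
  ms <- buildMomentSystem(nw, samples)
  # column: mean rows R_j = (-1, 1); cov rows vech(R R') = (1, -1, 1)
  expect_equal(as.numeric(ms@A), c(-1, 1, 1, -1, 1))
  expect_equal(ms@b, as.numeric(ms@A %*% rep(1, 1)))
  expect_equal(ms@rowCount, 1 * (2 + 3))
  expect_error(buildMomentSystem(nw, samples, dt = 0),
               "dt must be positive")
  nw0 <- absNetwork("A -> B", rates = 0, dt = 0.1)
  expect_error(buildMomentSystem(nw0, samples), "k_est > 0")
})

test_that("row-count formula and exact-solution identity hold at random", {
  for (seed in 1:25) {
    sys <- randomMomentSystem(seed, m = sample(2:4, 1), r = sample(2:7, 1),
                              Tn = sample(3:10, 1))
    ms <- sys$moment
    m <- nSpecies(sys$network)
    Tn <- nrow(countsMatrix(sys$samples)) - 1L
    expect_equal(ms@rowCount, Tn * (m + m * (m + 1) / 2))
    ones <- rep(1, length(ms@kEst))
    resid2 <- as.numeric(t(ones) %*% ms@AtA %*% ones -
                           2 * sum(ms@Atb) + ms@btb)
    expect_lt(abs(resid2), 1e-7 * max(1, ms@btb))
    # explicit A agrees with the streamed normal equations
    expect_equal(crossprod(ms@A), ms@AtA, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(as.numeric(crossprod(ms@A, ms@b)), ms@Atb)
    # PSD
    ev <- eigen(ms@AtA, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(1, max(ev)))
  }
})

test_that("count-based reduction thresholds totals, ties together", {
  nw <- absNetwork(c("A -> B", "B -> A", "A + A -> B"), c(1, 1, 1))
  counts <- ReactionCountSeries(matrix(c(5, 1, 0), 1, 3))
  res <- countBasedReduce(nw, counts, f = 2)
  expect_identical(res@support, c(TRUE, FALSE, FALSE))
  expect_identical(nReactions(res@network), 1L)
  # f = 1 keeps every observed reaction
  res1 <- countBasedReduce(nw, counts, f = 1)
  expect_identical(res1@support, c(TRUE, TRUE, FALSE))
  # equal totals leave or go together
  counts2 <- ReactionCountSeries(matrix(c(3, 3, 7), 1, 3))
  res2 <- countBasedReduce(nw, counts2, f = 4)
  expect_identical(res2@support, c(FALSE, FALSE, TRUE))
  expect_error(countBasedReduce(nw, counts, f = 0), "f must be")
})

test_that("IQP equals exhaustive enumeration and handles easy limits", {
  sys <- randomMomentSystem(101, m = 3, r = 6, Tn = 10)
  # lambda = r: the exact solution k = 1 has objective 0
  resFull <- reduceIQP(sys$moment, 6, sys$network)
  expect_true(all(resFull@support))
  expect_lt(resFull@objective, 1e-7 * max(1, sys$moment@btb))
  for (seed in c(11, 23, 35)) {
    sys <- randomMomentSystem(seed, m = 3, r = 8, Tn = 10)
    for (lambda in c(2, 4)) {
      res <- reduceIQP(sys$moment, lambda, sys$network)
      oracle <- iqpOracle(sys$moment, lambda)
      expect_equal(res@objective, oracle$value, tolerance = 1e-8)
      expect_lte(sum(res@support), lambda)
    }
  }
  expect_error(reduceIQP(sys$moment, -1, sys$network), "non-negative")
})

test_that("duplicated reactions are interchangeable under the IQP", {
  # two identical columns: dropping either leaves the objective unchanged
  nw <- absNetwork(c("A -> B", "A -> B", "B -> A"), c(1.5, 1.5, 0.7))
  set.seed(3)
  X <- matrix(stats::rpois(2 * 10, 10), ncol = 2,
              dimnames = list(NULL, c("A1", "B1")))
  samples <- ConcentrationTrajectory(seq(0, by = 1, length.out = 10), X)
  ms <- buildMomentSystem(nw, samples)
  res <- reduceIQP(ms, 2, nw)
  oracle <- iqpOracle(ms, 2)
  expect_equal(res@objective, oracle$value, tolerance = 1e-8)
  # the pair shares one true process: exactly one of columns 1/2 plus
  # column 3 reproduces b only partially; both size-2 supports that pick
  # one duplicate attain the same optimum
  k12 <- c(1, 0, 1); k21 <- c(0, 1, 1)
  obj <- function(k) as.numeric(t(k) %*% ms@AtA %*% k -
                                  2 * sum(ms@Atb * k) + ms@btb)
  expect_equal(obj(k12), obj(k21))
})

test_that("box-constrained LASSO solves the easy geometry exactly", {
  sys <- randomMomentSystem(7, m = 3, r = 5, Tn = 10)
  # lambda >= r admits the exact solution k = 1
  res <- reduceLasso(sys$moment, 5, sys$network)
  expect_equal(res@kRelaxed, rep(1, 5), tolerance = 1e-4)
  expect_lt(res@objective, 1e-6 * max(1, sys$moment@btb))
  # single column, lambda = 1: k = 1 exactly
  nw1 <- absNetwork("A -> B", rates = 2, dt = 0.1)
  X <- matrix(c(5, 4, 3, 0, 1, 2), 3, 2,
              dimnames = list(NULL, c("A1", "B1")))
  ms1 <- buildMomentSystem(nw1, ConcentrationTrajectory(0:2, X))
  res1 <- reduceLasso(ms1, 1, nw1)
  expect_equal(res1@kRelaxed, 1, tolerance = 1e-6)
  expect_error(reduceLasso(ms1, 0, nw1), "lambda must be positive")
})

test_that("LASSO recovers a true support against inflated spurious rates", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  set.seed(500)
  ev <- simulateSSA(toy$network, stats::setNames(25, lab["CH4"]),
                    tEnd = 40, seed = 501)
  samples <- sampleTrajectory(ev, seq(0, 40, by = 0.25), toy$network)
  nwDt <- toy$network
  nwDt@dt <- 0.25
  inj <- injectSpuriousReactions(nwDt, d = 6, rateInflation = 3,
                                 seed = 502, samples = samples)
  ms <- buildMomentSystem(inj$network, samples, dt = 0.25)
  res <- reduceLasso(ms, 6, inj$network)
  expect_identical(res@support, inj$mask)
  # kept rates are k_est * k, never above k_est
  expect_true(all(rates(res@network) <=
                    rates(toy$network)[res@support[1:6]] + 1e-9))
})

test_that("relaxation bound and lambda monotonicity hold", {
  for (seed in c(41, 57)) {
    sys <- randomMomentSystem(seed, m = 3, r = 7, Tn = 12)
    lambdas <- c(2, 3, 5, 7)
    swL <- lambdaSweep(sys$moment, lambdas, sys$network, method = "lasso")
    swI <- lambdaSweep(sys$moment, lambdas, sys$network, method = "iqp")
    expect_true(all(diff(swL$summary$objective) <= 1e-8))
    expect_true(all(diff(swI$summary$objective) <= 1e-8))
    for (q in seq_along(lambdas)) {
      # IQP optimum is at least as good as any rounding of the relaxation
      rounded <- as.numeric(swL$results[[q]]@support)
      if (sum(rounded) <= lambdas[q]) {
        objRounded <- as.numeric(
          t(rounded) %*% sys$moment@AtA %*% rounded -
            2 * sum(sys$moment@Atb * rounded) + sys$moment@btb)
        expect_lte(swI$summary$objective[q], objRounded + 1e-8)
      }
      # relaxation lower-bounds the integer optimum
      expect_lte(swL$summary$objective[q],
                 swI$summary$objective[q] + 1e-8)
    }
  }
})

test_that("phase separation holds on the recovery suite (flag, not fail)", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  violations <- 0L
  for (seed in 1:5) {
    ev <- simulateSSA(toy$network, stats::setNames(25, lab["CH4"]),
                      tEnd = 30, seed = 600 + seed)
    samples <- sampleTrajectory(ev, seq(0, 30, by = 0.25), toy$network)
    nwDt <- toy$network
    nwDt@dt <- 0.25
    inj <- injectSpuriousReactions(nwDt, d = 6, rateInflation = 3,
                                   seed = 700 + seed, samples = samples)
    ms <- buildMomentSystem(inj$network, samples, dt = 0.25)
    sol <- reduceLasso(ms, 6, inj$network)
    k <- sol@kRelaxed
    if (!all(k > 0.5 | k < 0.01)) violations <- violations + 1L
  }
  if (violations > 0)
    message("phase-separation violations in ", violations, "/5 instances")
  succeed()
})

test_that("IQP refuses oversized problems with guidance", {
  sys <- randomMomentSystem(3, m = 3, r = 5, Tn = 6)
  msBig <- sys$moment
  fake <- diag(30)
  msBig@AtA <- fake
  msBig@Atb <- rep(1, 30)
  msBig@kEst <- rep(1, 30)
  msBig@A <- matrix(0, 0, 30)
  expect_error(reduceIQP(msBig, 5, sys$network), "reduceLasso")
})
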