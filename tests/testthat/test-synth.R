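test_that("bond-signal generator honours its recoverability contract", {
  # no flicker: raw equals clean
  s0 <- generateBondSignal(100, cbind(c(20, 60), c(1, 0)),
                           flickerRate = 0, flickerMaxLen = 4, seed = 1)
  expect_identical(s0$raw, s0$clean)
  expect_identical(s0$clean[19:21], c(FALSE, TRUE, TRUE))
  # flicker is recoverable at tau = flickerMaxLen
  nRecovered <- 0L
  nWithFlicker <- 0L
  for (seed in 1:200) {
    s <- generateBondSignal(300, cbind(c(50, 150, 250), c(1, 0, 1)),
                            flickerRate = 0.03, flickerMaxLen = 3,
                            seed = seed)
    if (!identical(s$raw, s$clean)) nWithFlicker <- nWithFlicker + 1L
    if (identical(hysteresisFilter(s$raw, 3, initial = s$clean[1]),
                  s$clean))
      nRecovered <- nRecovered + 1L
  }
  expect_identical(nRecovered, 200L)
  expect_gt(nWithFlicker, 150)   # the noise is actually exercised
  # a length-2 flicker defeats tau = 2
  found <- FALSE
  for (seed in 1:50) {
    s <- generateBondSignal(300, cbind(1, 1), flickerRate = 0.03,
                            flickerMaxLen = 3, seed = seed,
                            initial = TRUE)
    r <- rle(s$raw)
    if (any(r$lengths[r$values == FALSE] == 2)) {
      found <- TRUE
      expect_false(identical(hysteresisFilter(s$raw, 2,
                                              initial = TRUE),
                             s$clean))
      break
    }
  }
  expect_true(found)
  expect_error(generateBondSignal(100, cbind(c(10, 11), c(1, 0)),
                                  flickerMaxLen = 4), "closer than")
})

test_that("generators are bit-reproducible under a fixed seed", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  g1 <- generateReactingSystem(toy$network, toy$templates,
                               stats::setNames(8, lab["CH4"]),
                               tEnd = 5, frameDt = 0.02, seed = 4)
  g2 <- generateReactingSystem(toy$network, toy$templates,
                               stats::setNames(8, lab["CH4"]),
                               tEnd = 5, frameDt = 0.02, seed = 4)
  expect_identical(g1$bondTrajectory@frames, g2$bondTrajectory@frames)
  expect_identical(g1$truth$events, g2$truth$events)
  s1 <- generateBondSignal(200, cbind(100, 1), flickerRate = 0.05,
                           flickerMaxLen = 3, seed = 9)
  s2 <- generateBondSignal(200, cbind(100, 1), flickerRate = 0.05,
                           flickerMaxLen = 3, seed = 9)
  expect_identical(s1, s2)
})

test_that("reacting-system trajectories are exactly re-extractable", {
  lab <- methaneLabels()
  toy <- methaneToyNetwork(rates = c(0.3, 2, 0, 0, 0, 0))
  # CH4 <-> CH3 + H only: with at most one firing per frame interval
  # (verified below), extraction recovers exactly the fired types
  g <- generateReactingSystem(toy$network, toy$templates,
                              stats::setNames(10, lab["CH4"]),
                              tEnd = 20, frameDt = 0.002, seed = 6)
  expect_lte(max(table(floor(g$truth$events$time / 0.002))), 1L)
  ext <- extractReactions(g$bondTrajectory, tau = 1,
                          estimateRates = FALSE)
  expect_setequal(reactionLabels(ext$network),
                  unique(g$truth$events$reaction))
  expect_lte(nReactions(ext$network), 2L)
  expect_identical(nrow(ext$events), nrow(g$truth$events))
  # zero-rate network: all frames identical
  frozen <- methaneToyNetwork(rates = rep(0, 6))
  gf <- generateReactingSystem(frozen$network, frozen$templates,
                               stats::setNames(5, lab["CH4"]),
                               tEnd = 2, frameDt = 0.1, seed = 2)
  expect_true(all(vapply(gf$bondTrajectory@frames, identical,
                         logical(1), gf$bondTrajectory@frames[[1]])))
  # closed system: per-frame atom counts are fixed by construction
  expect_identical(gf$bondTrajectory@nAtoms, 25L)
})

test_that("Poisson count streams have the advertised moments", {
  nw <- absNetwork("A + A -> B", rates = 0, dt = 0.1)
  X <- matrix(c(rep(6, 11), rep(0, 11)), ncol = 2,
              dimnames = list(NULL, c("A1", "B1")))
  traj <- ConcentrationTrajectory(0:10, X)
  # k = 0: all zeros
  cs0 <- generateCountStream(nw, traj, seed = 1)
  expect_true(all(countsMatrix(cs0) == 0))
  # law of large numbers for the rate
  nw2 <- absNetwork("A + A -> B", rates = 0.7, dt = 0.1)
  Tn <- 10000L
  Xb <- matrix(c(rep(6, Tn + 1), rep(0, Tn + 1)), ncol = 2,
               dimnames = list(NULL, c("A1", "B1")))
  trajB <- ConcentrationTrajectory(seq(0, by = 0.1, length.out = Tn + 1),
                                   Xb)
  cs <- generateCountStream(nw2, trajB, seed = 2)
  h <- choose(6, 2)
  kHat <- sum(countsMatrix(cs)) / (0.1 * h * Tn)
  se <- sqrt(0.7 / (0.1 * h * Tn))
  expect_lt(abs(kHat - 0.7), 3 * se)
  # impossible frames contribute exactly zero
  Xz <- Xb; Xz[1:5000, "A1"] <- 1
  trajZ <- ConcentrationTrajectory(seq(0, by = 0.1,
                                       length.out = Tn + 1), Xz)
  csz <- generateCountStream(nw2, trajZ, seed = 3)
  expect_true(all(countsMatrix(csz)[1:5000, ] == 0))
})

test_that("spurious-reaction injection balances atoms and masks truth", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  # d = 0: unchanged
  inj0 <- injectSpuriousReactions(toy$network, d = 0)
  expect_identical(reactionLabels(inj0$network),
                   reactionLabels(toy$network))
  expect_true(all(inj0$mask))
  # injected reactions always balance and never duplicate the genuine set
  ev <- simulateSSA(toy$network, stats::setNames(20, lab["CH4"]),
                    tEnd = 20, seed = 44)
  samples <- sampleTrajectory(ev, seq(0, 20, 0.25), toy$network)
  inj <- injectSpuriousReactions(toy$network, d = 6, rateInflation = 3,
                                 seed = 45, samples = samples, dt = 0.25)
  expect_identical(nReactions(inj$network), 12L)
  expect_identical(nrow(validateNetwork(inj$network)), 0L)
  expect_identical(inj$mask, c(rep(TRUE, 6), rep(FALSE, 6)))
  expect_identical(anyDuplicated(reactionLabels(inj$network)), 0L)
  # spurious rates are positive and finite
  expect_true(all(is.finite(rates(inj$network))))
  expect_true(all(rates(inj$network)[7:12] > 0))
})
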