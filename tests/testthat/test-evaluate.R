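mkTraj <- function(times, ...) {
  cols <- list(...)
  ConcentrationTrajectory(times,
    matrix(unlist(cols), ncol = length(cols),
           dimnames = list(NULL, names(cols))))
}

test_that("ensemble-mean RMSE closed forms hold", {
  times <- 0:4
  ref <- mkTraj(times, A1 = c(4, 3, 2, 1, 0))
  # two replicates whose mean equals the reference: error 0
  s1 <- mkTraj(times, A1 = c(4, 4, 2, 0, 0))
  s2 <- mkTraj(times, A1 = c(4, 2, 2, 2, 0))
  rep0 <- rmseVsReference(list(s1, s2), ref)
  expect_equal(unname(rep0$perSpecies["A1"]), 0)
  # constant offset of +2 gives RMSE 2
  s3 <- mkTraj(times, A1 = c(4, 3, 2, 1, 0) + 2)
  expect_equal(unname(rmseVsReference(list(s3), ref)$perSpecies["A1"]), 2)
  # random small case against a direct loop
  set.seed(8)
  sims <- lapply(1:4, function(q) mkTraj(times, A1 = rpois(5, 5)))
  got <- rmseVsReference(sims, ref)$perSpecies["A1"]
  mu <- rowMeans(sapply(sims, function(s) countsMatrix(s)[, "A1"]))
  want <- sqrt(mean((mu - countsMatrix(ref)[, "A1"])^2))
  expect_equal(unname(got), want)
  # misaligned grids error
  expect_error(rmseVsReference(list(mkTraj(0:3, A1 = rep(1, 4))), ref),
               "time grids")
})

test_that("mean per-replicate error dominates the ensemble-mean RMSE", {
  times <- 0:4
  ref <- mkTraj(times, A1 = c(4, 3, 2, 1, 0))
  # every replicate equal to the reference mean: 0
  reps <- list(ref, ref)
  expect_equal(unname(meanErrorBetweenModels(reps, ref)$perSpecies["A1"]),
               0)
  # S = 1 reduces to the plain RMSE of that replicate
  s1 <- mkTraj(times, A1 = c(5, 3, 1, 1, 2))
  e1 <- meanErrorBetweenModels(list(s1), ref)$perSpecies["A1"]
  expect_equal(unname(e1),
               sqrt(mean((countsMatrix(s1)[, "A1"] -
                            countsMatrix(ref)[, "A1"])^2)))
  # Jensen: mean-of-RMSE >= RMSE-of-mean on the same inputs
  set.seed(9)
  sims <- lapply(1:6, function(q) mkTraj(times, A1 = rpois(5, 4)))
  eM <- meanErrorBetweenModels(sims, ref)$perSpecies["A1"]
  eR <- rmseVsReference(sims, ref)$perSpecies["A1"]
  expect_gte(unname(eM), unname(eR) - 1e-12)
})

test_that("metrics are invariant to replicate and species order", {
  times <- 0:3
  set.seed(10)
  sims <- lapply(1:3, function(q)
    mkTraj(times, A1 = rpois(4, 5), B1 = rpois(4, 2)))
  ref <- mkTraj(times, A1 = c(5, 5, 5, 5), B1 = c(2, 2, 2, 2))
  base <- rmseVsReference(sims, ref)$perSpecies
  perm <- rmseVsReference(sims[c(3, 1, 2)], ref)$perSpecies
  expect_equal(base, perm)
  refSwap <- mkTraj(times, B1 = c(2, 2, 2, 2), A1 = c(5, 5, 5, 5))
  swap <- rmseVsReference(sims, refSwap)$perSpecies
  expect_equal(base[sort(names(base))], swap[sort(names(swap))])
})

test_that("support comparison measures common fraction and Jaccard", {
  toy <- methaneToyNetwork()
  full <- toy$network
  cmp1 <- compareSupports(list(full, full))
  expect_equal(cmp1$commonFraction, 1)
  expect_true(all(cmp1$jaccard == 1))
  sub <- ReactionNetwork(speciesList(full), reactionList(full)[1:3],
                         dt = deltaT(full))
  other <- ReactionNetwork(speciesList(full), reactionList(full)[4:6],
                           dt = deltaT(full))
  cmp0 <- compareSupports(list(sub, other))
  expect_equal(cmp0$commonFraction, 0)
  # {a,b,c} vs {b,c,d} vs {b,c} -> 2/4
  n1 <- ReactionNetwork(speciesList(full), reactionList(full)[1:3],
                        dt = deltaT(full))
  n2 <- ReactionNetwork(speciesList(full), reactionList(full)[2:4],
                        dt = deltaT(full))
  n3 <- ReactionNetwork(speciesList(full), reactionList(full)[2:3],
                        dt = deltaT(full))
  cmp <- compareSupports(list(n1, n2, n3))
  expect_equal(cmp$commonFraction, 0.5)
  expect_equal(cmp$jaccard[1, 2], 2 / 4)
})

test_that("bond-duration selection scans the error curve", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  g <- generateReactingSystem(toy$network, toy$templates,
                              stats::setNames(10, lab["CH4"]),
                              tEnd = 8, frameDt = 0.01, seed = 19)
  # shortest post-initial bonded/unbonded run of any atom pair: taus at or
  # below it must extract identical event sets (flat start of the curve)
  frames <- g$bondTrajectory@frames
  n <- g$bondTrajectory@nAtoms
  keyList <- lapply(frames, function(f) (f[, 1] - 1) * n + f[, 2])
  keys <- sort(unique(unlist(keyList)))
  sig <- matrix(FALSE, length(keys), length(frames))
  for (f in seq_along(frames)) sig[match(keyList[[f]], keys), f] <- TRUE
  minRun <- min(unlist(lapply(seq_len(nrow(sig)), function(p) {
    r <- rle(sig[p, ])$lengths
    if (length(r) > 1) r[-1] else Inf   # the initial state is always kept
  })))
  minRun <- min(minRun, 50)
  expect_gt(minRun, 1)
  taus <- unique(c(1, minRun, minRun + 4))
  sel <- selectBondDuration(g$bondTrajectory, tauGrid = taus, S = 5,
                            seed = 20)
  expect_identical(sel$curve$events[1], sel$curve$events[2])
  expect_identical(sel$curve$error[1], sel$curve$error[2])
  expect_true(all(is.finite(sel$curve$error)))
  expect_true(sel$tauStar %in% taus)
  # tau longer than the trajectory: no events, finite frozen-model error
  selBig <- selectBondDuration(g$bondTrajectory, tauGrid = c(1, 10000),
                               S = 2, seed = 21)
  expect_identical(selBig$curve$events[2], 0)
  expect_true(is.finite(selBig$curve$error[2]))
  # freezing a reacting system scores worse than the fitted model
  expect_gt(selBig$curve$error[2], selBig$curve$error[1])
  expect_identical(selBig$tauStar, 1L)
})

test_that("vibrational flicker inflates event counts below its duration", {
  # one H2 whose bond flickers off for 2 frames repeatedly
  sig <- generateBondSignal(400, trueTransitions = cbind(1, 1),
                            flickerRate = 0.05, flickerMaxLen = 3,
                            seed = 33, initial = TRUE)
  frames <- lapply(sig$raw, function(b)
    if (b) cbind(1L, 2L) else matrix(integer(), ncol = 2))
  bt <- BondTrajectory(c("H", "H"), frames, frameDt = 0.1)
  nEv <- function(tau) nrow(extractReactions(bt, tau = tau,
                                             estimateRates = FALSE)$events)
  expect_gt(nEv(1), 0)      # flicker registers without smoothing
  expect_identical(nEv(3), 0L)  # smoothed away at tau = flickerMaxLen
  expect_gt(nEv(2), nEv(3))
})
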