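test_that("hysteresis filter matches the stated examples", {
  expect_identical(hysteresisFilter(c(1, 1, 1, 0, 1, 1, 1, 1), tau = 1,
                                    initial = FALSE),
                   as.logical(c(1, 1, 1, 0, 1, 1, 1, 1)))
  expect_identical(hysteresisFilter(c(1, 0, 1, 0, 1, 0), tau = 2,
                                    initial = FALSE),
                   rep(FALSE, 6))
  expect_identical(hysteresisFilter(c(0, 1, 1, 1, 0, 0, 0, 1), tau = 3,
                                    initial = FALSE),
                   as.logical(c(0, 1, 1, 1, 0, 0, 0, 0)))
  expect_error(hysteresisFilter(c(1, 0), tau = 0), "tau")
})

test_that("hysteresis filter equals the brute-force automaton", {
  set.seed(42)
  for (q in 1:400) {
    n <- sample(1:200, 1)
    raw <- stats::runif(n) < stats::runif(1)
    tau <- sample(1:20, 1)
    init <- sample(c(TRUE, FALSE), 1)
    expect_identical(hysteresisFilter(raw, tau, initial = init),
                     hysteresisOracle(raw, tau, initial = init))
  }
})

test_that("distance cutoffs define raw bond states (boundary inclusive)", {
  cutoffs <- c("C-C" = 1.98, "C-H" = 1.57, "H-H" = 1.09)
  frames <- list(rbind(c(0, 0, 0), c(1.50, 0, 0)))
  bt <- bondStatesFromCoordinates(frames, c("C", "H"), cutoffs)
  expect_identical(bt@frames[[1]], cbind(1L, 2L))
  # exactly at the cutoff counts as bonded
  bt2 <- bondStatesFromCoordinates(list(rbind(c(0, 0, 0), c(1.09, 0, 0))),
                                   c("H", "H"), cutoffs)
  expect_identical(nrow(bt2@frames[[1]]), 1L)
  bt3 <- bondStatesFromCoordinates(list(rbind(c(0, 0, 0), c(10, 0, 0))),
                                   c("H", "H"), cutoffs)
  expect_identical(nrow(bt3@frames[[1]]), 0L)
  expect_error(
    bondStatesFromCoordinates(frames, c("C", "O"), cutoffs),
    "missing bond-length cutoff")
  # periodic minimum image: atoms near opposite faces are close
  btp <- bondStatesFromCoordinates(list(rbind(c(0.2, 0, 0), c(9.9, 0, 0))),
                                   c("H", "H"), cutoffs, box = c(10, 10, 10))
  expect_identical(nrow(btp@frames[[1]]), 1L)
})

test_that("molecules are connected components labelled as species", {
  lab <- methaneLabels()
  els <- c("C", "H", "H", "H", "H")
  bt <- BondTrajectory(els, list(cbind(1L, 2:5)))
  mols <- moleculesPerFrame(bt)
  expect_identical(mols$partitions[[1]]$labels, unname(lab["CH4"]))
  # no edges: three lone H
  bt2 <- BondTrajectory(c("H", "H", "H"), list(matrix(integer(), ncol = 2)))
  mols2 <- moleculesPerFrame(bt2)
  expect_identical(unname(countsMatrix(mols2$trajectory)[1, "H1"]), 3)
  # two CH3 components and one lone H
  els3 <- c("C", "H", "H", "H", "C", "H", "H", "H", "H")
  edges3 <- rbind(cbind(1L, 2:4), cbind(5L, 6:8))
  mols3 <- moleculesPerFrame(BondTrajectory(els3, list(edges3)))
  X <- countsMatrix(mols3$trajectory)
  expect_identical(unname(X[1, lab[["CH3"]]]), 2)
  expect_identical(unname(X[1, "H1"]), 1)
})

test_that("reaction events come from the bipartite change graph", {
  lab <- methaneLabels()
  els <- c("C", "H", "H", "H", "H")
  f0 <- cbind(1L, 2:5)
  f1 <- cbind(1L, 2:4)
  det <- detectReactionEvents(moleculesPerFrame(
    BondTrajectory(els, list(f0, f1))))
  expect_identical(nrow(det$events), 1L)
  expect_identical(det$events$reaction,
                   paste(lab[["CH4"]], "⇒", lab[["CH3"]], "+ H1"))
  expect_identical(sum(countsMatrix(det$counts)), 1)
  # identical partitions: no events
  det0 <- detectReactionEvents(moleculesPerFrame(
    BondTrajectory(els, list(f0, f0))))
  expect_identical(nrow(det0$events), 0L)
  # two simultaneous independent dissociations in disjoint atom sets
  els2 <- rep(els, 2)
  g0 <- rbind(cbind(1L, 2:5), cbind(6L, 7:10))
  g1 <- rbind(cbind(1L, 2:4), cbind(6L, 7:9))
  det2 <- detectReactionEvents(moleculesPerFrame(
    BondTrajectory(els2, list(g0, g1))))
  expect_identical(nrow(det2$events), 2L)
  expect_identical(as.numeric(countsMatrix(det2$counts)), 2)
  expect_identical(nReactions(det2$network), 1L)
})

test_that("extraction satisfies the bookkeeping invariants", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  g <- generateReactingSystem(toy$network, toy$templates,
                              stats::setNames(12, lab["CH4"]),
                              tEnd = 15, frameDt = 0.01, seed = 7)
  ext <- extractReactions(g$bondTrajectory, tau = 1)
  # counts reproduce concentration changes exactly
  dX <- diff(countsMatrix(ext$trajectory))
  pred <- countsMatrix(ext$counts) %*% t(stoichMatrix(ext$network))
  expect_identical(max(abs(dX - pred[, colnames(dX)])), 0)
  # every event type balances atoms
  expect_identical(sum(validateNetwork(ext$network)$type == "atom-balance"),
                   0L)
  # element totals implied by X(t) are constant across frames
  sp <- speciesList(ext$network)
  labs <- speciesLabels(ext$network)
  nC <- vapply(sp, function(s) sum(s@elementCounts[names(s@elementCounts) == "C"]),
               numeric(1))
  nH <- vapply(sp, function(s) sum(s@elementCounts[names(s@elementCounts) == "H"]),
               numeric(1))
  X <- countsMatrix(ext$trajectory)[, labs, drop = FALSE]
  expect_identical(length(unique(as.numeric(X %*% nC))), 1L)
  expect_identical(length(unique(as.numeric(X %*% nH))), 1L)
})

test_that("detected event totals are non-increasing in tau", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  g <- generateReactingSystem(toy$network, toy$templates,
                              stats::setNames(10, lab["CH4"]),
                              tEnd = 10, frameDt = 0.01, seed = 11)
  totals <- vapply(c(1, 2, 4, 8, 16, 64), function(tau)
    nrow(extractReactions(g$bondTrajectory, tau = tau,
                          estimateRates = FALSE)$events), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("bond-list and XYZ files round-trip through their readers", {
  toy <- methaneToyNetwork()
  lab <- methaneLabels()
  g <- generateReactingSystem(toy$network, toy$templates,
                              stats::setNames(4, lab["CH4"]),
                              tEnd = 2, frameDt = 0.1, seed = 3)
  f <- tempfile(fileext = ".txt")
  writeBondList(g$bondTrajectory, f)
  bt2 <- readBondList(f, frameDt = 0.1)
  expect_identical(bt2@frames, g$bondTrajectory@frames)
  expect_identical(bt2@elements, g$bondTrajectory@elements)
  # coordinate emission -> XYZ file -> cutoffs reproduce the bond graphs
  xyz <- bondFramesToCoordinates(g$bondTrajectory, jitter = 0.02, seed = 5)
  fx <- tempfile(fileext = ".xyz")
  con <- file(fx, "w")
  for (fr in xyz) {
    writeLines(c(as.character(length(g$bondTrajectory@elements)), "frame"),
               con)
    writeLines(sprintf("%s %.6f %.6f %.6f", g$bondTrajectory@elements,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  close(con)
  parsed <- readXYZ(fx)
  expect_identical(parsed$elements, g$bondTrajectory@elements)
  bt3 <- bondStatesFromCoordinates(parsed$frames, parsed$elements,
                                   c("C-C" = 1.98, "C-H" = 1.57,
                                     "H-H" = 1.09), frameDt = 0.1)
  expect_identical(bt3@frames, g$bondTrajectory@frames)
})
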