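# align a trajectory's columns onto a fixed label set (absent species = 0)
alignColumns <- function(traj, labels) {
  X <- countsMatrix(traj)
  out <- matrix(0, nrow = nrow(X), ncol = length(labels),
                dimnames = list(NULL, labels))
  common <- intersect(colnames(X), labels)
  out[, common] <- X[, common]
  out
}

checkAligned <- function(sims, reference) {
  for (s in sims)
    if (length(s@times) != length(reference@times) ||
        max(abs(s@times - reference@times)) > 1e-9 * max(1, max(abs(reference@times))))
      stop("simulated and reference trajectories are on different time grids")
}

#' RMSE between an ensemble mean and a reference trajectory
#'
#' Per species, the root mean square difference over time between the
#' mean of `S` stochastic simulations and the reference concentrations:
#' `sqrt(mean_t (mean_s x_s(t) - x_ref(t))^2)`. Species absent from one
#' side are treated as zero concentration. An optional burn-in drops the
#' initial transient from the comparison.
#'
#' @param sims list of [ConcentrationTrajectory-class] replicates, all on
#'   the reference's time grid.
#' @param reference the reference [ConcentrationTrajectory-class].
#' @param burnIn comparisons start after this time (default 0).
#' @return list with `perSpecies` (named RMSE vector, molecule-count
#'   units), `S` and `method`.
#' @export
rmseVsReference <- function(sims, reference, burnIn = 0) {
  checkAligned(sims, reference)
  labels <- sort(union(colnames(countsMatrix(reference)),
                       unique(unlist(lapply(sims, function(s)
                         colnames(countsMatrix(s)))))),
                 method = "radix")
  keep <- reference@times >= burnIn
  ref <- alignColumns(reference, labels)[keep, , drop = FALSE]
  meanSim <- Reduce(`+`, lapply(sims, alignColumns, labels)) /
    length(sims)
  meanSim <- meanSim[keep, , drop = FALSE]
  rmse <- sqrt(colMeans((meanSim - ref)^2))
  list(perSpecies = rmse, S = length(sims), method = "ensemble-mean-rmse")
}

#' Mean per-replicate error between two stochastic models
#'
#' Per species, the mean over replicates of each replicate's RMSE against
#' the reference model's mean trajectory:
#' `(1/S) sum_s sqrt(mean_t (x_s(t) - xbar_ref(t))^2)`. By convexity this
#' is at least the ensemble-mean RMSE on the same inputs; with `S = 1` it
#' reduces to the plain RMSE of the single replicate.
#'
#' @param sims list of [ConcentrationTrajectory-class] replicates.
#' @param referenceMean the reference model's mean
#'   [ConcentrationTrajectory-class] (e.g. the mean of its own ensemble).
#' @param burnIn comparisons start after this time (default 0).
#' @return list with `perSpecies`, `S` and `method`.
#' @export
meanErrorBetweenModels <- function(sims, referenceMean, burnIn = 0) {
  checkAligned(sims, referenceMean)
  labels <- sort(union(colnames(countsMatrix(referenceMean)),
                       unique(unlist(lapply(sims, function(s)
                         colnames(countsMatrix(s)))))),
                 method = "radix")
  keep <- referenceMean@times >= burnIn
  ref <- alignColumns(referenceMean, labels)[keep, , drop = FALSE]
  perRep <- lapply(sims, function(s)
    sqrt(colMeans((alignColumns(s, labels)[keep, , drop = FALSE] - ref)^2)))
  err <- Reduce(`+`, perRep) / length(sims)
  list(perSpecies = err, S = length(sims),
       method = "mean-per-replicate-rmse")
}

#' Mean trajectory of an ensemble
#'
#' @param sims list of [ConcentrationTrajectory-class] replicates on a
#'   common grid.
#' @return list with `times` and the real-valued `mean` count matrix
#'   (species aligned over the union of labels).
#' @keywords internal
ensembleMean <- function(sims) {
  labels <- sort(unique(unlist(lapply(sims, function(s)
    colnames(countsMatrix(s))))), method = "radix")
  M <- Reduce(`+`, lapply(sims, alignColumns, labels)) / length(sims)
  list(times = sims[[1]]@times, mean = M)
}

#' Bond-duration model selection
#'
#' For each candidate bond-duration criterion tau, extracts a network and
#' maximum-likelihood rates from the trajectory, runs `S` Gillespie
#' replicates from the initial state, and scores the ensemble mean with
#' the RMSE metric against a single fixed reference: the source
#' concentrations projected at `referenceTau` (default 1, the raw
#' molecule counts). Scoring every candidate against the same reference
#' exposes both failure modes — small tau overfits vibrational flicker as
#' spurious reactions, while large tau suppresses genuine chemistry until,
#' in the limit, nothing reacts at all. The tau minimizing the mean RMSE
#' over the designated species is selected (ties towards smaller tau, the
#' less-smoothed model). A tau whose extraction fails outright scores an
#' infinite error; a tau that yields an event-free network is scored as
#' the frozen (constant) model.
#'
#' @param bondTraj a raw [BondTrajectory-class].
#' @param tauGrid integer vector of at least two candidate taus.
#' @param S replicates per tau (default 20).
#' @param seed base seed for the ensembles.
#' @param species labels to score (default: every species of the
#'   reference; the field's practice is the few highest-concentration
#'   stable molecules).
#' @param burnIn comparison start time (default 0).
#' @param referenceTau smoothing applied to the source trajectory that
#'   defines the reference concentrations (default 1 = raw).
#' @return list with `tauStar`, `curve` (data.frame: tau, error, events,
#'   reactions) and `details` (per-tau error reports).
#' @export
selectBondDuration <- function(bondTraj, tauGrid, S = 20, seed = 1,
                               species = NULL, burnIn = 0,
                               referenceTau = 1) {
  if (length(tauGrid) < 2L) stop("tauGrid must contain at least two values")
  tauGrid <- as.integer(tauGrid)
  reference <- moleculesPerFrame(
    applyBondDuration(bondTraj, referenceTau))$trajectory
  errs <- numeric(length(tauGrid))
  nEvents <- numeric(length(tauGrid))
  nRx <- numeric(length(tauGrid))
  details <- vector("list", length(tauGrid))
  for (q in seq_along(tauGrid)) {
    tau <- tauGrid[q]
    ext <- tryCatch(extractReactions(bondTraj, tau = tau),
                    error = function(e) NULL)
    if (is.null(ext)) {
      errs[q] <- Inf
      nEvents[q] <- NA_real_; nRx[q] <- NA_real_
      next
    }
    nEvents[q] <- nrow(ext$events)
    nRx[q] <- nReactions(ext$network)
    x0 <- countsMatrix(ext$trajectory)[1L, ]
    sims <- if (nReactions(ext$network) == 0L) {
      # frozen model: constant state
      list(ConcentrationTrajectory(reference@times,
             matrix(rep(x0, each = length(reference@times)),
                    nrow = length(reference@times),
                    dimnames = list(NULL, names(x0)))))
    } else {
      simulateEnsemble(ext$network, x0, reference@times, S, seed = seed)
    }
    rep_ <- rmseVsReference(sims, reference, burnIn = burnIn)
    sel <- if (is.null(species)) names(rep_$perSpecies)
           else intersect(species, names(rep_$perSpecies))
    errs[q] <- mean(rep_$perSpecies[sel])
    details[[q]] <- rep_
  }
  ord <- order(errs, tauGrid)
  list(tauStar = tauGrid[ord[1L]],
       curve = data.frame(tau = tauGrid, error = errs, events = nEvents,
                          reactions = nRx),
       details = details)
}

#' Reaction-support overlap across models
#'
#' Reaction identity is the canonical reactant-to-product equation. The
#' common fraction is the share of the union of all reactions that is
#' present in every network; the pairwise Jaccard matrix gives
#' intersection-over-union for each network pair.
#'
#' @param networks list of at least two [ReactionNetwork-class] objects.
#' @return list with `commonFraction`, `jaccard` (matrix), `union` and
#'   `common` (character vectors of reaction equations).
#' @export
compareSupports <- function(networks) {
  if (length(networks) < 2L) stop("at least two networks are required")
  sets <- lapply(networks, reactionLabels)
  un <- Reduce(union, sets)
  com <- Reduce(intersect, sets)
  n <- length(networks)
  J <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- length(union(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- if (u == 0L) 1 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  list(commonFraction = if (length(un) == 0L) 1 else length(com) / length(un),
       jaccard = J, union = un, common = com)
}

#' Write an error report as CSV
#'
#' @param report an error report from [rmseVsReference()] or
#'   [meanErrorBetweenModels()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeErrorReportCSV <- function(report, path) {
  df <- data.frame(species = names(report$perSpecies),
                   error = unname(report$perSpecies),
                   S = report$S, method = report$method,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
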