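#' Exact Gillespie simulation of a reaction network
#'
#' Direct-method stochastic simulation of the chemical master equation:
#' waiting times are exponential in the total propensity and the firing
#' reaction is chosen with probability proportional to its propensity
#' `a_j(x) = k_j h_j(x)`. Only reactions in the network can ever fire, and
#' species counts can never go negative because `h_j` vanishes whenever a
#' reactant is insufficient. When the total propensity reaches zero the
#' system is frozen: the trajectory silently extends to `tEnd` and the
#' condition is flagged on the returned object.
#'
#' @param network a [ReactionNetwork-class] with rates set.
#' @param x0 named non-negative integer initial counts (names are species
#'   labels; missing species start at 0).
#' @param tEnd simulation horizon (> 0).
#' @param seed optional integer seed; identical seed gives an identical
#'   trajectory.
#' @param maxEvents safety cap on the number of events.
#' @return an [EventTrajectory-class].
#' @export
simulateSSA <- function(network, x0, tEnd, seed = NULL, maxEvents = 5e7) {
  if (tEnd <= 0) stop("tEnd must be positive")
  labs <- speciesLabels(network)
  x <- stats::setNames(rep(0, length(labs)), labs)
  if (is.null(names(x0)) && length(x0) == length(labs)) names(x0) <- labs
  unknown <- setdiff(names(x0), labs)
  if (length(unknown))
    stop("x0 names not in network: ", paste(unknown, collapse = ", "))
  x[names(x0)] <- x0
  if (any(x < 0) || any(x != round(x)))
    stop("x0 must be non-negative integers")
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_core(unname(x), tEnd, stoichMatrix(network),
                  reactantMatrix(network), rates(network), maxEvents)
  if (isTRUE(res$truncated))
    warning("simulation truncated at ", maxEvents, " events before tEnd")
  new("EventTrajectory", x0 = stats::setNames(as.integer(x), labs),
      eventTimes = as.numeric(res$times),
      eventReactions = as.integer(res$reactions),
      tEnd = as.numeric(tEnd), frozen = isTRUE(res$frozen))
}

#' Sample an event trajectory at fixed times
#'
#' Evaluates the piecewise-constant (right-continuous) state of a
#' Gillespie realization at each requested time: at an event time the
#' post-event state is reported.
#'
#' @param eventTraj an [EventTrajectory-class].
#' @param times sample times within `[0, tEnd]`.
#' @param network the [ReactionNetwork-class] that produced the
#'   trajectory (supplies the stoichiometry matrix).
#' @return a [ConcentrationTrajectory-class].
#' @export
sampleTrajectory <- function(eventTraj, times, network) {
  if (length(times) && (min(times) < 0 || max(times) > eventTraj@tEnd))
    stop("sample times must lie within [0, tEnd]")
  R <- stoichMatrix(network)
  x0 <- rep(0, nrow(R))
  names(x0) <- rownames(R)
  x0[names(eventTraj@x0)] <- eventTraj@x0
  nEv <- length(eventTraj@eventTimes)
  if (nEv == 0L) {
    X <- matrix(rep(x0, each = length(times)), nrow = length(times),
                dimnames = list(NULL, rownames(R)))
    return(ConcentrationTrajectory(times, X))
  }
  deltas <- t(R[, eventTraj@eventReactions, drop = FALSE])
  states <- apply(deltas, 2L, cumsum)
  if (nEv == 1L) states <- matrix(states, nrow = 1L)
  states <- sweep(states, 2L, x0, `+`)
  idx <- findInterval(times, eventTraj@eventTimes)
  X <- rbind(x0, states)[idx + 1L, , drop = FALSE]
  dimnames(X) <- list(NULL, rownames(R))
  ConcentrationTrajectory(times, X)
}

#' Bin SSA events into tau-leaping observation counts
#'
#' Counts the firings of each reaction in consecutive half-open windows
#' `[t dt, (t+1) dt)`; an event exactly on a boundary belongs to the later
#' window. The total of all counts equals the number of events.
#'
#' @param eventTraj an [EventTrajectory-class].
#' @param dt bin width (> 0).
#' @param nReactions number of reactions (columns); defaults to the
#'   largest fired index.
#' @return a [ReactionCountSeries-class].
#' @export
binEventCounts <- function(eventTraj, dt, nReactions = NULL) {
  if (dt <= 0) stop("dt must be positive")
  ev <- eventTraj@eventTimes
  rx <- eventTraj@eventReactions
  if (is.null(nReactions))
    nReactions <- if (length(rx)) max(rx) else 0L
  nBins <- max(floor(eventTraj@tEnd / dt + 1e-12), 1L)
  bins <- floor(ev / dt) + 1L
  nBins <- max(nBins, if (length(bins)) max(bins) else 0L)
  counts <- matrix(0, nrow = nBins, ncol = nReactions)
  for (e in seq_along(ev)) counts[bins[e], rx[e]] <- counts[bins[e], rx[e]] + 1
  ReactionCountSeries(counts)
}

#' Ensemble of Gillespie simulations sampled on a fixed grid
#'
#' Runs `S` independent realizations (seeded `seed`, `seed + 1`, ...) and
#' samples each on the same time grid.
#'
#' @param network a [ReactionNetwork-class] with rates set.
#' @param x0 named initial counts.
#' @param times sample time grid (the horizon is `max(times)`).
#' @param S number of replicates.
#' @param seed base seed; replicate s uses `seed + s - 1`.
#' @return list of S [ConcentrationTrajectory-class] objects.
#' @export
simulateEnsemble <- function(network, x0, times, S, seed = 1) {
  tEnd <- max(times)
  lapply(seq_len(S), function(s) {
    ev <- simulateSSA(network, x0, tEnd, seed = seed + s - 1)
    sampleTrajectory(ev, times, network)
  })
}

#' @describeIn EventTrajectory-class compact summary
#' @param object an EventTrajectory
#' @export
setMethod("show", "EventTrajectory", function(object) {
  cat("EventTrajectory:", length(object@eventTimes), "events in [0,",
      object@tEnd, "]", if (object@frozen) "(frozen before tEnd)" else "",
      "\n")
  invisible(object)
})
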