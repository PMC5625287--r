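#' Bond-duration hysteresis filter
#'
#' Two-state smoothing of a raw boolean bonded/unbonded signal: the state
#' flips only after the raw signal has held the opposite value for
#' `tau` consecutive frames, and the flip is stamped retroactively at the
#' first frame of that persistent run (the physical event time). Runs of
#' the opposite value shorter than `tau` — vibrational flicker — never
#' register. `tau = 1` returns the raw series unchanged.
#'
#' @param raw logical (or 0/1) vector of per-frame raw bond states.
#' @param tau bond duration criterion in frames (integer >= 1).
#' @param initial state before the first frame; by default the frame-0
#'   raw state is accepted as the initial smoothed state, since no
#'   tau-frame history exists before the trajectory.
#' @return logical vector of smoothed states, same length as `raw`.
#' @examples
#' hysteresisFilter(c(0, 1, 1, 1, 0, 0, 0, 1), tau = 3, initial = FALSE)
#' @export
hysteresisFilter <- function(raw, tau, initial = raw[1]) {
  if (length(tau) != 1L || is.na(tau) || tau < 1 || tau != round(tau))
    stop("tau must be a single integer >= 1")
  raw <- as.logical(raw)
  n <- length(raw)
  if (n == 0L) return(logical(0))
  state <- as.logical(initial)
  out <- logical(n)
  runs <- rle(raw)
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    val <- runs$values[i]
    if (val != state && len >= tau) state <- val
    out[pos:(pos + len - 1L)] <- state
    pos <- pos + len
  }
  out
}

# canonical integer key for an edge (i < j), used to track bonds over time
edgeKeys <- function(edges, nAtoms) {
  (pmin(edges[, 1L], edges[, 2L]) - 1L) * nAtoms +
    pmax(edges[, 1L], edges[, 2L])
}

#' Smooth a bond trajectory with the bond-duration criterion
#'
#' Applies [hysteresisFilter()] independently to the boolean time series
#' of every atom pair that is ever bonded in the raw trajectory.
#'
#' @param bondTraj a raw [BondTrajectory-class].
#' @param tau bond duration criterion in frames.
#' @return a smoothed [BondTrajectory-class].
#' @export
applyBondDuration <- function(bondTraj, tau) {
  if (tau == 1) return(bondTraj)
  n <- bondTraj@nAtoms
  nf <- length(bondTraj@frames)
  keys <- sort(unique(unlist(lapply(bondTraj@frames, function(f)
    if (nrow(f)) edgeKeys(f, n) else integer()))))
  if (length(keys) == 0L) return(bondTraj)
  sig <- matrix(FALSE, nrow = length(keys), ncol = nf)
  for (f in seq_len(nf)) {
    e <- bondTraj@frames[[f]]
    if (nrow(e)) sig[match(edgeKeys(e, n), keys), f] <- TRUE
  }
  for (p in seq_len(nrow(sig)))
    sig[p, ] <- hysteresisFilter(sig[p, ], tau)
  iAtom <- as.integer((keys - 1L) %/% n + 1L)
  jAtom <- as.integer((keys - 1L) %% n + 1L)
  frames <- vector("list", nf)
  prevMask <- NULL
  for (f in seq_len(nf)) {
    mask <- sig[, f]
    if (!is.null(prevMask) && identical(mask, prevMask)) {
      frames[[f]] <- frames[[f - 1L]]
    } else {
      frames[[f]] <- cbind(iAtom[mask], jAtom[mask])
    }
    prevMask <- mask
  }
  BondTrajectory(bondTraj@elements, frames, frameDt = bondTraj@frameDt)
}

#' Raw bond states from a coordinate trajectory
#'
#' Two atoms are bonded in a frame iff their distance is at or below the
#' cutoff for their element pair (boundary inclusive). With a periodic
#' box, minimum-image distances are used.
#'
#' @param frames list of n x 3 coordinate matrices (one per frame), e.g.
#'   from [readXYZ()].
#' @param elements per-atom element symbols.
#' @param cutoffs named vector or list of bond-length cutoffs keyed by
#'   canonical element-pair key (`"C-C"`, `"C-H"`, `"H-H"`, see
#'   [bondPairKey()]); every element pair occurring among the atoms must
#'   have a cutoff.
#' @param box optional length-3 periodic box edge lengths.
#' @param frameDt time between frames.
#' @return a raw (unsmoothed) [BondTrajectory-class].
#' @export
bondStatesFromCoordinates <- function(frames, elements, cutoffs,
                                      box = NULL, frameDt = 1) {
  n <- length(elements)
  cutoffs <- unlist(cutoffs)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) < 3L)
      stop("inconsistent atom counts across frames")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  iIdx <- idx[, 1L]; jIdx <- idx[, 2L]
  pairKey <- bondPairKey(elements[iIdx], elements[jIdx])
  need <- unique(pairKey)
  missing <- setdiff(need, names(cutoffs))
  if (length(missing))
    stop("missing bond-length cutoff for element pair(s): ",
         paste(missing, collapse = ", "))
  cut <- unname(cutoffs[pairKey])
  edgeFrames <- lapply(frames, function(xyz) {
    d <- xyz[iIdx, , drop = FALSE] - xyz[jIdx, , drop = FALSE]
    if (!is.null(box))
      d <- d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
    bonded <- rowSums(d * d) <= cut * cut
    cbind(iIdx[bonded], jIdx[bonded])
  })
  BondTrajectory(elements, edgeFrames, frameDt = frameDt)
}

# connected components + species of one bond-graph frame
frameMolecules <- function(edges, elements, nAtoms) {
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nAtoms - igraph::vcount(g)))
    membership <- igraph::components(g)$membership
  } else {
    membership <- seq_len(nAtoms)
  }
  atomSets <- split(seq_len(nAtoms), membership)
  labels <- character(length(atomSets))
  speciesObjs <- vector("list", length(atomSets))
  if (nrow(edges)) {
    comp <- membership[edges[, 1L]]
    pk <- bondPairKey(elements[edges[, 1L]], elements[edges[, 2L]])
  }
  for (ci in seq_along(atomSets)) {
    atoms <- atomSets[[ci]]
    ec <- table(elements[atoms])
    bc <- if (nrow(edges)) table(pk[comp == ci]) else integer()
    sp <- Species(stats::setNames(as.integer(ec), names(ec)),
                  stats::setNames(as.integer(bc), names(bc)))
    labels[ci] <- sp@label
    speciesObjs[[ci]] <- sp
  }
  list(membership = membership, atomSets = atomSets, labels = labels,
       species = speciesObjs)
}

#' Molecules and species per frame of a (smoothed) bond trajectory
#'
#' Molecules are the connected components of each frame's bond graph;
#' each component maps to a [Species-class] via its element and bond-type
#' counts. Consecutive identical frames share the computed partition.
#'
#' @param bondTraj a [BondTrajectory-class] (smooth it first with
#'   [applyBondDuration()] if a bond-duration criterion is wanted).
#' @return list with `partitions` (one record per frame: `membership`,
#'   `atomSets`, `labels`), `trajectory` (the
#'   [ConcentrationTrajectory-class] X(t)) and `speciesRegistry`
#'   (label -> [Species-class] lookup for every species observed).
#' @export
moleculesPerFrame <- function(bondTraj) {
  nf <- length(bondTraj@frames)
  partitions <- vector("list", nf)
  registry <- new.env(parent = emptyenv())
  prev <- NULL
  for (f in seq_len(nf)) {
    e <- bondTraj@frames[[f]]
    if (!is.null(prev) && identical(e, bondTraj@frames[[f - 1L]])) {
      partitions[[f]] <- prev
    } else {
      prev <- frameMolecules(e, bondTraj@elements, bondTraj@nAtoms)
      for (ci in seq_along(prev$labels))
        if (is.null(registry[[prev$labels[ci]]]))
          assign(prev$labels[ci], prev$species[[ci]], envir = registry)
      prev$species <- NULL
      partitions[[f]] <- prev
    }
  }
  allLabs <- sort(ls(registry), method = "radix")
  X <- matrix(0, nrow = nf, ncol = length(allLabs),
              dimnames = list(NULL, allLabs))
  lastRow <- NULL
  for (f in seq_len(nf)) {
    if (f > 1L && identical(partitions[[f]], partitions[[f - 1L]])) {
      X[f, ] <- lastRow
    } else {
      tb <- table(partitions[[f]]$labels)
      row <- stats::setNames(rep(0, length(allLabs)), allLabs)
      row[names(tb)] <- as.numeric(tb)
      X[f, ] <- row
      lastRow <- X[f, ]
    }
  }
  traj <- ConcentrationTrajectory((seq_len(nf) - 1L) * bondTraj@frameDt, X)
  list(partitions = partitions, trajectory = traj,
       speciesRegistry = as.list(registry))
}

#' Detect reaction events between consecutive frames
#'
#' For each interval, molecules whose atom set and species label are both
#' unchanged are ignored. The remaining molecules that disappeared from
#' frame t and appeared in frame t+1 are linked when they share atoms;
#' every connected component of this bipartite link graph is one reaction
#' event, with the frame-t molecules as reactants and the frame-(t+1)
#' molecules as products. Distinct reaction types (reactant multiset to
#' product multiset) become the reactions of a skeleton network, and the
#' per-interval firing counts of each type form a
#' [ReactionCountSeries-class].
#'
#' @param mols result of [moleculesPerFrame()].
#' @param frameDt time between frames (defaults to the trajectory's
#'   spacing recorded in `mols`).
#' @return list with `events` (data.frame: `interval` 1-based, `reaction`
#'   equation string, `atoms` atom-index list column), `counts`
#'   ([ReactionCountSeries-class] T x r), `network` (skeleton
#'   [ReactionNetwork-class]: rates zero, observed totals filled) and
#'   `trajectory` (passed through from `mols`).
#' @export
detectReactionEvents <- function(mols, frameDt = NULL) {
  partitions <- mols$partitions
  traj <- mols$trajectory
  if (is.null(frameDt))
    frameDt <- if (length(traj@times) > 1L) diff(traj@times)[1] else 1
  nf <- length(partitions)
  nT <- max(nf - 1L, 0L)
  typeKeys <- character()
  typeReactants <- list(); typeProducts <- list()
  countRows <- list()  # per type: integer vector of intervals (may repeat)
  evInterval <- integer(); evType <- integer(); evAtoms <- list()
  for (t in seq_len(nT)) {
    p0 <- partitions[[t]]; p1 <- partitions[[t + 1L]]
    if (identical(p0, p1)) next
    key0 <- vapply(p0$atomSets, paste, character(1), collapse = ",")
    key1 <- vapply(p1$atomSets, paste, character(1), collapse = ",")
    id0 <- paste(key0, p0$labels); id1 <- paste(key1, p1$labels)
    changed0 <- which(!(id0 %in% id1))
    changed1 <- which(!(id1 %in% id0))
    if (!length(changed0) && !length(changed1)) next
    # group changed molecules by shared atoms (union-find over atom ids)
    atoms0 <- p0$atomSets[changed0]; atoms1 <- p1$atomSets[changed1]
    allAtoms <- sort(unique(c(unlist(atoms0), unlist(atoms1))))
    parent <- seq_along(allAtoms)
    findRoot <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
      x
    }
    unionSets <- function(a, b) {
      ra <- findRoot(a); rb <- findRoot(b)
      if (ra != rb) parent[ra] <<- rb
    }
    for (as_ in c(atoms0, atoms1)) {
      ix <- match(as_, allAtoms)
      for (q in seq_along(ix)[-1]) unionSets(ix[1], ix[q])
    }
    root0 <- vapply(atoms0, function(a) findRoot(match(a[1], allAtoms)),
                    integer(1))
    root1 <- vapply(atoms1, function(a) findRoot(match(a[1], allAtoms)),
                    integer(1))
    for (gr in unique(c(root0, root1))) {
      rIdx <- changed0[root0 == gr]; pIdx <- changed1[root1 == gr]
      if (!length(rIdx) || !length(pIdx))
        stop("internal consistency error: one-sided reaction event at ",
             "interval ", t)
      reac <- asMultiset(p0$labels[rIdx])
      prod <- asMultiset(p1$labels[pIdx])
      rx <- Reaction(reac, prod)
      keyRx <- reactionEquation(rx)
      ti <- match(keyRx, typeKeys)
      if (is.na(ti)) {
        typeKeys <- c(typeKeys, keyRx)
        ti <- length(typeKeys)
        typeReactants[[ti]] <- reac; typeProducts[[ti]] <- prod
        countRows[[ti]] <- integer()
      }
      countRows[[ti]] <- c(countRows[[ti]], t)
      evInterval <- c(evInterval, t); evType <- c(evType, ti)
      evAtoms <- c(evAtoms, list(sort(unique(c(unlist(p0$atomSets[rIdx]),
                                               unlist(p1$atomSets[pIdx]))))))
    }
  }
  r <- length(typeKeys)
  counts <- matrix(0, nrow = nT, ncol = r)
  for (ti in seq_len(r)) {
    tb <- table(countRows[[ti]])
    counts[as.integer(names(tb)), ti] <- as.numeric(tb)
  }
  registry <- mols$speciesRegistry
  speciesObjs <- registry[sort(names(registry), method = "radix")]
  reactions <- vector("list", r)
  for (ti in seq_len(r))
    reactions[[ti]] <- Reaction(typeReactants[[ti]], typeProducts[[ti]],
                                rateK = 0,
                                observedCountTotal = sum(counts[, ti]))
  network <- ReactionNetwork(unname(speciesObjs), reactions, dt = frameDt)
  bal <- validateNetwork(network)
  if (any(bal$type == "atom-balance"))
    stop("internal consistency error: unbalanced extracted event: ",
         paste(bal$message[bal$type == "atom-balance"], collapse = "; "))
  events <- data.frame(interval = evInterval,
                       reaction = typeKeys[evType],
                       stringsAsFactors = FALSE)
  events$atoms <- evAtoms
  list(events = events, counts = ReactionCountSeries(counts),
       network = network, trajectory = traj)
}

#' Extract a reaction network from a bond trajectory
#'
#' Convenience wrapper for the full extraction stage: smooth bonds with
#' the duration criterion, partition each frame into molecules, detect
#' reaction events, and estimate rate coefficients by maximum likelihood.
#'
#' @param bondTraj a raw [BondTrajectory-class].
#' @param tau bond duration criterion in frames (default 1 = no
#'   smoothing).
#' @param estimateRates if TRUE (default) fill in maximum-likelihood rate
#'   coefficients via [estimateRates()].
#' @return list with `network` ([ReactionNetwork-class] with rates),
#'   `counts`, `trajectory`, `events` and `informative` (informative
#'   interval counts per reaction; NULL when rates are not estimated).
#' @export
extractReactions <- function(bondTraj, tau = 1, estimateRates = TRUE) {
  sm <- applyBondDuration(bondTraj, tau)
  mols <- moleculesPerFrame(sm)
  det <- detectReactionEvents(mols, frameDt = bondTraj@frameDt)
  informative <- NULL
  if (estimateRates && nReactions(det$network) > 0L) {
    est <- estimateRates(det$counts, det$trajectory, det$network)
    rates(det$network) <- est$k
    for (j in seq_along(det$network@reactions))
      det$network@reactions[[j]]@observedCountTotal <- est$totalCounts[j]
    informative <- est$informative
  }
  list(network = det$network, counts = det$counts,
       trajectory = det$trajectory, events = det$events,
       informative = informative)
}

#' Write the extracted event log as CSV
#'
#' @param events the `events` data.frame from [detectReactionEvents()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEventsCSV <- function(events, path) {
  df <- data.frame(interval = events$interval, reaction = events$reaction,
                   atoms = vapply(events$atoms, paste, character(1),
                                  collapse = " "),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
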