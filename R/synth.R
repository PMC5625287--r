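#' Toy methane-fragment chemistry
#'
#' A small ground-truth network over the species set
#' {CH4, CH3, H, H2, C2H6} with six reactions (three reversible pairs):
#' CH4 dissociation/recombination, H2 formation/dissociation and ethane
#' formation/dissociation. The default rates are chosen so that, from a
#' few tens of CH4 molecules, all six reactions fire repeatedly over a
#' horizon of ~100 time units while the system relaxes towards a mixture
#' of fragments — a desk-scale stand-in for a reactive high-temperature
#' hydrocarbon system.
#'
#' @param rates length-6 rate vector (order: CH4 -> CH3 + H,
#'   CH3 + H -> CH4, H + H -> H2, H2 -> H + H, CH3 + CH3 -> C2H6,
#'   C2H6 -> CH3 + CH3).
#' @param dt sampling interval attached to the network.
#' @return list with `network` ([ReactionNetwork-class]) and `templates`
#'   (per-species atom templates for [generateReactingSystem()]: each a
#'   list with `elements` and `bonds`).
#' @export
methaneToyNetwork <- function(rates = c(0.3, 2.0, 1.0, 0.4, 0.5, 0.3),
                              dt = 0.01) {
  stopifnot(length(rates) == 6L)
  spCH4 <- Species(c(C = 1, H = 4), c("C-H" = 4))
  spCH3 <- Species(c(C = 1, H = 3), c("C-H" = 3))
  spH <- Species(c(H = 1))
  spH2 <- Species(c(H = 2), c("H-H" = 1))
  spC2H6 <- Species(c(C = 2, H = 6), c("C-C" = 1, "C-H" = 6))
  lab <- function(s) s@label
  rx <- list(
    Reaction(c(lab(spCH4)), c(lab(spCH3), lab(spH)), rateK = rates[1]),
    Reaction(c(lab(spCH3), lab(spH)), c(lab(spCH4)), rateK = rates[2]),
    Reaction(c(lab(spH), lab(spH)), c(lab(spH2)), rateK = rates[3]),
    Reaction(c(lab(spH2)), c(lab(spH), lab(spH)), rateK = rates[4]),
    Reaction(c(lab(spCH3), lab(spCH3)), c(lab(spC2H6)), rateK = rates[5]),
    Reaction(c(lab(spC2H6)), c(lab(spCH3), lab(spCH3)), rateK = rates[6]))
  nw <- ReactionNetwork(list(spCH4, spCH3, spH, spH2, spC2H6), rx, dt = dt)
  templates <- stats::setNames(list(
    list(elements = c("C", "H", "H", "H", "H"),
         bonds = cbind(1L, 2:5)),
    list(elements = c("C", "H", "H", "H"),
         bonds = cbind(1L, 2:4)),
    list(elements = "H", bonds = matrix(integer(), ncol = 2)),
    list(elements = c("H", "H"), bonds = cbind(1L, 2L)),
    list(elements = c("C", "C", "H", "H", "H", "H", "H", "H"),
         bonds = rbind(c(1L, 2L), cbind(1L, 3:5), cbind(2L, 6:8)))),
    c(lab(spCH4), lab(spCH3), lab(spH), lab(spH2), lab(spC2H6)))
  list(network = nw, templates = templates)
}

#' Generate a noisy boolean bond signal with known clean truth
#'
#' The clean series is a step function given by the true transitions; the
#' raw series XORs in short spurious runs ("flicker", emulating atomic
#' vibrations that momentarily cross the bond-length threshold). Flickers
#' are placed by a Poisson process and each has length strictly less than
#' `flickerMaxLen`; placements that would touch another flicker or come
#' within `flickerMaxLen` frames of a true transition (or the series
#' ends) are rejected, so the clean signal is exactly recoverable by
#' [hysteresisFilter()] with `tau = flickerMaxLen`.
#'
#' @param nFrames series length.
#' @param trueTransitions data.frame or 2-column matrix of
#'   (frame, newState) pairs (1-based frame at which the clean state
#'   changes); transitions closer than `flickerMaxLen` frames are a
#'   generator error.
#' @param flickerRate expected flickers per frame (Poisson placement).
#' @param flickerMaxLen flickers are strictly shorter than this (>= 1;
#'   `flickerMaxLen = 1` disables flicker).
#' @param seed RNG seed.
#' @param initial clean state before the first transition.
#' @return list with `raw` and `clean` logical vectors.
#' @export
generateBondSignal <- function(nFrames, trueTransitions = NULL,
                               flickerRate = 0, flickerMaxLen = 1,
                               seed = 1, initial = FALSE) {
  if (flickerMaxLen < 1) stop("flickerMaxLen must be >= 1")
  set.seed(seed)
  tr <- if (is.null(trueTransitions) || NROW(trueTransitions) == 0L)
    matrix(numeric(), ncol = 2) else as.matrix(trueTransitions)
  if (nrow(tr) > 1L && any(diff(tr[, 1L]) < flickerMaxLen))
    stop("true transitions closer than flickerMaxLen frames")
  clean <- rep(as.logical(initial), nFrames)
  if (nrow(tr))
    for (q in seq_len(nrow(tr)))
      if (tr[q, 1L] <= nFrames)
        clean[tr[q, 1L]:nFrames] <- as.logical(tr[q, 2L])
  raw <- clean
  if (flickerRate > 0 && flickerMaxLen > 1) {
    nFlick <- stats::rpois(1L, flickerRate * nFrames)
    starts <- sort(sample.int(nFrames, min(nFlick, nFrames)))
    lens <- sample.int(flickerMaxLen - 1L, length(starts), replace = TRUE)
    blocked <- rep(FALSE, nFrames)
    # exclusion zone around every true transition and the series ends
    guard <- function(f) max(1L, f - flickerMaxLen):min(nFrames, f + flickerMaxLen)
    if (nrow(tr)) for (q in seq_len(nrow(tr))) blocked[guard(tr[q, 1L])] <- TRUE
    blocked[seq_len(min(flickerMaxLen, nFrames))] <- TRUE
    blocked[max(1L, nFrames - flickerMaxLen + 1L):nFrames] <- TRUE
    for (q in seq_along(starts)) {
      span <- starts[q]:min(nFrames, starts[q] + lens[q] - 1L)
      spanPad <- max(1L, starts[q] - 1L):min(nFrames, starts[q] + lens[q])
      if (any(blocked[spanPad])) next
      raw[span] <- !raw[span]
      blocked[spanPad] <- TRUE
    }
  }
  list(raw = raw, clean = clean)
}

# instantiate a molecule from a species template with fresh atom ids
newMolecule <- function(template, nextAtomId) {
  nA <- length(template$elements)
  atoms <- nextAtomId:(nextAtomId + nA - 1L)
  bonds <- template$bonds
  if (nrow(bonds)) bonds <- cbind(atoms[bonds[, 1L]], atoms[bonds[, 2L]])
  list(atoms = atoms, bonds = bonds)
}

#' Generate an atom-resolved reacting bond trajectory from a known network
#'
#' Runs a Gillespie simulation of the template network while maintaining
#' explicit atoms: every molecule is an instantiated copy of its species'
#' atom template, and each reaction firing consumes the chosen reactant
#' molecules, pools their atoms by element, and rewires them into fresh
#' product template instances. Per-frame bond graphs are emitted on a
#' fixed grid. Element totals are conserved across frames (closed
#' system), and event detection on the output at `tau = 1` recovers
#' exactly the fired reaction types whenever no two firings share atoms
#' within the same frame interval — firings that do overlap are detected
#' as their composite, just as they would be in real data sampled at
#' finite resolution, so choose `frameDt` small relative to the firing
#' rate when exact recovery matters.
#'
#' @param templateNetwork a [ReactionNetwork-class] ground truth with
#'   rates set.
#' @param atomTemplates named list (species label -> list(elements,
#'   bonds)) as from [methaneToyNetwork()].
#' @param x0 named initial molecule counts.
#' @param tEnd simulated horizon.
#' @param frameDt frame spacing of the emitted bond trajectory.
#' @param seed RNG seed.
#' @return list with `bondTrajectory` ([BondTrajectory-class]), `truth`
#'   (list: `network`, `events` data.frame of fired (time, reaction),
#'   `seed`, `x0`, `frameDt`) — the generator's ground truth.
#' @export
generateReactingSystem <- function(templateNetwork, atomTemplates, x0,
                                   tEnd, frameDt, seed = 1) {
  labs <- speciesLabels(templateNetwork)
  missing <- setdiff(labs, names(atomTemplates))
  if (length(missing))
    stop("missing atom template for species: ",
         paste(missing, collapse = ", "))
  for (lab in labs) {
    tpl <- atomTemplates[[lab]]
    ec <- table(tpl$elements)
    bc <- if (nrow(tpl$bonds))
      table(bondPairKey(tpl$elements[tpl$bonds[, 1L]],
                        tpl$elements[tpl$bonds[, 2L]])) else integer()
    tplLab <- canonicalLabel(stats::setNames(as.integer(ec), names(ec)),
                             stats::setNames(as.integer(bc), names(bc)))
    if (tplLab != lab)
      stop("atom template for '", lab, "' renders as '", tplLab, "'")
  }
  set.seed(seed)
  ev <- simulateSSA(templateNetwork, x0, tEnd)
  # instantiate initial molecules
  molecules <- list()
  bySpecies <- stats::setNames(vector("list", length(labs)), labs)
  elements <- character()
  nextAtom <- 1L
  fullX0 <- stats::setNames(rep(0, length(labs)), labs)
  fullX0[names(x0)] <- x0
  for (lab in labs) {
    for (q in seq_len(fullX0[[lab]])) {
      tpl <- atomTemplates[[lab]]
      mol <- newMolecule(tpl, nextAtom)
      elements <- c(elements, tpl$elements)
      nextAtom <- nextAtom + length(tpl$elements)
      molecules[[length(molecules) + 1L]] <- mol
      bySpecies[[lab]] <- c(bySpecies[[lab]], length(molecules))
    }
  }
  nAtoms <- nextAtom - 1L
  rxList <- reactionList(templateNetwork)
  snapshot <- function() {
    eb <- do.call(rbind, lapply(molecules[aliveIds], function(m) m$bonds))
    if (is.null(eb)) eb <- matrix(integer(), ncol = 2)
    eb
  }
  aliveIds <- seq_along(molecules)
  times <- seq(0, tEnd, by = frameDt)
  frames <- vector("list", length(times))
  curFrame <- snapshot()
  fIdx <- 1L
  evTimes <- ev@eventTimes
  evRx <- ev@eventReactions
  for (e in seq_len(length(evTimes) + 1L)) {
    tNext <- if (e <= length(evTimes)) evTimes[e] else Inf
    while (fIdx <= length(times) && times[fIdx] < tNext) {
      frames[[fIdx]] <- curFrame
      fIdx <- fIdx + 1L
    }
    if (e > length(evTimes)) break
    rx <- rxList[[evRx[e]]]
    # choose reactant molecules uniformly among each species' instances
    chosen <- integer()
    for (lab in names(rx@reactants)) {
      pool <- bySpecies[[lab]]
      nu <- rx@reactants[[lab]]
      if (length(pool) < nu)
        stop("internal: insufficient molecules of ", lab, " at event ", e)
      pick <- pool[sample.int(length(pool), nu)]
      chosen <- c(chosen, pick)
      bySpecies[[lab]] <- setdiff(bySpecies[[lab]], pick)
    }
    atomPool <- sort(unlist(lapply(molecules[chosen], `[[`, "atoms")))
    poolByElement <- split(atomPool, elements[atomPool])
    aliveIds <- setdiff(aliveIds, chosen)
    for (lab in rep(names(rx@products), rx@products)) {
      tpl <- atomTemplates[[lab]]
      atoms <- integer(length(tpl$elements))
      for (ai in seq_along(tpl$elements)) {
        el <- tpl$elements[ai]
        atoms[ai] <- poolByElement[[el]][1L]
        poolByElement[[el]] <- poolByElement[[el]][-1L]
      }
      bonds <- tpl$bonds
      if (nrow(bonds)) bonds <- cbind(atoms[bonds[, 1L]], atoms[bonds[, 2L]])
      molecules[[length(molecules) + 1L]] <-
        list(atoms = atoms, bonds = bonds)
      bySpecies[[lab]] <- c(bySpecies[[lab]], length(molecules))
      aliveIds <- c(aliveIds, length(molecules))
    }
    if (any(vapply(poolByElement, length, integer(1)) > 0L))
      stop("template/stoichiometry mismatch: leftover atoms at event ", e)
    curFrame <- snapshot()
  }
  while (fIdx <= length(times)) { frames[[fIdx]] <- curFrame; fIdx <- fIdx + 1L }
  bt <- BondTrajectory(elements, frames, frameDt = frameDt)
  truth <- list(network = templateNetwork,
                events = data.frame(time = evTimes,
                                    reaction = reactionLabels(
                                      templateNetwork)[evRx]),
                seed = seed, x0 = fullX0, frameDt = frameDt)
  list(bondTrajectory = bt, truth = truth)
}

#' Simulate a tau-leaping Poisson count stream with known rates
#'
#' Draws `n_j(t) ~ Poisson(k_j h_j(X(t)) dt)`, independent across
#' reactions and intervals, conditioning on the first T = nrow - 1 states
#' of the supplied path. Frames where a reaction is combinatorially
#' impossible (`h_j = 0`) contribute exactly zero counts.
#'
#' @param network a [ReactionNetwork-class] with rates set.
#' @param Xpath a [ConcentrationTrajectory-class] of conditioning states.
#' @param seed RNG seed.
#' @param dt observation interval; defaults to the network's.
#' @return a [ReactionCountSeries-class] (T x r).
#' @export
generateCountStream <- function(network, Xpath, seed = 1,
                                dt = deltaT(network)) {
  set.seed(seed)
  X <- countsMatrix(Xpath)
  Tn <- nrow(X) - 1L
  if (Tn < 1L) stop("Xpath needs at least two samples")
  H <- propensityMatrix(network, X[seq_len(Tn), , drop = FALSE])
  mu <- sweep(H, 2L, rates(network), `*`) * dt
  counts <- matrix(stats::rpois(length(mu), as.numeric(mu)),
                   nrow = nrow(mu))
  ReactionCountSeries(counts)
}

# all species multisets of total size 1..maxOrder, as label-count lists
speciesMultisets <- function(labs, maxOrder) {
  out <- list()
  m <- length(labs)
  for (ord in seq_len(maxOrder)) {
    combos <- utils::combn(m + ord - 1L, ord)  # multiset via stars & bars
    for (q in seq_len(ncol(combos))) {
      idx <- combos[, q] - seq_len(ord) + 1L
      out[[length(out) + 1L]] <- asMultiset(labs[idx])
    }
  }
  out
}

#' Inject atom-balanced spurious reactions with inflated rate estimates
#'
#' Appends `d` reactions built by recombining the network's existing
#' species under per-element atom balance. The injected reactions never
#' fired in the ground truth, but carry the kind of overestimated rate a
#' maximum-likelihood fit assigns to a rarely possible reaction observed
#' a handful of times: when a sample path is supplied, each spurious rate
#' is set to `rateInflation / (dt * sum_t h_j(X(t)))` — the estimate a
#' `rateInflation`-count observation would produce — and candidates that
#' are never possible along the path are skipped; without a path, rates
#' default to `rateInflation` times the median genuine rate.
#'
#' @param network a [ReactionNetwork-class] (the genuine model).
#' @param d number of spurious reactions to add (>= 0).
#' @param rateInflation pseudo-count (or multiplier, see above)
#'   controlling how inflated the spurious rates are.
#' @param seed RNG seed for sampling candidates.
#' @param samples optional [ConcentrationTrajectory-class] used to
#'   calibrate the spurious rates as overestimated MLEs.
#' @param dt observation interval; defaults to the network's.
#' @param maxOrder maximum reactant/product multiset size searched
#'   (default 2 reactants, products up to `maxOrder + 1`).
#' @return list with `network` (augmented [ReactionNetwork-class]) and
#'   `mask` (logical, TRUE for the genuine reactions).
#' @export
injectSpuriousReactions <- function(network, d, rateInflation = 1,
                                    seed = 1, samples = NULL,
                                    dt = deltaT(network), maxOrder = 2) {
  r0 <- nReactions(network)
  if (d == 0)
    return(list(network = network, mask = rep(TRUE, r0)))
  if (d < 0) stop("d must be >= 0")
  set.seed(seed)
  labs <- speciesLabels(network)
  byLabel <- stats::setNames(network@species, labs)
  existing <- reactionLabels(network)
  reactSets <- speciesMultisets(labs, maxOrder)
  prodSets <- speciesMultisets(labs, maxOrder + 1L)
  elKey <- function(ms) {
    tot <- elementTotals(ms, byLabel)
    paste(names(tot)[order(names(tot))], tot[order(names(tot))],
          collapse = " ")
  }
  rKeys <- vapply(reactSets, elKey, character(1))
  pKeys <- vapply(prodSets, elKey, character(1))
  candidates <- list()
  for (i in seq_along(reactSets)) {
    for (j in which(pKeys == rKeys[i])) {
      if (identical(reactSets[[i]], prodSets[[j]])) next
      rx <- Reaction(reactSets[[i]], prodSets[[j]])
      eq <- reactionEquation(rx)
      if (eq %in% existing) next
      candidates[[length(candidates) + 1L]] <- rx
    }
  }
  if (length(candidates) == 0L)
    stop("cannot construct any balanced spurious reaction from the ",
         "species pool")
  eqs <- vapply(candidates, reactionEquation, character(1))
  candidates <- candidates[!duplicated(eqs)]
  # identifiability: a candidate whose net stoichiometric vector is a
  # positive multiple of a genuine reaction's (or of another selected
  # candidate's) is indistinguishable at the conditional-moments level
  # (e.g. a spectator-catalysed copy of an existing reaction); such
  # candidates are excluded so the ground-truth mask is well defined
  netVec <- function(rx) {
    v <- stats::setNames(rep(0, length(labs)), labs)
    v[names(rx@reactants)] <- v[names(rx@reactants)] - rx@reactants
    v[names(rx@products)] <- v[names(rx@products)] + rx@products
    v
  }
  normNet <- function(rx) {
    v <- netVec(rx)
    paste(round(v / sqrt(sum(v^2)), 10), collapse = ",")
  }
  trueNets <- vapply(network@reactions, normNet, character(1))
  candNets <- vapply(candidates, normNet, character(1))
  keepId <- !(candNets %in% trueNets) & !duplicated(candNets)
  candidates <- candidates[keepId]
  candNets <- candNets[keepId]
  if (!is.null(samples)) {
    probe <- ReactionNetwork(network@species, candidates, dt = dt)
    X <- countsMatrix(samples)
    H <- propensityMatrix(probe, X[-nrow(X), , drop = FALSE])
    sumH <- colSums(H)
    keep <- sumH > 0
    candidates <- candidates[keep]
    sumH <- sumH[keep]
    if (length(candidates) < d)
      stop("only ", length(candidates),
           " feasible spurious candidates along the sample path")
    pick <- sample.int(length(candidates), d)
    spurious <- candidates[pick]
    kSpur <- rateInflation / (dt * sumH[pick])
  } else {
    if (length(candidates) < d)
      stop("only ", length(candidates), " spurious candidates available")
    pick <- sample.int(length(candidates), d)
    spurious <- candidates[pick]
    genuine <- rates(network)
    base <- if (any(genuine > 0)) stats::median(genuine[genuine > 0]) else 1
    kSpur <- rep(rateInflation * base, d)
  }
  for (q in seq_len(d)) spurious[[q]]@rateK <- kSpur[q]
  aug <- ReactionNetwork(network@species,
                         c(network@reactions, spurious), dt = network@dt)
  list(network = aug, mask = c(rep(TRUE, r0), rep(FALSE, d)))
}

# fixed internal geometries (angstroms) for the methane fragment species;
# bonded pairs sit well inside the standard cutoffs (C-C 1.98, C-H 1.57,
# H-H 1.09) and non-bonded intra-molecular pairs well outside them
fragmentGeometry <- function(nC, nH, hasCC) {
  if (nC == 0L && nH == 1L) return(matrix(0, 1, 3))
  if (nC == 0L && nH == 2L)
    return(rbind(c(0, 0, 0), c(0.74, 0, 0)))
  if (nC == 1L) {
    # C first, then H: tetrahedral directions scaled to 1.09
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    return(rbind(c(0, 0, 0), 1.09 * dirs[seq_len(nH), , drop = FALSE]))
  }
  if (nC == 2L && hasCC) {
    # staggered ethane-like: C at +-0.77 z, three H per C
    ang1 <- c(0, 2, 4) * pi / 3
    ang2 <- ang1 + pi / 3
    h1 <- cbind(1.03 * cos(ang1), 1.03 * sin(ang1), -0.77 - 0.36)
    h2 <- cbind(1.03 * cos(ang2), 1.03 * sin(ang2), 0.77 + 0.36)
    return(rbind(c(0, 0, -0.77), c(0, 0, 0.77),
                 h1[seq_len(min(3L, nH)), , drop = FALSE],
                 h2[seq_len(max(0L, nH - 3L)), , drop = FALSE]))
  }
  stop("no toy geometry for this species")
}

#' Toy coordinate emission for a bond trajectory
#'
#' Places every molecule of each frame on a coarse cubic lattice (spacing
#' far beyond all bond cutoffs) using fixed internal geometries for the
#' methane fragment set {CH4, CH3, H, H2, C2H6}, plus small Gaussian
#' jitter emulating thermal vibration. Atom-to-position assignment
#' follows each molecule's actual adjacency (hydrogens sit next to the
#' carbon they are bonded to), so [bondStatesFromCoordinates()] with the
#' standard cutoffs recovers the input bond graphs when the jitter is
#' small.
#'
#' @param bondTraj a [BondTrajectory-class] over C/H atoms of the
#'   methane fragment set.
#' @param jitter standard deviation of the Gaussian positional noise
#'   (angstroms, default 0.02).
#' @param spacing lattice spacing between molecule centers (default 8).
#' @param seed RNG seed.
#' @return list of n x 3 coordinate matrices, one per frame.
#' @export
bondFramesToCoordinates <- function(bondTraj, jitter = 0.02, spacing = 8,
                                    seed = 1) {
  set.seed(seed)
  els <- bondTraj@elements
  n <- bondTraj@nAtoms
  lapply(bondTraj@frames, function(edges) {
    part <- frameMolecules(edges, els, n)
    xyz <- matrix(0, n, 3)
    side <- ceiling(length(part$atomSets)^(1 / 3))
    for (ci in seq_along(part$atomSets)) {
      atoms <- part$atomSets[[ci]]
      cEls <- els[atoms]
      nC <- sum(cEls == "C"); nH <- sum(cEls == "H")
      e <- if (nrow(edges))
        edges[part$membership[edges[, 1L]] ==
                as.integer(names(part$atomSets))[ci], , drop = FALSE]
      else matrix(integer(), ncol = 2)
      hasCC <- any(els[e[, 1L]] == "C" & els[e[, 2L]] == "C")
      geo <- fragmentGeometry(nC, nH, hasCC)
      # order atoms: carbons first (by id); hydrogens grouped with the
      # carbon they bond to (slot blocks follow the geometry layout)
      cs <- atoms[cEls == "C"]
      hs <- atoms[cEls == "H"]
      if (length(cs) == 2L && length(hs)) {
        nb <- function(h) {
          row <- which(e[, 1L] == h | e[, 2L] == h)[1]
          if (is.na(row)) cs[1] else setdiff(e[row, ], h)[1]
        }
        hs <- hs[order(match(vapply(hs, nb, numeric(1)), cs))]
      }
      ordered <- c(cs, hs)
      center <- spacing * c((ci - 1) %% side,
                            ((ci - 1) %/% side) %% side,
                            (ci - 1) %/% side^2)
      xyz[ordered, ] <- geo[seq_along(ordered), , drop = FALSE] +
        rep(center, each = length(ordered)) +
        matrix(stats::rnorm(3 * length(ordered), 0, jitter),
               ncol = 3)
    }
    xyz
  })
}
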