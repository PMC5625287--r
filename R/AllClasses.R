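#' @import methods
NULL

#' Species: a molecule type identified by element and bond-type counts
#'
#' A molecular species is identified by how many atoms of each element it
#' contains and how many bonds of each unordered element-pair type it has.
#' This label dialect cannot distinguish structural isomers that share both
#' element counts and bond-type counts; that is a deliberate, documented
#' limitation of the notation.
#'
#' @slot elementCounts named integer vector, element symbol -> atom count
#'   (all positive).
#' @slot bondCounts named integer vector, canonical pair key (e.g. "C-H",
#'   elements in ascending priority order, ASCII hyphen) -> bond count.
#' @slot label canonical text rendering; a pure function of the two count
#'   vectors, so two Species are equal iff their labels are equal.
#' @export
setClass("Species",
  slots = c(elementCounts = "integer", bondCounts = "integer",
            label = "character"))

setValidity("Species", function(object) {
  ec <- object@elementCounts
  bc <- object@bondCounts
  msgs <- character()
  if (length(ec) == 0L || sum(ec) < 1L)
    msgs <- c(msgs, "species must contain at least one atom")
  if (any(ec <= 0L)) msgs <- c(msgs, "element counts must be positive")
  if (length(bc) && any(bc < 0L))
    msgs <- c(msgs, "bond counts must be non-negative")
  n <- sum(ec)
  if (length(bc) && sum(bc) > n * (n - 1L) / 2L)
    msgs <- c(msgs, "total bond count exceeds choose(atoms, 2)")
  if (length(bc)) {
    els <- unique(unlist(strsplit(names(bc), "-", fixed = TRUE)))
    if (!all(els %in% names(ec)))
      msgs <- c(msgs, "bond pair references an element not in the molecule")
  }
  if (!identical(object@label, canonicalLabel(ec, bc)))
    msgs <- c(msgs, "label is not the canonical rendering of the counts")
  if (length(msgs)) msgs else TRUE
})

#' Reaction: reactant and product multisets with a rate coefficient
#'
#' Reactants and products are stored as named integer multisets keyed by
#' species label; the stoichiometric column vector is derived against a
#' [ReactionNetwork]'s species ordering via [stoichMatrix()].
#'
#' @slot reactants,products named integer vectors (label -> multiplicity,
#'   all positive).
#' @slot rateK non-negative rate coefficient, units
#'   count^(1 - order) / time.
#' @slot observedCountTotal total number of observed firings across all
#'   sampled intervals.
#' @export
setClass("Reaction",
  slots = c(reactants = "integer", products = "integer",
            rateK = "numeric", observedCountTotal = "numeric"))

setValidity("Reaction", function(object) {
  msgs <- character()
  if (length(object@reactants) == 0L)
    msgs <- c(msgs, "reaction must have at least one reactant")
  if (any(object@reactants < 1L) || any(object@products < 1L))
    msgs <- c(msgs, "multiplicities must be positive integers")
  if (is.null(names(object@reactants)) ||
      (length(object@products) && is.null(names(object@products))))
    msgs <- c(msgs, "reactant/product multisets must be named by species label")
  if (length(object@rateK) != 1L || is.na(object@rateK) || object@rateK < 0)
    msgs <- c(msgs, "rateK must be a single non-negative number")
  if (length(object@observedCountTotal) != 1L || object@observedCountTotal < 0)
    msgs <- c(msgs, "observedCountTotal must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' ReactionNetwork: m species, r reactions, and the sampling interval
#'
#' @slot species list of [Species] with unique labels (ordering defines the
#'   rows of the stoichiometry matrix).
#' @slot reactions list of [Reaction]; every reactant/product label must
#'   resolve to a network species.
#' @slot dt sampling interval Delta-t between trajectory frames (time
#'   units; the tau-leaping observation window).
#' @export
setClass("ReactionNetwork",
  slots = c(species = "list", reactions = "list", dt = "numeric"))

# Structural validity only (types, dt). Label uniqueness, species-reference
# resolution and atom balance are reported by validateNetwork(), which the
# ReactionNetwork() constructor enforces; keeping them out of the S4
# validity lets validateNetwork() be exercised on deliberately broken
# objects built with new().
setValidity("ReactionNetwork", function(object) {
  msgs <- character()
  if (length(object@species) < 1L)
    msgs <- c(msgs, "network needs at least one species")
  if (!all(vapply(object@species, is, logical(1), "Species")))
    msgs <- c(msgs, "species slot must contain Species objects")
  if (!all(vapply(object@reactions, is, logical(1), "Reaction")))
    msgs <- c(msgs, "reactions slot must contain Reaction objects")
  if (length(object@dt) != 1L || is.na(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "dt must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' ConcentrationTrajectory: per-frame species counts X(t)
#'
#' @slot times strictly increasing sample times (length T+1).
#' @slot counts (T+1) x m non-negative integer matrix; column names are
#'   species labels.
#' @export
setClass("ConcentrationTrajectory",
  slots = c(times = "numeric", counts = "matrix"))

setValidity("ConcentrationTrajectory", function(object) {
  msgs <- character()
  if (nrow(object@counts) != length(object@times))
    msgs <- c(msgs, "one row of counts per sample time required")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@counts < 0))
    msgs <- c(msgs, "species counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    msgs <- c(msgs, "species counts must be integers")
  if (is.null(colnames(object@counts)))
    msgs <- c(msgs, "counts columns must be named by species label")
  if (length(msgs)) msgs else TRUE
})

#' ReactionCountSeries: observed per-interval firing counts n_j(t, t+dt)
#'
#' @slot counts T x r non-negative integer matrix; entry (t, j) is the
#'   number of firings of reaction j in the interval starting at sample t.
#' @export
setClass("ReactionCountSeries", slots = c(counts = "matrix"))

setValidity("ReactionCountSeries", function(object) {
  msgs <- character()
  if (length(object@counts) && any(object@counts < 0))
    msgs <- c(msgs, "firing counts must be non-negative")
  if (length(object@counts) && any(object@counts != round(object@counts)))
    msgs <- c(msgs, "firing counts must be integers")
  if (length(msgs)) msgs else TRUE
})

#' BondTrajectory: per-frame bond graphs over a fixed set of typed atoms
#'
#' @slot nAtoms number of atoms (fixed across frames).
#' @slot elements per-atom element symbols, length nAtoms.
#' @slot frames list of T+1 edge matrices (k x 2 integer, 1-based atom
#'   indices, no self-edges).
#' @slot frameDt time between frames (the sampling interval Delta-t).
#' @export
setClass("BondTrajectory",
  slots = c(nAtoms = "integer", elements = "character", frames = "list",
            frameDt = "numeric"))

setValidity("BondTrajectory", function(object) {
  msgs <- character()
  if (length(object@elements) != object@nAtoms)
    msgs <- c(msgs, "one element symbol per atom required")
  for (f in object@frames) {
    if (!is.matrix(f) || ncol(f) != 2L) {
      msgs <- c(msgs, "each frame must be a 2-column edge matrix")
      break
    }
    if (nrow(f) && (any(f < 1L) || any(f > object@nAtoms) ||
                    any(f[, 1L] == f[, 2L]))) {
      msgs <- c(msgs, "edge references an invalid atom index or a self-edge")
      break
    }
  }
  if (length(object@frameDt) != 1L || object@frameDt <= 0)
    msgs <- c(msgs, "frameDt must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' EventTrajectory: one realization of a Gillespie simulation
#'
#' @slot x0 named integer initial state (species counts).
#' @slot eventTimes strictly increasing firing times.
#' @slot eventReactions reaction index (column of the stoichiometry
#'   matrix) fired at each event time.
#' @slot tEnd end of the simulated horizon.
#' @slot frozen TRUE when the simulation stopped because the total
#'   propensity reached zero before tEnd.
#' @export
setClass("EventTrajectory",
  slots = c(x0 = "integer", eventTimes = "numeric",
            eventReactions = "integer", tEnd = "numeric",
            frozen = "logical"))

setValidity("EventTrajectory", function(object) {
  msgs <- character()
  if (length(object@eventTimes) != length(object@eventReactions))
    msgs <- c(msgs, "one reaction index per event time required")
  if (length(object@eventTimes) > 1L && any(diff(object@eventTimes) <= 0))
    msgs <- c(msgs, "event times must be strictly increasing")
  if (length(object@eventTimes) &&
      (min(object@eventTimes) < 0 || max(object@eventTimes) > object@tEnd))
    msgs <- c(msgs, "event times must lie within [0, tEnd]")
  if (length(msgs)) msgs else TRUE
})

#' MomentSystem: the conditional-moments linear system in normal form
#'
#' Stacks, over all sampled states X(t), the per-step conditional mean
#' (m rows) and upper-triangular conditional covariance (m(m+1)/2 rows) of
#' the concentration change, each expressed as a linear function of the
#' dimensionless scaled rates k in [0,1]^r. Only the normal-equation
#' summaries A'A, A'b and b'b are required by the reducers; the explicit
#' A and b are retained for small problems.
#'
#' @slot AtA r x r symmetric positive semidefinite normal matrix.
#' @slot Atb length-r normal vector.
#' @slot btb squared norm of the target vector b.
#' @slot rowCount number of rows of the (possibly implicit) A, equal to
#'   T * (m + m(m+1)/2).
#' @slot kEst the maximum-likelihood rates used to scale the columns.
#' @slot A,b the explicit system when rowCount is small enough to store
#'   (zero-row matrix / zero-length vector otherwise).
#' @export
setClass("MomentSystem",
  slots = c(AtA = "matrix", Atb = "numeric", btb = "numeric",
            rowCount = "numeric", kEst = "numeric", A = "matrix",
            b = "numeric"))

setValidity("MomentSystem", function(object) {
  msgs <- character()
  r <- length(object@kEst)
  if (!identical(dim(object@AtA), c(r, r)))
    msgs <- c(msgs, "AtA must be r x r")
  if (length(object@Atb) != r)
    msgs <- c(msgs, "Atb must have length r")
  if (max(abs(object@AtA - t(object@AtA))) > 1e-8 * (1 + max(abs(object@AtA))))
    msgs <- c(msgs, "AtA must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' ReductionResult: outcome of one model-reduction run
#'
#' @slot support logical vector over the input network's reactions
#'   (TRUE = kept).
#' @slot kRelaxed the relaxed scaled rates in [0,1] (LASSO; for the other
#'   methods the binary support as numeric).
#' @slot network the reduced [ReactionNetwork] (kept reactions with rates
#'   kEst * k; dropped reactions removed).
#' @slot objective value of the moment-matching objective ||Ak - b||^2
#'   (NA for count-based reduction).
#' @slot method one of "count", "iqp", "lasso".
#' @slot lambda the complexity budget used (minimum count f for "count").
#' @export
setClass("ReductionResult",
  slots = c(support = "logical", kRelaxed = "numeric",
            network = "ReactionNetwork", objective = "numeric",
            method = "character", lambda = "numeric"))
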