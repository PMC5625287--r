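EQ_ARROW <- "\u21d2"

# normalise a multiset given either as a named count vector or as a
# character vector of labels (multiplicity by repetition)
asMultiset <- function(x) {
  if (is.character(x)) {  # labels with multiplicity by repetition
    tb <- table(unname(x))
    out <- as.integer(tb)
    names(out) <- names(tb)
    return(out)
  }
  out <- as.integer(x)
  names(out) <- names(x)
  out[out > 0L]
}

#' Construct a Reaction
#'
#' @param reactants,products species multisets: either a named integer
#'   vector (label -> multiplicity) or a character vector of labels with
#'   multiplicity by repetition.
#' @param rateK rate coefficient (count^(1-order)/time); default 0.
#' @param observedCountTotal total observed firings; default 0.
#' @return a [Reaction-class] object.
#' @examples
#' Reaction(c(A = 2), c(B = 1), rateK = 0.5)  # A + A => B
#' @export
Reaction <- function(reactants, products, rateK = 0, observedCountTotal = 0) {
  new("Reaction", reactants = asMultiset(reactants),
      products = asMultiset(products), rateK = as.numeric(rateK),
      observedCountTotal = as.numeric(observedCountTotal))
}

#' Textual equation for a reaction
#'
#' Renders `"A + A => B"` style equations with each molecule copy printed
#' separately, in deterministic (radix-sorted) label order; used as the
#' reaction identity when comparing networks.
#'
#' @param reaction a [Reaction-class] object.
#' @return single character equation.
#' @export
reactionEquation <- function(reaction) {
  side <- function(ms) {
    labs <- rep(names(ms), ms)
    paste(sort(labs, method = "radix"), collapse = " + ")
  }
  paste(side(reaction@reactants), EQ_ARROW, side(reaction@products))
}

#' Reaction order (total reactant multiplicity)
#' @param reaction a [Reaction-class] object.
#' @return integer order (>= 1).
#' @export
reactionOrder <- function(reaction) sum(reaction@reactants)

#' Construct a ReactionNetwork
#'
#' @param species list of [Species-class] objects (or a single Species).
#' @param reactions list of [Reaction-class] objects.
#' @param dt sampling interval Delta-t between trajectory frames.
#' @param check if TRUE (default), structural violations reported by
#'   [validateNetwork()] other than atom-balance are errors. Atom balance
#'   is always reported, never an error here, so that abstract networks
#'   over symbolic species remain constructible.
#' @return a [ReactionNetwork-class] object.
#' @export
ReactionNetwork <- function(species, reactions = list(), dt = 1,
                            check = TRUE) {
  if (is(species, "Species")) species <- list(species)
  if (is(reactions, "Reaction")) reactions <- list(reactions)
  nw <- new("ReactionNetwork", species = species, reactions = reactions,
            dt = as.numeric(dt))
  if (check) {
    v <- validateNetwork(nw)
    v <- v[v$type %in% c("duplicate-species", "unknown-species"), ,
           drop = FALSE]
    if (nrow(v))
      stop("invalid network: ", paste(v$message, collapse = "; "))
  }
  nw
}

#' @rdname accessors
#' @export
setMethod("speciesList", "ReactionNetwork", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("speciesLabels", "ReactionNetwork", function(object)
  vapply(object@species, function(s) s@label, character(1)))

#' @rdname accessors
#' @export
setMethod("reactionList", "ReactionNetwork", function(object)
  object@reactions)

#' @rdname accessors
#' @export
setMethod("reactionLabels", "ReactionNetwork", function(object)
  vapply(object@reactions, reactionEquation, character(1)))

#' @rdname accessors
#' @export
setMethod("nSpecies", "ReactionNetwork", function(object)
  length(object@species))

#' @rdname accessors
#' @export
setMethod("nReactions", "ReactionNetwork", function(object)
  length(object@reactions))

#' @rdname accessors
#' @export
setMethod("deltaT", "ReactionNetwork", function(object) object@dt)

#' @rdname accessors
#' @export
setMethod("rates", "ReactionNetwork", function(object)
  vapply(object@reactions, function(rx) rx@rateK, numeric(1)))

#' @rdname accessors
#' @export
setReplaceMethod("rates", "ReactionNetwork", function(object, value) {
  stopifnot(length(value) == length(object@reactions), all(value >= 0))
  for (j in seq_along(value)) object@reactions[[j]]@rateK <- value[j]
  object
})

#' Total observed firing counts per reaction
#' @param network a [ReactionNetwork-class] object.
#' @return numeric vector of length r.
#' @export
observedCounts <- function(network)
  vapply(network@reactions, function(rx) rx@observedCountTotal, numeric(1))

#' @describeIn ReactionNetwork-class stoichiometry matrix R (m x r):
#'   column j is the net species change R_j of one firing of reaction j
#'   (products minus reactants).
#' @param object a ReactionNetwork
#' @export
setMethod("stoichMatrix", "ReactionNetwork", function(object) {
  labs <- speciesLabels(object)
  r <- length(object@reactions)
  R <- matrix(0L, nrow = length(labs), ncol = r,
              dimnames = list(labs, NULL))
  for (j in seq_len(r)) {
    rx <- object@reactions[[j]]
    R[names(rx@reactants), j] <- R[names(rx@reactants), j] - rx@reactants
    R[names(rx@products), j] <- R[names(rx@products), j] + rx@products
  }
  R
})

#' Reactant multiplicity matrix (m x r)
#'
#' Entry (i, j) is the stoichiometric multiplicity of species i among the
#' reactants of reaction j; the propensity combinatorics are driven by
#' this matrix.
#'
#' @param network a [ReactionNetwork-class] object.
#' @return m x r integer matrix with species labels as row names.
#' @export
reactantMatrix <- function(network) {
  labs <- speciesLabels(network)
  r <- length(network@reactions)
  M <- matrix(0L, nrow = length(labs), ncol = r,
              dimnames = list(labs, NULL))
  for (j in seq_len(r)) {
    rx <- network@reactions[[j]]
    M[names(rx@reactants), j] <- rx@reactants
  }
  M
}

# per-element atom totals for a species multiset, given a label -> Species
# lookup
elementTotals <- function(multiset, speciesByLabel) {
  tot <- integer()
  for (lab in names(multiset)) {
    ec <- speciesByLabel[[lab]]@elementCounts * multiset[[lab]]
    for (el in names(ec)) tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0L) + ec[[el]]
  }
  tot
}

#' Validate a reaction network
#'
#' Reporting operation: checks species-label uniqueness, that every
#' reactant/product label resolves to a network species, that reaction
#' order is at least one, and per-element atom balance of every reaction
#' (atoms in reactants equal atoms in products, element by element).
#'
#' @param network a [ReactionNetwork-class] object.
#' @return a data.frame with columns `type`, `reaction` (index, NA for
#'   network-level violations) and `message`; zero rows iff the network is
#'   valid.
#' @export
validateNetwork <- function(network) {
  out <- data.frame(type = character(), reaction = integer(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(type, reaction, message)
    rbind(out, data.frame(type = type, reaction = reaction,
                          message = message, stringsAsFactors = FALSE))
  labs <- speciesLabels(network)
  dup <- unique(labs[duplicated(labs)])
  for (d in dup)
    out <- add("duplicate-species", NA_integer_,
               paste0("duplicate species label: ", d))
  byLabel <- stats::setNames(network@species, labs)
  for (j in seq_along(network@reactions)) {
    rx <- network@reactions[[j]]
    unknown <- setdiff(c(names(rx@reactants), names(rx@products)), labs)
    if (length(unknown)) {
      out <- add("unknown-species", j,
                 paste0("reaction ", j, " references unknown species: ",
                        paste(unknown, collapse = ", ")))
      next
    }
    if (sum(rx@reactants) < 1L)
      out <- add("order", j, paste0("reaction ", j, " has order < 1"))
    lhs <- elementTotals(rx@reactants, byLabel)
    rhs <- elementTotals(rx@products, byLabel)
    els <- union(names(lhs), names(rhs))
    l <- stats::setNames(rep(0L, length(els)), els); l[names(lhs)] <- lhs
    r <- stats::setNames(rep(0L, length(els)), els); r[names(rhs)] <- rhs
    if (any(l != r))
      out <- add("atom-balance", j,
                 paste0("reaction ", j, " (", reactionEquation(rx),
                        ") unbalanced in: ",
                        paste(els[l != r], collapse = ", ")))
  }
  out
}

#' @describeIn ReactionNetwork-class compact summary
#' @export
setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", nSpecies(object), "species,",
      nReactions(object), "reactions, dt =", object@dt, "\n")
  labs <- reactionLabels(object)
  k <- rates(object)
  n <- min(length(labs), 10L)
  for (j in seq_len(n))
    cat(sprintf("  [%d] %s  (k = %.4g)\n", j, labs[j], k[j]))
  if (length(labs) > n) cat("  ...", length(labs) - n, "more\n")
  invisible(object)
})
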