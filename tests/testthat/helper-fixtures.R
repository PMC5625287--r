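# abstract (symbolic) species: one pseudo-atom of element <name>
absSpecies <- function(name) Species(stats::setNames(1L, name))

# network of abstract unimolecular/bimolecular reactions given as strings
# like "A -> B" or "A + A -> B"; rates parallel vector
absNetwork <- function(eqs, rates, dt = 1) {
  parse1 <- function(eq) {
    sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
    lapply(sides, function(s) {
      toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      toks[nzchar(toks)]
    })
  }
  parsed <- lapply(eqs, parse1)
  els <- unique(unlist(parsed))
  sp <- lapply(els, absSpecies)
  labs <- stats::setNames(vapply(sp, function(s) s@label, character(1)), els)
  rxs <- lapply(seq_along(parsed), function(i)
    Reaction(unname(labs[parsed[[i]][[1]]]), unname(labs[parsed[[i]][[2]]]),
             rateK = rates[i]))
  ReactionNetwork(sp, rxs, dt = dt)
}

# label helper for abstract states: x0 by element letter
absState <- function(network, ...) {
  vals <- c(...)
  labs <- speciesLabels(network)
  out <- stats::setNames(rep(0, length(labs)), labs)
  out[paste0(names(vals), "1")] <- vals
  out
}

# brute-force reference automaton for the bond-duration filter:
# frame-by-frame two-state machine with retroactive stamping
hysteresisOracle <- function(raw, tau, initial = raw[1]) {
  raw <- as.logical(raw)
  n <- length(raw)
  state <- as.logical(initial)
  out <- logical(n)
  runLen <- 0L
  runStart <- 1L
  for (f in seq_len(n)) {
    if (raw[f] != state) {
      if (runLen == 0L) runStart <- f
      runLen <- runLen + 1L
      if (runLen >= tau) {
        state <- raw[f]
        out[runStart:f] <- state
        runLen <- 0L
      } else out[f] <- state
    } else {
      runLen <- 0L
      out[f] <- state
    }
  }
  out
}

# brute-force count of distinct unordered reactant tuples: enumerate
# subsets of labelled molecules per species and multiply the subset counts
tupleCountOracle <- function(multiplicities, X) {
  total <- 1
  for (spec in names(multiplicities)) {
    nu <- multiplicities[[spec]]
    x <- X[[spec]]
    if (x < nu) return(0)
    total <- total * nrow(unique(t(utils::combn(x, nu))))
  }
  total
}

# random moment system over an abstract network; returns list(moment,
# network, samples)
randomMomentSystem <- function(seed, m = 3, r = 5, Tn = 12) {
  set.seed(seed)
  els <- LETTERS[seq_len(m)]
  sp <- lapply(els, absSpecies)
  labs <- vapply(sp, function(s) s@label, character(1))
  rxs <- list()
  while (length(rxs) < r) {
    ord <- sample(1:2, 1)
    re <- sample(labs, ord, replace = TRUE)
    pr <- sample(labs, sample(1:2, 1), replace = TRUE)
    if (identical(sort(re), sort(pr))) next
    rxs[[length(rxs) + 1L]] <- Reaction(re, pr,
                                        rateK = stats::runif(1, 0.1, 2))
  }
  nw <- ReactionNetwork(sp, rxs, dt = 0.1)
  X <- matrix(stats::rpois((Tn + 1) * m, 8), ncol = m,
              dimnames = list(NULL, labs))
  samples <- ConcentrationTrajectory(seq(0, by = 0.1, length.out = Tn + 1),
                                     X)
  list(moment = buildMomentSystem(nw, samples), network = nw,
       samples = samples)
}

# exhaustive IQP oracle: minimize ||Ak-b||^2 over binary k, sum(k) <= lambda
iqpOracle <- function(moment, lambda) {
  r <- length(moment@kEst)
  best <- Inf
  bestK <- rep(0, r)
  for (size in 0:lambda) {
    combos <- if (size == 0) matrix(integer(), nrow = 0, ncol = 1) else
      utils::combn(r, size)
    nc <- if (size == 0) 1L else ncol(combos)
    for (q in seq_len(nc)) {
      k <- rep(0, r)
      if (size > 0) k[combos[, q]] <- 1
      val <- as.numeric(t(k) %*% moment@AtA %*% k -
                          2 * sum(moment@Atb * k) + moment@btb)
      if (val < best - 1e-12) { best <- val; bestK <- k }
    }
  }
  list(value = best, k = bestK)
}

# labels of the methane fragment set, for readable tests
methaneLabels <- function() {
  toy <- methaneToyNetwork()
  stats::setNames(speciesLabels(toy$network),
                  c("CH4", "CH3", "H", "H2", "C2H6"))
}
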