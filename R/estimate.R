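#' Combinatorial reactant-tuple count h_j
#'
#' Number of distinct unordered reactant tuples available for one firing
#' of a reaction at the current species counts: the product over reactant
#' species of `choose(X_m, nu_m)`. This reproduces the standard propensity
#' combinatorics — `X_m` for a unimolecular reaction, `X_m * X_m'` for a
#' bimolecular reaction of two distinct species, `choose(X_m, 2)` when the
#' two reactants are the same species — and extends it to trimolecular
#' reactions with repeated species (e.g. A + A + B gives
#' `choose(X_A, 2) * X_B`). Returns 0 whenever any reactant count is below
#' its required multiplicity.
#'
#' @param multiplicities named vector, species label -> reactant
#'   multiplicity nu (all >= 1).
#' @param X named species counts (must cover the reactant species).
#' @return a single non-negative number.
#' @examples
#' combinatorialCount(c(A = 1), c(A = 7))            # 7
#' combinatorialCount(c(A = 2), c(A = 4))            # choose(4, 2) = 6
#' combinatorialCount(c(A = 2, B = 1), c(A = 3, B = 2))  # 3 * 2 = 6
#' @export
combinatorialCount <- function(multiplicities, X) {
  if (any(X < 0)) stop("species counts must be non-negative")
  if (any(multiplicities < 1)) stop("multiplicities must be >= 1")
  prod(choose(X[names(multiplicities)], multiplicities))
}

#' Propensity combinatorics over a whole trajectory
#'
#' Evaluates h_j(X(t)) for every reaction j at every sampled state.
#'
#' @param network a [ReactionNetwork-class].
#' @param X a T x m matrix of species counts (columns named by species
#'   label) or a [ConcentrationTrajectory-class].
#' @return T x r matrix of combinatorial counts.
#' @export
propensityMatrix <- function(network, X) {
  if (is(X, "ConcentrationTrajectory")) X <- X@counts
  labs <- speciesLabels(network)
  missing <- setdiff(labs, colnames(X))
  if (length(missing)) {
    X <- cbind(X, matrix(0, nrow = nrow(X), ncol = length(missing),
                         dimnames = list(NULL, missing)))
  }
  M <- reactantMatrix(network)
  H <- matrix(1, nrow = nrow(X), ncol = ncol(M))
  for (j in seq_len(ncol(M))) {
    nz <- which(M[, j] > 0L)
    for (i in nz)
      H[, j] <- H[, j] * choose(X[, labs[i]], M[i, j])
  }
  H
}

#' Maximum-likelihood rate coefficients under the tau-leaping model
#'
#' Per-interval firing counts are modelled as conditionally independent
#' Poisson variables with mean `k_j * h_j(X(t)) * dt`. The closed-form
#' maximizer of the Poisson log-likelihood is, per reaction,
#' `k_j = sum_t n_j(t) / (dt * sum_t h_j(X(t)))`. Reactions estimated from
#' few informative intervals (frames where the reaction was possible at
#' all) carry noisy, typically overestimated rates; the informative
#' interval count is returned as a confidence proxy and no shrinkage is
#' applied — model reduction handles such reactions downstream.
#'
#' @param counts a [ReactionCountSeries-class] (T x r); row t holds the
#'   firings in the interval starting at sample t.
#' @param trajectory a [ConcentrationTrajectory-class] with at least T
#'   rows; row t of `counts` conditions on state row t.
#' @param network the [ReactionNetwork-class] defining reactant
#'   multiplicities (column order matching `counts`).
#' @param dt observation interval; defaults to the network's.
#' @return list with `k` (rate estimates; NA for reactions never possible
#'   and never observed), `informative` (number of intervals with
#'   h_j > 0), `totalCounts` (sum_t n_j) and `sumH` (sum_t h_j).
#' @export
estimateRates <- function(counts, trajectory, network,
                          dt = deltaT(network)) {
  if (dt <= 0) stop("dt must be positive")
  N <- countsMatrix(counts)
  Tn <- nrow(N)
  X <- countsMatrix(trajectory)
  if (nrow(X) < Tn)
    stop("trajectory must provide a state for every counted interval")
  H <- propensityMatrix(network, X[seq_len(Tn), , drop = FALSE])
  totalN <- colSums(N)
  sumH <- colSums(H)
  informative <- colSums(H > 0)
  bad <- sumH == 0 & totalN > 0
  if (any(bad))
    stop("inconsistent data: reaction(s) ",
         paste(which(bad), collapse = ", "),
         " observed at states where they were never possible")
  k <- ifelse(sumH > 0, totalN / (dt * sumH), NA_real_)
  list(k = k, informative = informative, totalCounts = totalN,
       sumH = sumH)
}

#' Poisson log-likelihood of observed counts under a rate vector
#'
#' `l = sum_{t,j} [ n log(mu) - mu - log(n!) ]` with
#' `mu = k_j h_j(X(t)) dt`; terms with `mu = 0, n = 0` contribute zero.
#' When some `mu = 0` but `n > 0` the likelihood is zero: the function
#' returns `-Inf` with attribute `zeroMeanViolations` giving the number of
#' offending terms, rather than raising an error. `log(n!)` is computed
#' via the log-gamma function.
#'
#' @param network a [ReactionNetwork-class] with rates set.
#' @param counts a [ReactionCountSeries-class].
#' @param trajectory the conditioning [ConcentrationTrajectory-class].
#' @param dt observation interval; defaults to the network's.
#' @return the log-likelihood (scalar; possibly `-Inf`, flagged).
#' @export
poissonLogLikelihood <- function(network, counts, trajectory,
                                 dt = deltaT(network)) {
  N <- countsMatrix(counts)
  Tn <- nrow(N)
  X <- countsMatrix(trajectory)
  H <- propensityMatrix(network, X[seq_len(Tn), , drop = FALSE])
  mu <- sweep(H, 2L, rates(network), `*`) * dt
  viol <- sum(mu == 0 & N > 0)
  if (viol > 0)
    return(structure(-Inf, zeroMeanViolations = viol))
  pos <- mu > 0
  sum(N[pos] * log(mu[pos]) - mu[pos] - lgamma(N[pos] + 1)) - sum(mu[!pos])
}
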