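# indices of the upper triangle (with diagonal), column-major, for vech
vechIndex <- function(m) which(upper.tri(diag(m), diag = TRUE))

#' Build the conditional-moments linear system
#'
#' For each sampled state X(t), the conditional mean of the concentration
#' change over one interval is `R diag(k h(X(t)) dt) 1` and the
#' conditional covariance is `R Lambda(X(t)) R'` with `Lambda` diagonal
#' with entries `k_j h_j(X(t)) dt`. Scaling the rate variable by the
#' maximum-likelihood estimates makes `k = 1` reproduce the full model,
#' so the stacked system satisfies `b = A 1` exactly. Column j of A holds,
#' per sample, the m mean rows `R_j k_est,j h_j dt` and the m(m+1)/2
#' upper-triangular covariance rows of `R_j R_j' k_est,j h_j dt`; b is
#' accumulated through the independent full-model moment formulas.
#' Only the normal-equation summaries A'A and A'b are required downstream
#' and are accumulated streaming over t; the explicit A and b are kept
#' when the row count `T (m + m(m+1)/2)` is at most `explicitMax`.
#' A'A is symmetrised and repaired to positive semidefinite by clipping
#' tiny negative eigenvalues (above -1e-10 relative) to zero.
#'
#' @param network a [ReactionNetwork-class] whose rates are the
#'   maximum-likelihood estimates (all strictly positive; exclude
#'   zero-rate reactions first).
#' @param samples a [ConcentrationTrajectory-class] of sampled states
#'   (typically one Gillespie realization of the full model sampled at
#'   dt); the first T = nrow - 1 states condition the T transitions.
#' @param dt sampling interval; defaults to the network's.
#' @param explicitMax keep the explicit A and b when the row count is at
#'   most this (default 1e5).
#' @return a [MomentSystem-class].
#' @export
buildMomentSystem <- function(network, samples, dt = deltaT(network),
                              explicitMax = 1e5) {
  if (dt <= 0) stop("dt must be positive")
  kEst <- rates(network)
  if (any(kEst <= 0))
    stop("all included reactions need k_est > 0; drop zero-rate reactions first")
  X <- countsMatrix(samples)
  Tn <- nrow(X) - 1L
  if (Tn < 1L) stop("at least one sampled transition is required")
  R <- stoichMatrix(network)
  m <- nrow(R); r <- ncol(R)
  H <- propensityMatrix(network, X[seq_len(Tn), , drop = FALSE])
  ut <- vechIndex(m)
  blockRows <- m + length(ut)
  rowCount <- Tn * blockRows
  keepExplicit <- rowCount <= explicitMax
  # per-reaction vech(R_j R_j') templates
  covTemplates <- vapply(seq_len(r), function(j)
    (R[, j] %o% R[, j])[ut], numeric(length(ut)))
  covTemplates <- matrix(covTemplates, nrow = length(ut))
  AtA <- matrix(0, r, r)
  Atb <- numeric(r)
  btb <- 0
  Aexp <- if (keepExplicit) matrix(0, rowCount, r) else matrix(0, 0L, r)
  bexp <- if (keepExplicit) numeric(rowCount) else numeric(0)
  for (t in seq_len(Tn)) {
    w <- kEst * H[t, ] * dt
    Ablock <- rbind(sweep(R, 2L, w, `*`),
                    sweep(covTemplates, 2L, w, `*`))
    # independent full-model path for b: mean R a dt, covariance R Lambda R'
    mu <- as.numeric(R %*% w)
    Sg <- R %*% (w * t(R))
    bblock <- c(mu, Sg[ut])
    AtA <- AtA + crossprod(Ablock)
    Atb <- Atb + as.numeric(crossprod(Ablock, bblock))
    btb <- btb + sum(bblock^2)
    if (keepExplicit) {
      rows <- ((t - 1L) * blockRows + 1L):(t * blockRows)
      Aexp[rows, ] <- Ablock
      bexp[rows] <- bblock
    }
  }
  AtA <- (AtA + t(AtA)) / 2
  eg <- eigen(AtA, symmetric = TRUE)
  scale <- max(abs(eg$values), 1)
  if (any(eg$values < 0)) {
    vals <- eg$values
    vals[vals < 0 & vals > -1e-10 * scale] <- 0
    AtA <- eg$vectors %*% (vals * t(eg$vectors))
    AtA <- (AtA + t(AtA)) / 2
  }
  new("MomentSystem", AtA = AtA, Atb = Atb, btb = btb,
      rowCount = as.numeric(rowCount), kEst = kEst, A = Aexp, b = bexp)
}

#' @describeIn MomentSystem-class compact summary
#' @param object a MomentSystem
#' @export
setMethod("show", "MomentSystem", function(object) {
  cat("MomentSystem:", object@rowCount, "rows x", length(object@kEst),
      "reactions", if (nrow(object@A)) "(explicit A kept)" else "", "\n")
  invisible(object)
})

# moment-matching objective ||A k - b||^2 via normal-form summaries
momentObjective <- function(moment, k) {
  as.numeric(t(k) %*% moment@AtA %*% k - 2 * sum(moment@Atb * k) +
               moment@btb)
}

# subset a network's reactions, scaling kept rates by `scale`
subsetNetwork <- function(network, support, scale = NULL) {
  kept <- which(support)
  rxs <- network@reactions[kept]
  if (!is.null(scale))
    for (q in seq_along(kept))
      rxs[[q]]@rateK <- rxs[[q]]@rateK * scale[kept[q]]
  ReactionNetwork(network@species, rxs, dt = network@dt)
}

#' Count-based model reduction
#'
#' Removes every reaction whose total observed firing count is below the
#' minimum count `f`. All reactions with equal totals are necessarily
#' removed (or kept) together — the granularity limitation of this
#' method. Note this differs from removing the lowest-rate reactions: the
#' observed count depends on both the rate and how often the reaction was
#' combinatorially possible.
#'
#' @param network a [ReactionNetwork-class].
#' @param counts a [ReactionCountSeries-class] aligned with the network;
#'   if NULL the networks' stored `observedCountTotal`s are used.
#' @param f minimum count (integer >= 1); reaction j is kept iff
#'   `sum_t n_j >= f`.
#' @return a [ReductionResult-class].
#' @export
countBasedReduce <- function(network, counts = NULL, f = 1) {
  if (length(f) != 1L || is.na(f) || f < 1)
    stop("minimum count f must be >= 1")
  totals <- if (is.null(counts)) observedCounts(network)
            else colSums(countsMatrix(counts))
  if (length(totals) != nReactions(network))
    stop("counts are not aligned with the network")
  support <- totals >= f
  new("ReductionResult", support = support,
      kRelaxed = as.numeric(support),
      network = subsetNetwork(network, support),
      objective = NA_real_, method = "count", lambda = as.numeric(f))
}

# Euclidean projection onto { 0 <= k <= 1, sum(k) <= lambda } by
# bisection on the shift theta in clip(v - theta, 0, 1).
projectBoxCap <- function(v, lambda) {
  k <- pmin(pmax(v, 0), 1)
  if (sum(k) <= lambda + 1e-12) return(k)
  lo <- 0
  hi <- max(v)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    s <- sum(pmin(pmax(v - mid, 0), 1))
    if (s > lambda) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, hi)) break
  }
  pmin(pmax(v - (lo + hi) / 2, 0), 1)
}

# Accelerated projected-gradient minimizer of k'Qk - 2 c'k over the
# box-plus-L1-cap feasible set; deterministic given inputs.
solveBoxCapQP <- function(Q, cvec, lambda, k0 = NULL,
                          maxIter = 20000L, kktTol = 1e-8,
                          objTol = 1e-10) {
  r <- length(cvec)
  if (r == 0L) return(list(k = numeric(0), converged = TRUE, iter = 0L))
  L <- 2 * max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  obj <- function(k) as.numeric(t(k) %*% Q %*% k - 2 * sum(cvec * k))
  k <- if (is.null(k0)) projectBoxCap(rep(0, r), lambda) else
    projectBoxCap(k0, lambda)
  y <- k
  tAcc <- 1
  fPrev <- obj(k)
  stall <- 0L
  for (it in seq_len(maxIter)) {
    grad <- 2 * as.numeric(Q %*% y) - 2 * cvec
    kNew <- projectBoxCap(y - grad / L, lambda)
    f <- obj(kNew)
    if (f > fPrev) {  # restart acceleration on objective increase
      y <- k
      tAcc <- 1
      grad <- 2 * as.numeric(Q %*% y) - 2 * cvec
      kNew <- projectBoxCap(y - grad / L, lambda)
      f <- obj(kNew)
    }
    tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    y <- kNew + ((tAcc - 1) / tNew) * (kNew - k)
    k <- kNew
    tAcc <- tNew
    gradK <- 2 * as.numeric(Q %*% k) - 2 * cvec
    kktRes <- max(abs(k - projectBoxCap(k - gradK, lambda)))
    # objective-change stop only after it has stalled repeatedly, so a
    # momentum plateau cannot end the solve early
    stall <- if (abs(fPrev - f) <= max(objTol, 1e-15 * abs(f)))
      stall + 1L else 0L
    if (kktRes <= kktTol || stall >= 25L)
      return(list(k = k, converged = TRUE, iter = it, kkt = kktRes))
    fPrev <- f
  }
  list(k = k, converged = FALSE, iter = maxIter,
       kkt = max(abs(k - projectBoxCap(
         k - (2 * as.numeric(Q %*% k) - 2 * cvec), lambda))))
}

#' Exact integer-quadratic-program model reduction
#'
#' Finds the binary keep/drop vector `k in {0,1}^r` minimizing the
#' moment-matching objective `||A k - b||^2` subject to the cardinality
#' budget `sum(k) <= lambda`, by depth-first branch-and-bound over the
#' quadratic objective (using only A'A and A'b). Each node is bounded by
#' the box-constrained continuous relaxation of its free variables, an
#' admissible lower bound, so the returned solution is a global optimum;
#' branching is lexicographic by reaction index (include-first), which
#' makes the search deterministic.
#'
#' @param moment a [MomentSystem-class].
#' @param lambda cardinality budget (0 <= lambda <= r).
#' @param network the [ReactionNetwork-class] the system was built from
#'   (supplies the reactions for the reduced model).
#' @return a [ReductionResult-class] with binary `kRelaxed`.
#' @export
reduceIQP <- function(moment, lambda, network) {
  r <- length(moment@kEst)
  if (lambda < 0) stop("lambda must be non-negative")
  if (r > 25L)
    stop("exact IQP solve supported up to r = 25 reactions; ",
         "use reduceLasso() for larger networks")
  lambda <- min(lambda, r)
  Q <- moment@AtA; cvec <- moment@Atb; btb <- moment@btb
  objBin <- function(kvec)
    as.numeric(t(kvec) %*% Q %*% kvec - 2 * sum(cvec * kvec) + btb)
  # greedy forward-selection incumbent
  kInc <- rep(0, r)
  for (step in seq_len(lambda)) {
    bestGain <- 0; bestJ <- NA_integer_
    base <- objBin(kInc)
    for (j in which(kInc == 0)) {
      kTry <- kInc; kTry[j] <- 1
      g <- base - objBin(kTry)
      if (g > bestGain + 1e-12) { bestGain <- g; bestJ <- j }
    }
    if (is.na(bestJ)) break
    kInc[bestJ] <- 1
  }
  best <- list(k = kInc, val = objBin(kInc))
  # depth-first branch and bound, include-branch first
  recurse <- function(fixed, depth) {
    usedOnes <- sum(fixed[seq_len(depth - 1L)])
    if (usedOnes > lambda) return(invisible())
    if (depth > r) {
      val <- objBin(fixed)
      if (val < best$val - 1e-12) best <<- list(k = fixed, val = val)
      return(invisible())
    }
    free <- depth:r
    capacity <- lambda - usedOnes
    # admissible bound: continuous relaxation over the free block
    fixedIdx <- seq_len(depth - 1L)
    kFix <- fixed[fixedIdx]
    constTerm <- if (length(fixedIdx))
      as.numeric(t(kFix) %*% Q[fixedIdx, fixedIdx, drop = FALSE] %*% kFix -
                   2 * sum(cvec[fixedIdx] * kFix) + btb) else btb
    cFree <- cvec[free] -
      if (length(fixedIdx))
        as.numeric(Q[free, fixedIdx, drop = FALSE] %*% kFix) else 0
    sol <- solveBoxCapQP(Q[free, free, drop = FALSE], cFree,
                         capacity, maxIter = 2000L, kktTol = 1e-7,
                         objTol = 1e-9)
    bound <- constTerm + as.numeric(
      t(sol$k) %*% Q[free, free, drop = FALSE] %*% sol$k -
        2 * sum(cFree * sol$k))
    if (bound >= best$val - 1e-9) return(invisible())
    for (val in c(1, 0)) {
      fixed[depth] <- val
      recurse(fixed, depth + 1L)
    }
    invisible()
  }
  recurse(rep(0, r), 1L)
  support <- best$k > 0.5
  new("ReductionResult", support = support, kRelaxed = as.numeric(support),
      network = subsetNetwork(network, support),
      objective = best$val, method = "iqp", lambda = as.numeric(lambda))
}

#' Box-constrained LASSO model reduction
#'
#' Convex relaxation of the integer program: minimizes
#' `||A k - b||^2` subject to `k in [0,1]^r` and the L1 budget
#' `sum(k) <= lambda` (the constrained LASSO form with a box), solved by
#' deterministic accelerated projected gradient with exact projection
#' onto the feasible set. Entries below `epsilon` are then thresholded to
#' zero — empirically the relaxed solution phase-separates towards 0/1,
#' making a large threshold safe — and final rates are `k_est * k`, so
#' kept reactions may retain rates below their maximum-likelihood
#' estimates (rare-reaction rates are typically overestimated, never
#' underestimated).
#'
#' @param moment a [MomentSystem-class].
#' @param lambda positive L1 budget.
#' @param network the [ReactionNetwork-class] the system was built from.
#' @param epsilon threshold below which a relaxed rate is set to exactly
#'   zero (default 0.01, i.e. drop reactions whose rate the relaxation
#'   reduced by more than 99%).
#' @param maxIter iteration cap for the solver.
#' @return a [ReductionResult-class]; `kRelaxed` holds the thresholded
#'   relaxed coefficients, `objective` the moment objective at the
#'   (unthresholded) solution.
#' @export
reduceLasso <- function(moment, lambda, network, epsilon = 0.01,
                        maxIter = 50000L) {
  if (lambda <= 0) stop("lambda must be positive")
  sol <- solveBoxCapQP(moment@AtA, moment@Atb, lambda, maxIter = maxIter)
  if (!sol$converged)
    stop("LASSO solver did not converge in ", sol$iter,
         " iterations (KKT residual ", format(sol$kkt, digits = 3),
         "); increase maxIter")
  objective <- momentObjective(moment, sol$k)
  k <- sol$k
  k[k < epsilon] <- 0
  support <- k > 0
  new("ReductionResult", support = support, kRelaxed = k,
      network = subsetNetwork(network, support, scale = k),
      objective = objective, method = "lasso",
      lambda = as.numeric(lambda))
}

#' Reduction sweep over a grid of complexity budgets
#'
#' Runs [reduceIQP()] or [reduceLasso()] at each budget and summarises
#' model size and objective per budget.
#'
#' @param moment a [MomentSystem-class].
#' @param lambdas budgets to sweep.
#' @param network the originating [ReactionNetwork-class].
#' @param method `"iqp"` or `"lasso"`.
#' @param ... passed through to the reducer.
#' @return list with `results` (one [ReductionResult-class] per budget)
#'   and `summary` (data.frame: lambda, size, objective).
#' @export
lambdaSweep <- function(moment, lambdas, network,
                        method = c("lasso", "iqp"), ...) {
  method <- match.arg(method)
  results <- lapply(lambdas, function(l) {
    if (method == "iqp") reduceIQP(moment, l, network, ...)
    else reduceLasso(moment, l, network, ...)
  })
  summary <- data.frame(
    lambda = lambdas,
    size = vapply(results, function(x) sum(x@support), numeric(1)),
    objective = vapply(results, function(x) x@objective, numeric(1)))
  list(results = results, summary = summary)
}

#' @describeIn ReductionResult-class compact summary
#' @param object a ReductionResult
#' @export
setMethod("show", "ReductionResult", function(object) {
  cat("ReductionResult [", object@method, "]: kept ",
      sum(object@support), "/", length(object@support),
      " reactions (lambda = ", object@lambda, ")",
      if (!is.na(object@objective))
        paste0(", objective = ", format(object@objective, digits = 6)),
      "\n", sep = "")
  invisible(object)
})
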