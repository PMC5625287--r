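---
title: "Learning and reducing kinetic Monte Carlo models from bond trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and reducing kinetic Monte Carlo models from bond trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmclearn)
```

## The problem

Reactive atomistic simulations of dense, hot chemistry (pyrolysing
hydrocarbons are the motivating system) produce long trajectories in which
thousands of individual bond-breaking and bond-forming events occur. A
chemist usually wants something far smaller than the trajectory itself: a
*stochastic chemical reaction network* — a list of species, reactions and
rate coefficients — that reproduces the concentration dynamics and can be
simulated onward in milliseconds. `kmclearn` implements that whole chain:

1. **Bond states.** From per-frame coordinates (or pre-computed bond
   lists), two atoms are bonded when their distance is at or below a
   per-element-pair cutoff. The shipped defaults are the radial-
   distribution-function-derived values for hot dense hydrocarbons:
   1.98 Å for C–C, 1.57 Å for C–H and 1.09 Å for H–H.
2. **Bond duration criterion.** The raw bonded/unbonded signal flickers on
   the timescale of atomic vibration. A two-state hysteresis filter
   accepts a change of state only after it has persisted for `tau`
   consecutive frames, in both directions.
3. **Molecules and events.** Molecules are connected components of the
   smoothed bond graph; each maps to a species identified by its element
   counts and bond-type counts. Between consecutive frames, molecules
   unchanged in both atom set and species are ignored; the changed ones
   are linked through shared atoms, and every connected component of that
   bipartite link graph is one reaction event.
4. **Rates.** Under the tau-leaping approximation, per-interval firing
   counts are conditionally independent Poisson variables with mean
   `k_j h_j(X(t)) dt`, where `h_j` is the combinatorial number of
   reactant tuples. The maximum-likelihood estimate is closed form:
   `k_j = sum_t n_j / (dt * sum_t h_j(X(t)))`.
5. **Simulation.** The learned network is simulated exactly with the
   direct-method Gillespie algorithm; by construction it can never fire a
   reaction that was not observed.
6. **Reduction.** Three reducers shrink the learned network: a minimum
   observed-count filter; an exact integer quadratic program (IQP)
   matching the conditional mean and covariance of per-step concentration
   changes under a cardinality budget; and the box-constrained LASSO
   relaxation of that program with epsilon-thresholding.

## Model assumptions

The stochastic model is a chemical master equation for a well-stirred,
fixed-volume system: spatial structure, diffusion and local environment
effects are deliberately projected away. Concentrations are dimensionless
molecule counts in the simulation volume. The tau-leaping observation
model additionally assumes the frame spacing `dt` is short enough that
propensities are constant within a frame and firings do not interact; when
only one reactant tuple exists the Poisson count is really a Bernoulli
one, a known approximation that matters less as means grow. Rates of
rarely possible reactions are estimated from very few informative
intervals and are typically *over*estimates; no shrinkage is applied —
reduction is the mechanism that removes them.

Species identity is deliberately coarse: element counts plus bond-type
counts. Two structural isomers with identical formula and bond-type totals
receive the same label. This mirrors the label dialect of the observable
(a bond graph carries no stereochemistry), and it is a documented
limitation, not an oversight.

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `cutoffs` | bond-length thresholds per element pair | 1.98 (C–C), 1.57 (C–H), 1.09 (H–H) | Å |
| `tau` / `tau_frames` | bond duration criterion | 1 (extraction); pipelines should set it to the frame-count equivalent of ~0.096 ps for MD-scale data | frames |
| `dt` / `frame_dt` | observation interval | trajectory spacing | time |
| `f` (`min_count`) | minimum observed count kept | 1 | counts |
| `lambda` | cardinality / L1 budget of the reducers | none (full size) | reactions |
| `epsilon` | LASSO threshold | 0.01 | dimensionless (scaled rate) |
| `S` (`replicates`) | Gillespie replicates per ensemble | 20 | — |
| `burn_in` | comparison start time for error metrics | 0 | time |

`epsilon = 0.01` works because relaxed solutions phase-separate: entries
finish near 1 or near 0, so thresholding at "the rate was reduced by more
than 99%" is safe. The package flags (but does not fail on) instances
where separation does not occur, since it is an empirical property.

## Choosing the bond duration

`selectBondDuration()` treats `tau` as a model-selection problem: for each
candidate it extracts a network, estimates rates, simulates `S` replicates
and scores the ensemble mean against a *fixed* reference — the source
trajectory's concentrations projected at `referenceTau` (default 1, the
raw counts). Scoring every candidate against the same reference is what
exposes both failure modes: a small `tau` overfits vibrational flicker as
spurious reactions, while a large `tau` suppresses genuine chemistry (in
the limit nothing reacts and the frozen model scores its full drift).
Scoring each candidate against its own `tau`-smoothed projection would
instead make infinite smoothing trivially optimal. Ties prefer the
smaller, less-smoothed `tau`.

## The conditional-moments reduction

For each sampled state, the change in concentrations over one interval is
a linear combination of independent Poisson firing counts, so its
conditional mean is `R diag(k h dt) 1` and its conditional covariance is
`R Lambda R'` with `Lambda = diag(k h dt)`. Both are *linear in the rate
vector*. Stacking the mean rows (m per sample) and the upper-triangular
covariance rows (m(m+1)/2 per sample) over T sampled states gives a tall
linear system `A k ≈ b` with `T (m + m(m+1)/2)` rows. Rates are scaled by
their maximum-likelihood estimates so that `k = 1` reproduces the full
model exactly (`b = A 1` holds to machine precision; the package computes
`b` through the independent moment formulas and verifies the identity in
its tests). Only `A'A` and `A'b` are needed by the optimizers and are
accumulated streaming; the explicit system is kept below 1e5 rows.
`A'A` is symmetrised and repaired to positive semidefiniteness by
clipping eigenvalues above −1e-10 (relative) to zero.

The IQP (`reduceIQP`) minimizes `||A k − b||^2` over binary `k` with
`sum(k) <= lambda`, solved exactly by depth-first branch-and-bound with
the box-constrained continuous relaxation as an admissible node bound,
include-branch first and lexicographic variable order for determinism. It
refuses problems above 25 reactions and points at the LASSO path instead.
The LASSO (`reduceLasso`) solves the convex relaxation `k in [0,1]^r`,
`sum(k) <= lambda` by accelerated projected gradient with an exact
projection onto the box-plus-L1-cap set (bisection on the simplex shift);
step size is `1/L` from the largest eigenvalue of `2 A'A`, with a restart
whenever momentum increases the objective. Iteration stops at a projected-
gradient (KKT) residual of 1e-8 or after the objective change has stayed
below 1e-10 for 25 consecutive iterations; non-convergence is an error
carrying the iterate diagnostics. The budget `lambda` is interpreted in
the constrained form throughout, never as a penalty weight. Thresholding
happens after solving, and final rates are `k_est * k`, so kept reactions
may end with rates *below* their maximum-likelihood estimates — consistent
with rare-reaction rates being overestimated, never underestimated.

Covariance rows are not re-weighted against mean rows; that bias (and the
row-weighting variant that would address it) is out of scope here.

## What the synthetic generator emulates — and what it does not

`generateReactingSystem()` stands in for the reactive simulation: it runs
an exact Gillespie simulation of a known template network while tracking
explicit atoms, rewiring template bonds at every firing, and emits
per-frame bond graphs. `generateBondSignal()` emulates vibrational
flicker as short spurious runs XOR-ed onto a clean step signal;
`generateCountStream()` draws the tau-leaping Poisson counts directly;
`injectSpuriousReactions()` appends atom-balanced decoy reactions with
the overestimated rates a rarely-possible reaction would receive. The
default chemistry is a methane fragment set {CH4, CH3, H, H2, C2H6} with
six reactions (three reversible pairs) and rates
`(0.3, 2.0, 1.0, 0.4, 0.5, 0.3)` chosen once so that, from a few tens of
CH4, every reaction fires repeatedly over a ~100-time-unit horizon while
the mixture visibly evolves.

Passing tests on these fixtures shows the *bookkeeping and estimators*
are right; it does not show that real reactive trajectories satisfy the
assumptions. In particular the generator produces geometrically clean
bonds (its optional coordinate mode places idealized fragment geometries
on a lattice with Gaussian jitter), perfectly Markovian dynamics, and a
closed, well-stirred system — real molecular dynamics has none of these
guarantees exactly.

Three generator subtleties are deliberate design decisions:

* **Flicker placement.** Flickers are Poisson-placed but rejected within
  `flickerMaxLen` frames of a true transition, of another flicker, or of
  the series ends. Without the exclusion zone a flicker adjacent to a
  true transition would merge with it and shift the retroactively stamped
  event time, making the clean signal unrecoverable by *any* filter — the
  generator's recoverability contract would be vacuously false.
* **Composite events.** When two firings share atoms within one frame
  interval, detection necessarily sees their composite (exactly as real
  data sampled at finite resolution would). Exact type recovery therefore
  holds only when firings are isolated per interval; tests verify that
  precondition on their fixtures instead of assuming it.
* **Identifiable decoys.** A spurious candidate whose net stoichiometric
  vector is a positive multiple of a genuine reaction's (e.g. a
  spectator-catalysed copy) is indistinguishable at the level of
  conditional moments, so no reduction method could reject it; such
  candidates are excluded, which keeps the ground-truth mask well
  defined. Spurious rates are calibrated as the MLE that a
  `rateInflation`-count observation would produce
  (`k = rateInflation / (dt sum_t h)`), matching the "rarely possible but
  observed" mechanism that motivates reduction in the first place.

## Numerical conventions and degenerate inputs

* Distance comparisons are boundary-inclusive (`<=` cutoff); the
  minimum-image convention applies only when a periodic box is given.
* The hysteresis filter stamps a confirmed flip retroactively at the
  first frame of the persistent run — the physical event time — keeping
  events aligned with concentration changes. The frame-0 raw state is
  accepted as the initial state (no history exists before the data).
* Event binning uses half-open windows `[t dt, (t+1) dt)`; a boundary
  event belongs to the later window.
* A reaction never possible and never observed has an undefined rate,
  reported as `NA`; possible-but-unobserved rates are exactly 0; observed
  but never possible is an error (the data contradict the model).
* `log(n!)` uses the log-gamma function. A zero-mean interval with a
  positive count makes the log-likelihood `-Inf`, returned flagged rather
  than thrown.
* A frozen system (total propensity 0) advances silently to the horizon
  and is flagged on the trajectory object.
* The SSA inner loop is compiled (Rcpp) and draws from R's RNG, so
  `set.seed()` governs reproducibility; ensembles use `seed + replicate`.

## Problem sizes

The shipped tests and the acceptance study run at desk scale, chosen so
the full suite completes in a few minutes: trajectories of 1e4 frames
from 30 CH4 molecules, ensembles of 20 replicates, moment systems from a
single 161-sample Gillespie path, IQP instances of 10 reactions against
exhaustive enumeration, and 20-instance recovery suites with 6 genuine
plus 6 spurious reactions. The end-to-end check scores the learned model
against the source realization and requires its per-species RMSE to stay
within 3 times the ground-truth model's own noise floor (computed with
the same replicate count and reference; species whose floor is below half
a molecule are held to the half-molecule resolution instead).

## Known limitations

* No isomer resolution beyond bond-type counts, no charge or spin.
* Rates are time-homogeneous; systems whose chemistry drifts (e.g. late
  nucleation of large clusters) need training data covering the regime of
  interest — extrapolation recovers only reactions that were observed.
* The count-based reducer removes all equal-count reactions together;
  its granularity is data-dependent.
* The exact IQP is exponential in the worst case and capped at 25
  reactions; beyond that the LASSO relaxation is the supported path.
* The two inter-model error metrics share a reference-mean convention;
  the per-replicate variant is reported alongside its replicate count so
  the two are never silently interchanged.
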