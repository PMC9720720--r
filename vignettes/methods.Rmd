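---
title: "Asynchronous replica exchange with permanents: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronous replica exchange with permanents: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permex)
```

## The problem

Replica exchange Monte Carlo couples N ensembles so that each one profits
from the exploration done by the others.  The textbook ("cohort") version
advances all replicas in lockstep and swaps neighbours between sweeps; it
implicitly assumes that the CPU-intensive move costs about the same in every
ensemble.  In path sampling that assumption fails badly: a trajectory's
length — and hence the cost of regenerating it — varies by orders of
magnitude between interface ensembles, so lockstep parallelism leaves most
workers idle waiting for the slowest path.

`permex` implements a *noncohort* engine.  K workers (K < N) each run one
CPU-intensive move in one ensemble.  Whenever any worker finishes, its
ensemble is updated and the states of all currently *unoccupied* ensembles
are redistributed; the worker then picks a free ensemble at random and
starts the next move.  Ensembles are updated at irregular intervals and at
different rates, yet each ensemble's marginal distribution is preserved —
the package verifies this empirically on a toy with enumerable marginals
(see below) rather than by formal proof.  Occupied ensembles never
participate in swaps and are never sampled; that restriction is what keeps
the per-ensemble distributions intact.

Two swap modes are provided:

* **finite**: after each move completes, with probability `p_re` a random
  pair of free ensembles attempts a state swap with the usual acceptance
  ratio, repeating geometrically until a uniform draw exceeds `p_re`.
* **infinite**: the limit of infinitely many pair swaps.  All assignments
  of the pooled free states to the free ensembles are sampled *at once*:
  every free ensemble receives every compatible state with a fractional
  weight.  The weights come from a matrix-permanent identity.

## Permanents and the P-matrix

Let `W[i, j]` be proportional to the weight of state `s_i` in ensemble
`e_j` over the free pool.  The probability that the stationary
pair-swapping dynamics leaves state `s_i` in ensemble `e_j` is

    P[i, j] = W[i, j] * perm(W^{ij}) / perm(W),

where `perm` is the matrix permanent and `W^{ij}` removes row i and column
j.  `P` is doubly stochastic: each state goes somewhere, each ensemble gets
something.  The permanent is #P-hard in general; `permex` computes it
exactly with the Balasubramanian–Bax–Franklin–Glynn (BBFG) expansion in
O(2^n · n) using Gray-code updates and long-double accumulation
(`permanent_bbfg()`), after two structural reductions:

1. **Block decomposition** (`block_decompose()`): a bipartite perfect
   matching plus strongly connected components of the matching-directed
   column graph bring `W` to block lower-triangular form; the permanent is
   the product of the diagonal block permanents.
2. **Staircase closed form** (`to_staircase()`, `staircase_permanent()`,
   `staircase_p_matrix()`): when every row is (up to a positive row
   scaling, which provably leaves `P` unchanged) a run of leading ones,
   sorting rows by their count `n_i` gives `perm(W) = prod(n_i + 1 - i)`,
   and `P` fills row-by-row in O(1) amortised work per entry:
   `P[i, j] = (1 - colsum_j) / (n_i - i + 1)` for `j <= n_i`.  This closed
   form was derived for this package and is tested against the
   permanent-ratio definition on hundreds of random staircase matrices;
   that equivalence, not the formula itself, is the binding contract.

Interface path ensembles with indicator-only weights always produce
staircase matrices (membership is nested in rank), so a full `P` for tens
of ensembles costs microseconds; the BBFG route (capped at n = 20 by
default, configurable) only runs for dense weight structures such as
enumerable state densities or high-acceptance weights.

A subtle and easily-missed failure mode is a free pool whose states cannot
be matched to the free ensembles at all (`perm(W) = 0`).  The engine treats
this as corruption and aborts; it cannot occur in a correct run because the
previous assignment is always a witness matching.

## The virtual clock

"Workers" are emulated on a deterministic discrete-event clock: a move's
cost in virtual seconds is reported by the system (for paths: integration
steps × Δt; for the MSVS process: the drawn path duration).  The event loop
is serial, consumes a single R random stream, and is therefore
bit-reproducible per seed — `simulate twice, diff nothing` is a test, not a
hope.  Simultaneous finish times are broken by worker index.  Real
process-level parallelism is out of scope by design: every wall-time
phenomenon of interest (idle workers, skewed update rates, linear MD-time
scaling) is captured by the virtual clock, while results stay exactly
replayable.

## RETIS path ensembles

For interfaces λ₀ < … < λ_M the package builds N = M + 1 ensembles
`[0-], [0+], …, [(M-1)+]`.  A `[k+]` path starts below λ₀, ends below λ₀ or
at/above λ_M, stays inside [λ₀, λ_M) in between, and reaches at least λ_k;
`[0-]` is the mirror image exploring the reactant side.  The structural
conditions are re-checked on every trial path rather than inferred from the
integration legs: a shooting point that happens to sit on a boundary slice
can otherwise produce a "path" that never enters its ensemble's region —
accepting those silently biases path-length averages (we found exactly this
during development; the regression test pins it).

Moves:

* **Shooting** (`shooting_move()`): a uniformly random slice of the old
  path gets a fresh Maxwell–Boltzmann velocity and is integrated backward
  and forward until the start/end conditions terminate the trial;
  acceptance is `indicator(new) * L_old / L_new` with L the slice count.
  Trials longer than 50× the ensemble's running mean length are rejected
  and counted (`rejected_capped`), so users can detect the induced bias if
  it ever becomes non-negligible.
* **Point exchange** (`point_exchange_move()`): the `[0-]` end point is
  integrated forward into a new `[0+]` path and the `[0+]` start point
  backward into a new `[0-]` path.  Both are valid by construction.  The
  move costs dynamics and occupies one worker for *both* ensembles; it is
  offered at worker-assignment time with probability `p_point_exchange`
  (default 0.25) whenever `[0-]` or `[0+]` is picked and the partner is
  free.  Treating it as a scheduled CPU move (rather than an instantaneous
  swap) keeps the virtual-clock accounting honest, since the move is not
  cheap.

Plain path densities are never evaluated: moves report their own weight
ratios, and the engine only needs indicators and the optional
high-acceptance weights w_j (undone in analysis by 1/w reweighting).  The
w_j hook is fully supported and exercised in tests even though no
high-acceptance move generator ships with the package.

## Built-in systems

**MSVS** (`msvs_system()`) is a memoryless single-variable surrogate for a
path simulation: a "path" drawn in ensemble `[k+]` reaches rank k + j with
probability `p_cross^j` (one uniform draw) and takes an exponential
duration with mean `(k+1) * mean_length_scale` seconds.  Defaults —
`n_local = 50`, `p_cross = 0.1`, `mean_length_scale = 0.1` — make the exact
overall crossing probability `0.1^50 = 1e-50` and the move cost grow
linearly with rank.  Two conventions are fixed deliberately: the ensembles
are `[0+] … [49+]` with no `[0-]` (so exactly 50 local probabilities
multiply to the exact value, and no flux is defined), and the duration mean
is `(k+1)/10` rather than `k/10` so the lowest ensemble has nonzero-length
moves; the offset touches no probability.

**Langevin double well** (`langevin_double_well()`): a particle in
`V(x) = barrier * (x^2 - 1)^2` under underdamped Langevin dynamics, BAOAB
splitting (compiled, drawing from R's RNG stream).  Defaults
`barrier = 3, temperature = 1` (βΔV = 3), `gamma = 0.5`, `dt = 0.02`,
`mass = 1`, interfaces at (-0.75, -0.45, -0.15, 0.15, 0.6).  These are the
package's own documented parameters, chosen so that a low barrier gives
converged crossing statistics in minutes; all double-well checks are
therefore *self-consistency* properties (interface-sampling rate versus
brute-force dynamics on the same potential), not literature-value
reproductions.  The order parameter is the coordinate itself and crossings
are detected between consecutive slices without interpolation.

**Discrete toy** (`discrete_toy()`): m ≤ 6 states, one enumerable weight
row per ensemble, independence-sampler standard moves, heterogeneous
exponential move durations.  Exact marginals are the normalised rows, which
turns "the asynchronous engine preserves each ensemble's distribution" —
the method's central correctness claim — into a direct empirical test in
both modes, at K ∈ {1, 2}, with `p_re` ∈ {0, 0.5, 0.9} and infinite
swapping.

## Analysis

Estimators average over recorded events, not virtual time; occupied
ensembles contribute nothing between their events, mirroring the sampling
rule.  For ensemble `[k+]` the local conditional crossing probability is
`sum(w * (1/w_j) * crossed) / sum(w * (1/w_j))` over the post-burn-in
stream; the overall crossing probability is the product of the locals, the
flux is `1 / (mean duration [0-] + mean duration [0+])`, and
`rate = flux * P_cross`.  Relative errors come from weighted blocking
(default 10 blocks) and combine as `eps^2 = sum(eps_i^2)`; this neglects
inter-ensemble correlation induced by swapping and is reported as a
diagnostic, not a confidence interval.  Efficiency is `1 / (T * eps^2)`
with T either virtual wall-time or summed worker busy time.

Defaults that matter: burn-in 10% of the record stream (the engine's
initial paths are artificial ramps; they wash out within a few moves per
ensemble, and the discarded fraction is deliberately generous), 10 blocks,
chunked accumulation sized to ~2000 chunks per run.  The flux estimator's
endpoint convention (each path carries two boundary slices; duration is
slice count minus one times Δt) follows common interface-sampling practice
and is an assumption of this package, validated against brute-force
excursion statistics in the tests.

The brute-force rate reference (`direct_rate()`) counts A→B first passages
per unit A-residence time on one long trajectory with a history indicator
(in A after dropping below λ₀, in B after reaching λ_M).  This is exactly
the observable `flux × P_cross` estimates; the commonly quoted inverse
mean-first-passage time is kept as a secondary method but differs
systematically at low barriers (≈35% here), which is why it is not the
default comparison.

## What the tests do and do not show

The test suite checks, among others: BBFG versus minor-expansion permanents
(500 random matrices), staircase closed forms versus the permanent-ratio
definition (200 random specs to n = 12), bistochasticity and row-scaling
invariance of every emitted P-matrix, exact toy marginals in every mode at
10⁵ events, the MSVS overall crossing probability within 50% of 10⁻⁵⁰
(K = 15, 6·10⁵ events, about 12·10³ moves per ensemble), per-ensemble MSVS
estimates at 0.1 within 4 standard errors, the double-well rate within 3σ
of brute-force dynamics (3·10⁴ moves against 2·10⁷ MD steps), linear
MD-time scaling in K (R² > 0.99) and a superlinear move count.  Problem
sizes were chosen so the full suite runs in minutes on one core.

The built-in systems are deliberately low-dimensional.  They exercise every
code path of the engine — unequal and stochastic move costs, nested and
dense weight matrices, reactant-side point exchange — but they cannot
reveal effects that only appear in rough high-dimensional landscapes, such
as the loss of ergodicity when swap rates collapse near K ≈ N, or
correlation structure between path ensembles of a real molecular system.
Passing tests therefore validate the sampling machinery, not any claim
about a particular molecular application.

## Known limitations

* Permanent evaluation is exact only; no Monte-Carlo permanent estimators,
  and the BBFG cap (default n = 20) refuses rather than approximates.
* One R-level process; "workers" are bookkeeping, and wall-time claims are
  virtual-clock claims.
* The error combination ignores swap-induced correlations between
  ensembles; block errors within one ensemble handle autocorrelation in
  its own stream only.
* High-acceptance move generators (the reason the w_j hook exists) are not
  included.
* Trial-length capping introduces a small, flagged bias when paths near
  the cap occur; with the shipped systems the counter stays at zero in
  practice.
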