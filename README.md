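# permex

Asynchronous ("noncohort") replica-exchange Monte Carlo with infinite
swapping computed exactly through matrix permanents, applied to replica
exchange transition interface sampling (RETIS) for rare-event rate
calculations.

## The problem

Replica exchange parallelizes Monte Carlo across N coupled ensembles, but
the standard cohort scheme advances all replicas in lockstep, so every
worker waits for the slowest move.  In path sampling the cost of one move
is the length of the trajectory being regenerated, which varies enormously
between interface ensembles — lockstep parallelism wastes most of the
machine.  `permex` implements the asynchronous alternative: K < N workers
each run one CPU-intensive move; the moment any worker finishes, states are
exchanged among the currently *unoccupied* ensembles only, and the worker
moves on to a random free ensemble.  Updates arrive at irregular intervals
and at different per-ensemble rates, yet every ensemble's marginal
distribution is preserved.

Swaps come in two flavours.  Finite mode attempts random free pairs with
the usual Metropolis ratio, a geometric number of times (probability
`p_re` per attempt).  Infinite mode takes the limit of infinitely many
swaps in one shot: with `W[i, j]` the weight of free state `s_i` in free
ensemble `e_j`, every state is assigned to every ensemble with fractional
probability

    P[i, j] = W[i, j] * perm(W^{ij}) / perm(W),

a doubly stochastic matrix of matrix permanents (`W^{ij}` drops row i and
column j).  Permanents are evaluated exactly by the
Balasubramanian–Bax–Franklin–Glynn formula in O(2^n · n), after block
decomposition, and — for the nested 0/1 weight matrices that interface
ensembles produce — by a polynomial staircase closed form
(`perm(W) = prod(n_i + 1 - i)` over sorted leading-one counts), so infinite
swapping over dozens of ensembles costs microseconds per event.

For RETIS the engine computes the rate constant as flux through the first
interface times the overall crossing probability, the latter being the
product of per-interface conditional crossing probabilities with blocked
error estimates.

Everything runs on a deterministic discrete-event *virtual clock* — worker
parallelism is emulated, runs are bit-reproducible per seed, and a move's
cost is its virtual duration (integration steps × Δt, or the drawn path
length for the built-in stochastic toy).

## Worked example

The MSVS process is a built-in stochastic surrogate for a path simulation:
each "path" in ensemble `[k+]` crosses the next interface with probability
0.1 and costs (k+1)/10 virtual seconds, so the exact overall crossing
probability with 10 ensembles is 1e-10.

```r
library(permex)
sys <- msvs_system(msvs_params(n_local = 10L))
run <- run_scheduler(sys, scheduler_config(4L, "infinite",
                                           stop_moves = 40000L, seed = 11))
print(run)
#> <permex_run> msvs: N = 10 ensembles, K = 4 workers, infinite mode
#>   events: 40000   virtual clock: 4.91e+03 s   worker busy time: 1.96e+04 s

ca <- crossing_analysis(run)
head(ca$local, 4)
#>   ensemble rank p_local rel_err  mass
#> 1     [0+]    0  0.1022  0.0381 33327
#> 2     [1+]    1  0.1023  0.0507 29083   # etc.
ca$p_cross
#> 7.25e-11      # exact value 1e-10; blocked rel. err 0.19
```

Each row is one interface ensemble: `p_local` estimates the 0.1
conditional crossing probability from the fractionally weighted sample
stream, `mass` is the accumulated record weight, and the product of the
locals estimates the 1e-10 overall crossing probability.  Four workers
consumed 1.96e4 virtual CPU-seconds in 4.91e3 virtual wall-seconds — the
4× speedup with zero idle time that lockstep replica exchange cannot
deliver when move costs differ tenfold across ensembles.

For a dynamical system, `langevin_double_well()` gives an underdamped
Langevin particle in a quartic double well; `flux_and_rate(run)` returns
flux, crossing probability and the rate, which the test suite checks
against brute-force long-trajectory dynamics (`direct_rate()`).

A thin command-line wrapper is installed with the package
(`inst/cli/permex`): `permex run --config cfg.yaml --seed 1 --out dir`,
`permex analyze --run-dir dir`, `permex selftest`, with YAML configs
validated against the documented schema.

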