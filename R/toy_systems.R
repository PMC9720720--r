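# Built-in model systems.
#
# A "system" is a plain list contract consumed by the scheduler:
#   $name          label
#   $ensembles     list of ensemble_def, in rank order
#   $initial_states()            one valid state per ensemble (deterministic)
#   $propose(state, ens)         list(proposal = move_proposal, duration)
#   $crossed_next(state, ens)    0/1: does the state cross the ensemble's
#                                next interface (rate analysis)
#   $state_index(state)          optional small integer for marginal tallies
#   $point_exchange(s0m, s0p)    optional reactant-side point exchange
# States are lists carrying at least $duration (virtual seconds).

#' Parameters of the memoryless single-variable stochastic (MSVS) process
#'
#' The MSVS process mimics an interface-sampling simulation in which the
#' average path length grows linearly with the ensemble's rank: a "path"
#' generated in ensemble `[k+]` crosses the next interface with probability
#' `p_cross` (each further interface again with `p_cross`, a geometric
#' tail), and takes `(k+1) * mean_length_scale` virtual seconds on average.
#' With the defaults the exact overall crossing probability is
#' `p_cross^n_local` = 1e-50.
#'
#' @param n_local number of local crossing probabilities (ensembles).
#' @param p_cross per-interface crossing probability.
#' @param mean_length_scale virtual seconds per unit rank.
#' @return A list of class `msvs_params`.
#' @export
msvs_params <- function(n_local = 50L, p_cross = 0.1, mean_length_scale = 0.1) {
  stopifnot(n_local >= 1L, p_cross > 0, p_cross < 1, mean_length_scale > 0)
  structure(list(n_local = as.integer(n_local), p_cross = p_cross,
                 mean_length_scale = mean_length_scale),
            class = "msvs_params")
}

#' Draw one MSVS path at a given ensemble rank
#'
#' Two random numbers define the path: one uniform determines the progress
#' (the path reaches rank `k + j` with probability `p_cross^j`, capped at
#' `n_local`), one exponential determines the duration, with mean
#' `(k + 1) * mean_length_scale` seconds.  Every draw is a valid `[k+]`
#' path, so MSVS standard moves are always accepted.
#'
#' @param k ensemble rank, `0 <= k < n_local`.
#' @param params an [msvs_params()] object.
#' @return A state list with fields `r` (maximum rank reached) and
#'   `duration`.
#' @export
msvs_draw_path <- function(k, params) {
  stopifnot(k >= 0L, k < params$n_local)
  u <- stats::runif(1)
  j <- floor(log(u) / log(params$p_cross))
  r <- min(k + j, params$n_local)
  duration <- stats::rexp(1, rate = 1 / ((k + 1) * params$mean_length_scale))
  list(r = as.integer(r), duration = duration)
}

#' The MSVS system
#'
#' Builds the scheduler-ready system: ensembles `[0+] ... [(n_local-1)+]`
#' over interfaces 0..n_local (there is no reactant-side `[0-]` ensemble, so
#' no flux is defined; the observable is the overall crossing probability).
#'
#' @param params an [msvs_params()] object.
#' @return A system list (see package internals) with `$ensembles` of length
#'   `n_local`.
#' @export
msvs_system <- function(params = msvs_params()) {
  n <- params$n_local
  ensembles <- lapply(seq_len(n) - 1L, function(k) {
    force(k)
    ensemble_def(id = sprintf("[%d+]", k), rank = k,
                 indicator = function(state) as.integer(state$r >= k))
  })
  list(
    name = "msvs",
    params = params,
    ensembles = ensembles,
    nested = TRUE,   # memberships are nested in rank: staircase fast path
    initial_states = function() {
      lapply(seq_len(n) - 1L, function(k)
        list(r = k, duration = (k + 1) * params$mean_length_scale))
    },
    propose = function(state, ens) {
      new <- msvs_draw_path(ens$rank, params)
      list(proposal = move_proposal(state, new, 1, 1, weight_ratio = 1),
           duration = new$duration)
    },
    crossed_next = function(state, ens) as.integer(state$r >= ens$rank + 1L),
    cross_value = function(state) state$r,
    cross_thresholds = seq_len(n),    # [k+] crosses next iff r >= k + 1
    w_matrix_entries = function(pool, ens) {
      r <- vapply(pool, function(s) s$r, 1L)
      rk <- vapply(ens, function(e) e$rank, 1L)
      outer(r, rk, ">=") + 0
    },
    state_index = NULL,
    point_exchange = NULL
  )
}

#' A discrete validation toy with enumerable exact marginals
#'
#' `m` states and a weight table define one enumerable density per
#' ensemble; the standard move proposes independently from a fixed
#' distribution and applies Metropolis-Hastings acceptance, and move
#' durations are drawn from heterogeneous per-ensemble exponential
#' distributions.  Exact per-ensemble marginals are the normalised weight
#' rows, which makes the toy a direct empirical check that the asynchronous
#' engine samples every ensemble's distribution (standing in for a formal
#' detailed-balance proof).
#'
#' @param weights numeric matrix, one row per ensemble, one column per
#'   state; entries >= 0, each row with at least one positive entry.
#' @param proposal probability vector over states for the independence
#'   sampler (default uniform).
#' @param duration_means positive vector of per-ensemble mean move
#'   durations (default `1, 2, ..., n_ens`, deliberately heterogeneous).
#' @return A system list with `$ensembles`, `$exact_marginals` (matrix of
#'   normalised rows) and a `$state_index` accessor for marginal tallies.
#' @export
discrete_toy <- function(weights = rbind(c(1, 2, 3, 4),
                                         c(4, 3, 2, 1),
                                         c(1, 1, 1, 1)),
                         proposal = NULL,
                         duration_means = NULL) {
  weights <- as.matrix(weights)
  m <- ncol(weights); n_ens <- nrow(weights)
  stopifnot(m >= 1L, m <= 6L, all(weights >= 0), all(rowSums(weights) > 0))
  if (is.null(proposal)) proposal <- rep(1 / m, m)
  stopifnot(length(proposal) == m, all(proposal > 0))
  proposal <- proposal / sum(proposal)
  if (is.null(duration_means)) duration_means <- seq_len(n_ens)
  stopifnot(length(duration_means) == n_ens, all(duration_means > 0))

  ensembles <- lapply(seq_len(n_ens), function(j) {
    force(j)
    ensemble_def(id = sprintf("ens%d", j), rank = j - 1L,
                 indicator = function(state) as.integer(weights[j, state$k] > 0),
                 density = function(state) weights[j, state$k])
  })
  # an initial state valid in every ensemble exists when some column is
  # positive everywhere; otherwise match each ensemble to its best state
  init_k <- vapply(seq_len(n_ens), function(j) which.max(weights[j, ]), 1L)
  list(
    name = "discrete_toy",
    ensembles = ensembles,
    n_states = m,
    exact_marginals = weights / rowSums(weights),
    initial_states = function() {
      lapply(seq_len(n_ens), function(j)
        list(k = init_k[j], duration = duration_means[j]))
    },
    propose = function(state, ens) {
      j <- ens$rank + 1L
      knew <- sample.int(m, 1L, prob = proposal)
      wr <- if (weights[j, state$k] > 0) weights[j, knew] / weights[j, state$k] else
        stop_permex("incumbent has zero weight in its ensemble", "permex_state_error")
      dur <- stats::rexp(1, rate = 1 / duration_means[j])
      new <- list(k = knew, duration = dur)
      list(proposal = move_proposal(state, new,
                                    gen_forward = proposal[knew],
                                    gen_backward = proposal[state$k],
                                    weight_ratio = wr),
           duration = dur)
    },
    crossed_next = function(state, ens) 0L,
    cross_value = NULL,
    cross_thresholds = rep(Inf, n_ens),
    w_matrix_entries = function(pool, ens) {
      ks <- vapply(pool, function(s) s$k, 1L)
      js <- vapply(ens, function(e) e$rank, 1L) + 1L
      t(weights[js, ks, drop = FALSE])
    },
    state_index = function(state) state$k,
    point_exchange = NULL
  )
}
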