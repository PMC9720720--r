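# RETIS path-ensemble machinery: interfaces, path validity, W-matrix
# assembly, shooting and point-exchange moves.
#
# Paths are lists:
#   $x, $v        slice coordinates/velocities (absent for abstract states)
#   $lambda_max   maximum order parameter reached
#   $kind         "plus" (starts by crossing lambda_0 upward) or "minus"
#                 (explores the reactant side of lambda_0)
#   $valid        structural start/end conditions satisfied
#   $duration     virtual seconds of dynamics spent creating the path
# The order parameter of the built-in systems is the first coordinate;
# crossings are detected between consecutive slices, without interpolation.

#' An ordered set of interfaces
#'
#' @param lambdas strictly increasing order-parameter values
#'   `lambda_0 < ... < lambda_M`, `M >= 1`.
#' @return Object of class `interface_set`.
#' @export
interface_set <- function(lambdas) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2L || is.unsorted(lambdas, strictly = TRUE))
    stop_permex("interfaces must be strictly increasing with M >= 1",
                "permex_contract_error")
  structure(list(lambdas = lambdas, M = length(lambdas) - 1L),
            class = "interface_set")
}

#' Build the RETIS path-ensemble set for an interface set
#'
#' With `M + 1` interfaces there are `N = M + 1` ensembles:
#' `[0-], [0+], [1+], ..., [(M-1)+]`.  `[k+]` paths start by crossing
#' `lambda_0` from below, end by crossing `lambda_0` again or reaching
#' `lambda_M`, and reach at least `lambda_k`; `[0-]` paths explore the
#' reactant side of `lambda_0`.
#'
#' @param interfaces an [interface_set()].
#' @param ha_weight optional high-acceptance weight function(path) shared by
#'   the `[k+]` ensembles (default constant 1).
#' @return List of [ensemble_def()]s in rank order (`[0-]` first).
#' @export
path_ensembles <- function(interfaces, ha_weight = NULL) {
  lam <- interfaces$lambdas
  ens <- list(ensemble_def(
    id = "[0-]", rank = -1L,
    indicator = function(path)
      as.integer(isTRUE(path$valid) && path$kind == "minus")))
  for (k in seq_len(interfaces$M) - 1L) {
    local({
      kk <- k; lk <- lam[kk + 1L]
      ens[[length(ens) + 1L]] <<- ensemble_def(
        id = sprintf("[%d+]", kk), rank = kk,
        indicator = function(path)
          as.integer(isTRUE(path$valid) && path$kind == "plus" &&
                     path$lambda_max >= lk),
        ha_weight = ha_weight)
    })
  }
  ens
}

#' Path-ensemble membership indicator
#'
#' 1 iff the path satisfies the ensemble's start/end/crossing conditions.
#' Membership is monotone in rank: a path in `[k+]` is in every `[j+]`,
#' `j <= k`, and `[0-]` membership excludes every `[k+]`.
#'
#' @param path a path state.
#' @param ensemble an [ensemble_def()].
#' @return 0 or 1.
#' @export
path_indicator <- function(path, ensemble) ensemble$indicator(path)

#' Assemble the weight matrix of the free pool
#'
#' `W[i, j] = indicator_j(s_i) * w_j(s_i)` (or the ensemble's enumerable
#' density when one is supplied) over free states (rows) and free ensembles
#' (columns).  Columns are ordered by ensemble rank (`[0-]` first when
#' free); rows are ordered by the number of trailing zeros, descending, so
#' that nested interface-crossing membership yields a staircase (and a free
#' `[0-]` splits off as a 1 x 1 block).
#'
#' @param pool list of states.
#' @param ensembles list of [ensemble_def()]s, `length(pool) ==
#'   length(ensembles)`.
#' @param builder optional vectorised entry builder `function(pool, ens)`
#'   returning the matrix of weights (pool order x given ensemble order);
#'   defaults to elementwise evaluation of the ensemble weights.
#' @return List with `W` (the reordered matrix), `rows` (pool index per
#'   row), `ens` (ensemble list in column order), `col_of` (column per input
#'   ensemble index).
#' @export
build_w_matrix <- function(pool, ensembles, builder = NULL) {
  n <- length(pool)
  if (length(ensembles) != n)
    stop_permex("pool and free-ensemble counts differ", "permex_contract_error")
  rank_ord <- order(vapply(ensembles, function(e) e$rank, 1L))
  ens <- ensembles[rank_ord]
  if (!is.null(builder)) {
    W <- builder(pool, ens)
  } else {
    W <- matrix(0, n, n)
    for (j in seq_len(n)) for (i in seq_len(n))
      W[i, j] <- ens_weight(ens[[j]], pool[[i]])
  }
  trailing <- apply(W, 1L, function(row) {
    nz <- which(row != 0)
    if (length(nz) == 0L) n else n - max(nz)
  })
  row_ord <- order(-trailing)  # most trailing zeros first; stable
  col_of <- integer(n); col_of[rank_ord] <- seq_len(n)
  list(W = W[row_ord, , drop = FALSE], rows = row_ord, ens = ens,
       col_of = col_of)
}

# ---------------------------------------------------------------------------
# Path construction helpers (dynamical systems)
# ---------------------------------------------------------------------------

# internal: structural validity of a path's slice sequence.  A "plus" path
# starts below lambda_0, ends below lambda_0 or at/above lambda_M, and has
# all interior slices in [lambda_0, lambda_M); a "minus" path starts and
# ends at/above lambda_0 with all interior slices below it.  Trials whose
# shooting point sat on a boundary slice can violate these conditions even
# though each integration leg terminated correctly, so the assembled path
# is always re-checked.
plus_path_valid <- function(x, lam0, lamM) {
  n <- length(x)
  n >= 3L && x[1L] < lam0 && (x[n] < lam0 || x[n] >= lamM) &&
    all(x[2:(n - 1L)] >= lam0) && all(x[2:(n - 1L)] < lamM)
}
minus_path_valid <- function(x, lam0) {
  n <- length(x)
  n >= 3L && x[1L] >= lam0 && x[n] >= lam0 && all(x[2:(n - 1L)] < lam0)
}

# internal: assemble a "plus" path from backward/forward integration pieces
# around a shooting point.  bw/fw are lists with $x, $v from
# cpp_integrate_until (bw integrated with flipped velocity).
make_plus_path <- function(bw, fw, lam0, lamM, dt) {
  x <- c(rev(bw$x[-1L]), fw$x)
  v <- c(-rev(bw$v[-1L]), fw$v)
  nsl <- length(x)
  valid <- bw$status == 0L && fw$status != 2L && plus_path_valid(x, lam0, lamM)
  list(x = x, v = v, kind = "plus", valid = valid,
       lambda_max = max(x), L = nsl - 1L, duration = (nsl - 1L) * dt)
}

make_minus_path <- function(bw, fw, lam0, dt) {
  x <- c(rev(bw$x[-1L]), fw$x)
  v <- c(-rev(bw$v[-1L]), fw$v)
  nsl <- length(x)
  valid <- bw$status == 1L && fw$status == 1L && minus_path_valid(x, lam0)
  list(x = x, v = v, kind = "minus", valid = valid,
       lambda_max = max(x), L = nsl - 1L, duration = (nsl - 1L) * dt)
}

#' Shooting move on a path
#'
#' Selects a uniformly random time slice of the old path, redraws its
#' velocity from the Maxwell-Boltzmann distribution at the dynamics
#' temperature, and integrates backward and forward in time until the
#' ensemble's start/end conditions terminate the trial.  The proposal
#' carries `weight_ratio = indicator(new) * L_old / L_new` (slice-count
#' ratio of the uniform slice selection); a trial violating the ensemble's
#' criteria, or exceeding `max_slices`, is always rejected.
#'
#' @param path the incumbent path.
#' @param ensemble target [ensemble_def()].
#' @param dyn dynamics description: list with `params` (a
#'   [langevin_params()]) and `lambdas` (interface positions).
#' @param max_slices trial-length cap in slices; longer trials count as
#'   rejections (flagged via `capped`).
#' @return List with `proposal` (a [move_proposal()]), `duration` (virtual
#'   seconds of integration actually performed) and `capped`.
#' @export
shooting_move <- function(path, ensemble, dyn, max_slices = Inf) {
  p <- dyn$params; lam <- dyn$lambdas
  lam0 <- lam[1L]; lamM <- lam[length(lam)]
  nsl <- length(path$x)
  idx <- sample.int(nsl, 1L)
  xs <- path$x[idx]
  vs <- stats::rnorm(1L, 0, sqrt(p$temperature / p$mass))
  cap <- if (is.finite(max_slices)) as.integer(max_slices) else 1000000L
  if (ensemble$rank >= 0L) {
    bw <- cpp_integrate_until(xs, -vs, 0L, p$barrier, p$gamma, p$temperature,
                              p$dt, p$mass, lam0, lamM, cap)
    fw <- cpp_integrate_until(xs, vs, 0L, p$barrier, p$gamma, p$temperature,
                              p$dt, p$mass, lam0, lamM, cap)
    new <- make_plus_path(bw, fw, lam0, lamM, p$dt)
  } else {
    bw <- cpp_integrate_until(xs, -vs, 0L, p$barrier, p$gamma, p$temperature,
                              p$dt, p$mass, -Inf, lam0, cap)
    fw <- cpp_integrate_until(xs, vs, 0L, p$barrier, p$gamma, p$temperature,
                              p$dt, p$mass, -Inf, lam0, cap)
    new <- make_minus_path(bw, fw, lam0, p$dt)
  }
  capped <- bw$status == 2L || fw$status == 2L || length(new$x) > max_slices
  ind <- if (capped) 0L else path_indicator(new, ensemble)
  wr <- if (ind == 0L) 0 else (nsl / length(new$x))
  dur <- (length(bw$x) + length(fw$x) - 2L) * p$dt
  list(proposal = move_proposal(path, new, 1, 1, weight_ratio = wr),
       duration = max(dur, p$dt), capped = capped)
}

#' Point-exchange move between the `[0-]` and `[0+]` ensembles
#'
#' The end point of the `[0-]` path seeds a new `[0+]` path integrated
#' forward until it returns below `lambda_0` or reaches `lambda_M`; the
#' start point of the `[0+]` path seeds a new `[0-]` path integrated
#' backward into the reactant well.  Both trials satisfy their target
#' ensemble's conditions by construction, so the move is accepted whenever
#' neither integration exceeds the step cap.  Applies to dynamical systems
#' only (the MSVS process has no `[0-]` ensemble).
#'
#' @param p0m,p0p incumbent `[0-]` and `[0+]` paths.
#' @param dyn dynamics description as in [shooting_move()].
#' @param max_slices trial-length cap per direction.
#' @return List with `new0m`, `new0p`, `duration`, `accepted`.
#' @export
point_exchange_move <- function(p0m, p0p, dyn, max_slices = Inf) {
  p <- dyn$params; lam <- dyn$lambdas
  lam0 <- lam[1L]; lamM <- lam[length(lam)]
  cap <- if (is.finite(max_slices)) as.integer(max_slices) else 1000000L
  n0m <- length(p0m$x); n0p <- length(p0p$x)
  # forward continuation of [0-]'s end point: new [0+] path; its first slice
  # is [0-]'s penultimate slice (below lambda_0)
  fw <- cpp_integrate_until(p0m$x[n0m], p0m$v[n0m], 0L, p$barrier, p$gamma,
                            p$temperature, p$dt, p$mass, lam0, lamM, cap)
  x_p <- c(p0m$x[n0m - 1L], fw$x); v_p <- c(p0m$v[n0m - 1L], fw$v)
  new0p <- list(x = x_p, v = v_p, kind = "plus",
                valid = fw$status != 2L && plus_path_valid(x_p, lam0, lamM),
                lambda_max = max(x_p),
                L = length(x_p) - 1L, duration = (length(x_p) - 1L) * p$dt)
  # backward continuation of [0+]'s start point: new [0-] path; its last
  # slice is [0+]'s second slice (at or above lambda_0)
  bw <- cpp_integrate_until(p0p$x[1L], -p0p$v[1L], 0L, p$barrier, p$gamma,
                            p$temperature, p$dt, p$mass, -Inf, lam0, cap)
  x_m <- c(rev(bw$x), p0p$x[2L]); v_m <- c(-rev(bw$v), p0p$v[2L])
  new0m <- list(x = x_m, v = v_m, kind = "minus",
                valid = bw$status == 1L && minus_path_valid(x_m, lam0),
                lambda_max = max(x_m),
                L = length(x_m) - 1L, duration = (length(x_m) - 1L) * p$dt)
  accepted <- isTRUE(new0p$valid) && isTRUE(new0m$valid) &&
    length(x_p) <= max_slices && length(x_m) <= max_slices
  dur <- (length(fw$x) + length(bw$x) - 1L) * p$dt
  list(new0m = new0m, new0p = new0p, duration = max(dur, p$dt),
       accepted = accepted)
}

#' Deterministic initial paths for a system
#'
#' Builds one valid path per ensemble.  For the MSVS process the state of
#' rank k trivially seeds `[k+]`.  For dynamical systems, artificial ramp
#' paths are synthesised: a `[k+]` seed rises linearly from just below
#' `lambda_0` to just above `lambda_k` and returns; the `[0-]` seed dips
#' into the reactant well.  Velocities are finite-difference consistent.
#' The ramps satisfy every start/end/crossing condition by construction and
#' are replaced by genuine dynamics within the discarded burn-in.
#'
#' @param system a system list.
#' @param ensembles its ensembles (defaults to `system$ensembles`).
#' @return List of valid states, one per ensemble; errors if any seed fails
#'   its own indicator.
#' @export
initialize_states <- function(system, ensembles = system$ensembles) {
  states <- system$initial_states()
  ok <- vapply(seq_along(ensembles), function(i)
    ensembles[[i]]$indicator(states[[i]]) == 1L, TRUE)
  if (!all(ok))
    stop_permex(sprintf("initial state invalid in ensemble %s",
                        paste(vapply(ensembles[!ok], function(e) e$id, ""),
                              collapse = ", ")),
                "permex_init_error")
  states
}

# internal: ramp path used by dynamical systems' initial_states
ramp_path <- function(lam0, target, dt, kind = c("plus", "minus"),
                      n_half = 12L) {
  kind <- match.arg(kind)
  eps <- 1e-3 * max(abs(target - lam0), 1e-3)
  if (kind == "plus") {
    up <- seq(lam0 - eps, target + eps, length.out = n_half)
    x <- c(up, rev(up)[-1L])
  } else {
    dn <- seq(lam0 + eps, target - eps, length.out = n_half)
    x <- c(dn, rev(dn)[-1L])
  }
  v <- c(diff(x) / dt, 0)
  list(x = x, v = v, kind = kind, valid = TRUE, lambda_max = max(x),
       L = length(x) - 1L, duration = (length(x) - 1L) * dt)
}
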