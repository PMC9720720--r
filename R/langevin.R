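# Underdamped Langevin dynamics and the double-well model system.

#' Parameters of the underdamped Langevin double well
#'
#' The potential is the quartic double well `V(x) = barrier * (x^2 - 1)^2`
#' with minima at x = -1 and x = +1 and barrier height `barrier` at x = 0.
#' Dynamics are integrated with the BAOAB splitting.  Defaults give a low
#' barrier (`barrier / temperature = 3`) so that crossing statistics
#' converge in modest simulations.
#'
#' @param barrier barrier height (energy units; `k_B T` = `temperature`).
#' @param gamma friction coefficient (1/time).
#' @param temperature `k_B T` (energy units).
#' @param dt integration timestep.
#' @param mass particle mass.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(barrier = 3, gamma = 0.5, temperature = 1,
                            dt = 0.02, mass = 1) {
  stopifnot(barrier > 0, gamma > 0, temperature > 0, dt > 0, mass > 0)
  structure(list(barrier = barrier, gamma = gamma, temperature = temperature,
                 dt = dt, mass = mass), class = "langevin_params")
}

#' One BAOAB Langevin step
#'
#' @param state list with `x` and `v`.
#' @param params a [langevin_params()].
#' @param potential `"double_well"` (`V = barrier*(x^2-1)^2`) or
#'   `"harmonic"` (`V = 0.5*barrier*x^2`, for validation against the exact
#'   Gaussian stationary distribution).
#' @return Updated state list.
#' @export
langevin_step <- function(state, params, potential = c("double_well", "harmonic")) {
  potential <- match.arg(potential)
  pot <- if (potential == "double_well") 0L else 1L
  out <- cpp_baoab_run(state$x, state$v, 1L, pot, params$barrier,
                       params$gamma, params$temperature, params$dt,
                       params$mass, 1L)
  if (!all(is.finite(out[2L, ])))
    stop_permex("non-finite state after integration step", "permex_integration_error")
  list(x = out[2L, 1L], v = out[2L, 2L])
}

#' Simulate an underdamped Langevin trajectory
#'
#' Bulk driver around the compiled BAOAB integrator; draws from the
#' engine's R random stream.
#'
#' @inheritParams langevin_step
#' @param n_steps number of steps.
#' @param thin keep every `thin`-th slice.
#' @return Matrix with columns x, v (first row = initial state).
#' @export
langevin_trajectory <- function(state, params, n_steps,
                                potential = c("double_well", "harmonic"),
                                thin = 1L) {
  potential <- match.arg(potential)
  pot <- if (potential == "double_well") 0L else 1L
  cpp_baoab_run(state$x, state$v, as.integer(n_steps), pot, params$barrier,
                params$gamma, params$temperature, params$dt, params$mass,
                as.integer(thin))
}

#' The Langevin double-well system
#'
#' Builds the scheduler-ready system over a RETIS path-ensemble set.  The
#' order parameter is the coordinate x; interfaces default to five values
#' spanning the barrier from the reactant well (x near -1) to the product
#' side.  Standard moves are shooting moves; the `[0-]`/`[0+]`
#' point-exchange move is available to the scheduler.
#'
#' @param params a [langevin_params()].
#' @param lambdas interface positions (strictly increasing).
#' @param max_slice_factor trial paths longer than this multiple of the
#'   ensemble's running mean length are rejected (flagged in the run
#'   counters).
#' @return A system list with `N = length(lambdas)` ensembles
#'   (`[0-], [0+], ..., [(M-1)+]`).
#' @export
langevin_double_well <- function(params = langevin_params(),
                                 lambdas = c(-0.75, -0.45, -0.15, 0.15, 0.6),
                                 max_slice_factor = 50) {
  ifs <- interface_set(lambdas)
  ens <- path_ensembles(ifs)
  N <- length(ens)
  lam <- ifs$lambdas
  dyn <- list(params = params, lambdas = lam)
  # running mean trial length per ensemble (slices), for the length cap
  meanlen <- new.env(parent = emptyenv())
  meanlen$v <- rep(NA_real_, N)
  ens_pos <- function(e) which(vapply(ens, function(x) x$id, "") == e$id)
  # thresholds for "crossed the next interface": [k+] -> lambda_{k+1}
  thr <- c(Inf, lam[seq_len(ifs$M) + 1L])
  list(
    name = "langevin_double_well",
    params = params, lambdas = lam, ensembles = ens,
    initial_states = function() {
      out <- vector("list", N)
      out[[1L]] <- ramp_path(lam[1L], lam[1L] - 0.45, params$dt, "minus")
      for (k in seq_len(ifs$M) - 1L)
        out[[k + 2L]] <- ramp_path(lam[1L], lam[k + 1L], params$dt, "plus")
      out
    },
    propose = function(state, ens_j) {
      pos <- ens_pos(ens_j)
      ml <- meanlen$v[pos]
      cap <- if (is.na(ml)) Inf else max_slice_factor * ml
      mv <- shooting_move(state, ens_j, dyn, max_slices = cap)
      nl <- length(mv$proposal$new_state$x)
      meanlen$v[pos] <- if (is.na(ml)) nl else 0.99 * ml + 0.01 * nl
      list(proposal = mv$proposal, duration = mv$duration, capped = mv$capped)
    },
    crossed_next = function(state, ens_j) {
      rk <- ens_j$rank
      if (rk < 0L) return(0L)
      as.integer(state$lambda_max >= lam[rk + 2L])
    },
    cross_value = function(state) state$lambda_max,
    cross_thresholds = thr,
    w_matrix_entries = function(pool, ee) {
      lmax <- vapply(pool, function(s) s$lambda_max, 1)
      ok <- vapply(pool, function(s) isTRUE(s$valid), TRUE)
      plus <- ok & vapply(pool, function(s) s$kind == "plus", TRUE)
      minus <- ok & vapply(pool, function(s) s$kind == "minus", TRUE)
      rk <- vapply(ee, function(e) e$rank, 1L)
      W <- matrix(0, length(pool), length(ee))
      for (j in seq_along(ee)) {
        if (rk[j] == -1L) W[, j] <- as.numeric(minus)
        else W[, j] <- as.numeric(plus & lmax >= lam[rk[j] + 1L])
      }
      W
    },
    state_index = NULL,
    point_exchange = function(s0m, s0p)
      point_exchange_move(s0m, s0p, dyn, max_slices = 200000L)
  )
}

#' Direct brute-force rate reference for the double well
#'
#' Measures the A-to-B rate constant on plain long-trajectory dynamics,
#' with no path-sampling machinery, as the independent reference for the
#' interface-sampling rate (`flux x P_cross`).
#'
#' `method = "transition"` (default) runs one long trajectory and counts
#' first passages into B per unit of A-residence time, with A entered when
#' x drops below `lam0` and left when x first reaches `lamM`; this history
#' indicator measures exactly the rate constant that `flux x P_cross`
#' estimates.  `method = "fpt"` instead averages independent first-passage
#' times from the reactant minimum to `lamM`; its inverse approaches the
#' rate only when the barrier is high, so it is kept for diagnostics.
#'
#' @param params a [langevin_params()].
#' @param lam0 reactant-side boundary (first interface).
#' @param lamM product-side boundary (last interface).
#' @param n_steps trajectory length in steps (`"transition"`).
#' @param n passages (`"fpt"`).
#' @param n_blocks blocks for the error estimate.
#' @param method see above.
#' @return List with `rate`, `rel_err`, `n` (transitions or passages).
#' @export
direct_rate <- function(params = langevin_params(), lam0 = -0.75, lamM = 0.6,
                        n_steps = 2e7, n = 200L, n_blocks = 10L,
                        method = c("transition", "fpt")) {
  method <- match.arg(method)
  if (method == "fpt") {
    fpt <- cpp_first_passage(as.integer(n), -1, lamM, 0L, params$barrier,
                             params$gamma, params$temperature, params$dt,
                             params$mass, 100000000L)
    fpt <- fpt[is.finite(fpt)]
    if (length(fpt) < 2L)
      stop_permex("too few completed passages", "permex_contract_error")
    m <- mean(fpt)
    se <- stats::sd(fpt) / sqrt(length(fpt))
    return(list(rate = 1 / m, rel_err = se / m, n = length(fpt)))
  }
  bl <- cpp_transition_rate(-1, 0, n_steps, 0L, params$barrier, params$gamma,
                            params$temperature, params$dt, params$mass,
                            lam0, lamM, as.integer(n_blocks))
  if (sum(bl$nAB) < 2 * n_blocks)
    stop_permex("too few transitions observed: lengthen the trajectory",
                "permex_contract_error")
  rates <- bl$nAB / bl$tA
  rate <- sum(bl$nAB) / sum(bl$tA)
  se <- stats::sd(rates) / sqrt(n_blocks)
  list(rate = rate, rel_err = se / rate, n = sum(bl$nAB))
}
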