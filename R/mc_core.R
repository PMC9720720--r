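# Metropolis-Hastings acceptance for standard moves and pair swaps.
#
# Moves report their own weight ratio rho_j(new)/rho_j(old): for path
# ensembles the plain path density is never evaluated explicitly, only
# indicator functions and high-acceptance weights, so the engine cannot
# compute rho itself.

#' Define a sampling ensemble
#'
#' An ensemble is characterised by an indicator (membership) function, an
#' optional positive high-acceptance weight `ha_weight` (cancelled in the
#' analysis by 1/w reweighting), and optionally a directly computable
#' density for systems (like the discrete toy) where state weights are
#' enumerable.
#'
#' @param id label, e.g. `"[0-]"` or `"[2+]"`.
#' @param rank integer: -1 for the reactant-side ensemble `[0-]`, k for
#'   `[k+]`.
#' @param indicator function(state) -> 0 or 1; must be pure.
#' @param ha_weight function(state) -> positive number; default constant 1.
#' @param density optional function(state) -> nonnegative weight, used as
#'   rho(state) when supplied (takes precedence over indicator * ha_weight
#'   in swap decisions and W-matrices).
#' @return An object of class `ensemble_def`.
#' @export
ensemble_def <- function(id, rank, indicator, ha_weight = NULL, density = NULL) {
  stopifnot(is.function(indicator))
  if (is.null(ha_weight)) {
    ha_weight <- function(state) 1
    attr(ha_weight, "default") <- TRUE
  }
  structure(list(id = id, rank = as.integer(rank), indicator = indicator,
                 ha_weight = ha_weight, density = density),
            class = "ensemble_def")
}

# internal: unnormalised ensemble weight of a state
ens_weight <- function(ens, state) {
  if (!is.null(ens$density)) return(ens$density(state))
  ind <- ens$indicator(state)
  if (ind == 0) 0 else ind * ens$ha_weight(state)
}

#' Construct a move proposal
#'
#' @param old_state,new_state the incumbent and trial states.
#' @param gen_forward,gen_backward generation probability densities for the
#'   forward and reverse move; `gen_forward` must be positive.
#' @param weight_ratio rho(new)/rho(old) as computed by the move generator
#'   (0 when the trial violates the ensemble's membership conditions).
#' @return An object of class `move_proposal`.
#' @export
move_proposal <- function(old_state, new_state, gen_forward = 1,
                          gen_backward = 1, weight_ratio = 1) {
  structure(list(old_state = old_state, new_state = new_state,
                 gen_forward = gen_forward, gen_backward = gen_backward,
                 weight_ratio = weight_ratio),
            class = "move_proposal")
}

#' Metropolis-Hastings acceptance of a standard move
#'
#' Accepts with probability
#' \deqn{\min\left[1, \frac{\rho(s')}{\rho(s)}
#'       \frac{P_{gen}(s' \to s)}{P_{gen}(s \to s')}\right].}
#' On rejection the caller retains and resamples the old state.
#'
#' @param proposal a [move_proposal()].
#' @return `TRUE` (accept) or `FALSE` (reject).  Consumes one uniform
#'   variate from the engine's random stream unless the decision is forced.
#' @export
metropolis_accept <- function(proposal) {
  if (!is.finite(proposal$gen_forward) || proposal$gen_forward <= 0)
    stop_permex("gen_forward must be positive", "permex_contract_error")
  if (proposal$weight_ratio < 0)
    stop_permex("weight_ratio must be nonnegative", "permex_contract_error")
  a <- proposal$weight_ratio * proposal$gen_backward / proposal$gen_forward
  if (a >= 1) return(TRUE)
  if (a <= 0) return(FALSE)
  stats::runif(1) < a
}

#' Pair-swap acceptance between two ensembles
#'
#' Attempts to exchange the incumbent states of two free ensembles,
#' accepting with probability
#' \deqn{\min\left[1, \frac{\rho_1(s_2)\,\rho_2(s_1)}{\rho_1(s_1)\,\rho_2(s_2)}\right],}
#' which with indicator-times-weight ensemble densities reduces to the
#' indicator of the crossed assignment times the weight ratio.
#'
#' @param s1,s2 incumbent states of `e1` and `e2`.
#' @param e1,e2 [ensemble_def()] objects.
#' @return `TRUE` if the swap is accepted.
#' @export
swap_accept <- function(s1, s2, e1, e2) {
  w11 <- ens_weight(e1, s1); w22 <- ens_weight(e2, s2)
  if (w11 <= 0 || w22 <= 0)
    stop_permex("incumbent state invalid in its own ensemble", "permex_state_error")
  w12 <- ens_weight(e1, s2); w21 <- ens_weight(e2, s1)
  a <- (w12 * w21) / (w11 * w22)
  if (a >= 1) return(TRUE)
  if (a <= 0) return(FALSE)
  stats::runif(1) < a
}
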