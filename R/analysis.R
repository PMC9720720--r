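# Turning sample-record streams into crossing probabilities, fluxes,
# rates, block errors and efficiency diagnostics.
#
# Estimators average over recorded events (not over virtual time): occupied
# ensembles contribute nothing between their events, mirroring the
# engine's sampling rule.  High-acceptance weights are undone by the
# 1/w_j(X) factor carried on every record.

#' Weighted block error of a running series
#'
#' Standard blocking: the (weighted) series is split into `n_blocks`
#' contiguous blocks of equal total weight; the relative error of the
#' weighted mean is `sd(block means) / (mean * sqrt(n_blocks))`.
#'
#' @param values numeric series (e.g. per-record crossing indicators or
#'   chunk ratios).
#' @param weights nonnegative weights (default 1).
#' @param n_blocks number of blocks (default 10).
#' @return Relative error (NaN when the mean is zero).
#' @export
block_error <- function(values, weights = NULL, n_blocks = 10L) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  if (n < 2L * n_blocks)
    stop_permex(sprintf("series of length %d is too short for %d blocks",
                        n, n_blocks), "permex_contract_error")
  cw <- cumsum(weights)
  total <- cw[n]
  grp <- pmin(ceiling(cw / total * n_blocks), n_blocks)
  bs <- vapply(seq_len(n_blocks), function(g) {
    i <- grp == g
    sum(values[i] * weights[i]) / sum(weights[i])
  }, 1)
  m <- sum(values * weights) / total
  if (m == 0) return(NaN)
  stats::sd(bs) / (abs(m) * sqrt(n_blocks))
}

# internal: post-burn-in chunk selection for one ensemble
chunk_window <- function(run, j, burn_in) {
  k <- run$records$nchunk[j]
  if (k == 0L) return(integer(0))
  mass <- run$records$mass[j, seq_len(k)]
  cm <- cumsum(mass)
  start <- which(cm >= burn_in * cm[k])[1L]
  seq.int(start, k)
}

#' Local conditional crossing probability of one ensemble
#'
#' The chance that a path sampled in `[k+]` crosses the next interface,
#' estimated as
#' `sum(w * inv_ha * crossed) / sum(w * inv_ha)` over the post-burn-in
#' record stream, with a block-analysis relative error.
#'
#' @param records either a `permex_run` together with `ensemble` (index or
#'   id), or a data frame with columns `weight`, `crossed` and optionally
#'   `inv_ha`.
#' @param ensemble ensemble index or id (run input only).
#' @param n_blocks blocks for the error estimate.
#' @param burn_in fraction of record mass discarded (default: the run's
#'   configured value; 0 for data-frame input).
#' @return List with `p`, `rel_err`, `mass` (post-burn-in record mass).
#' @export
local_crossing_probability <- function(records, ensemble = NULL,
                                       n_blocks = 10L, burn_in = NULL) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0L)
      stop_permex("no records: estimate undefined", "permex_undefined_error")
    inv <- if ("inv_ha" %in% names(records)) records$inv_ha else 1
    w <- records$weight * inv
    p <- sum(w * records$crossed) / sum(w)
    err <- if (nrow(records) >= 2L * n_blocks)
      block_error(records$crossed, w, n_blocks) else NA_real_
    return(list(p = p, rel_err = err, mass = sum(records$weight)))
  }
  run <- records
  stopifnot(inherits(run, "permex_run"))
  j <- if (is.character(ensemble)) match(ensemble, run$ensemble_ids) else ensemble
  if (is.na(j) || is.null(j))
    stop_permex("unknown ensemble", "permex_contract_error")
  if (is.null(burn_in)) burn_in <- run$config$burn_in
  win <- chunk_window(run, j, burn_in)
  if (length(win) == 0L)
    stop_permex("no records for this ensemble: estimate undefined",
                "permex_undefined_error")
  num <- run$records$num[j, win]; den <- run$records$den[j, win]
  p <- sum(num) / sum(den)
  err <- if (length(win) >= 2L * n_blocks)
    block_error(num / pmax(den, .Machine$double.xmin), den, n_blocks)
  else NA_real_
  list(p = p, rel_err = err, mass = sum(run$records$mass[j, win]))
}

#' Overall crossing probability from local conditional ones
#'
#' The product of the per-ensemble conditional crossing probabilities; the
#' relative errors combine as `eps^2 = sum(eps_i^2)` (inter-ensemble
#' correlations neglected — a diagnostic, not a confidence interval).
#'
#' @param locals numeric vector of local probabilities, or the data frame
#'   from [crossing_analysis()].
#' @param rel_errs optional per-ensemble relative errors.
#' @return List with `p_cross` and `rel_err`.
#' @export
overall_crossing_probability <- function(locals, rel_errs = NULL) {
  if (is.data.frame(locals)) {
    rel_errs <- locals$rel_err
    locals <- locals$p_local
  }
  p <- prod(locals)
  err <- if (!is.null(rel_errs)) sqrt(sum(rel_errs^2, na.rm = TRUE)) else NA_real_
  list(p_cross = p, rel_err = err)
}

#' Per-ensemble crossing analysis of a run
#'
#' @param run a `permex_run`.
#' @param n_blocks,burn_in see [local_crossing_probability()].
#' @return List with `local` (data frame: ensemble, rank, p_local, rel_err,
#'   mass), `p_cross`, `rel_err`.
#' @export
crossing_analysis <- function(run, n_blocks = 10L, burn_in = NULL) {
  stopifnot(inherits(run, "permex_run"))
  plus <- which(run$ranks >= 0L)
  rows <- lapply(plus, function(j) {
    lc <- local_crossing_probability(run, j, n_blocks, burn_in)
    data.frame(ensemble = run$ensemble_ids[j], rank = run$ranks[j],
               p_local = lc$p, rel_err = lc$rel_err, mass = lc$mass)
  })
  local <- do.call(rbind, rows)
  ov <- overall_crossing_probability(local)
  list(local = local, p_cross = ov$p_cross, rel_err = ov$rel_err)
}

#' Flux through the first interface and the rate constant
#'
#' The flux through `lambda_0` is the inverse of the summed mean path
#' durations of the `[0-]` and `[0+]` ensembles; the rate is
#' `flux * P_cross`.  Requires both reactant-side ensembles, so it is
#' unavailable for the MSVS process.
#'
#' @param run a `permex_run` for a dynamical system.
#' @param crossing optional result of [crossing_analysis()] (recomputed
#'   otherwise).
#' @param n_blocks,burn_in see [local_crossing_probability()].
#' @return List of class `rate_result`: `local_probs`, `p_cross`, `flux`,
#'   `rate`, `rel_err_pcross`, `rel_err_flux`, `rel_err` (combined).
#' @export
flux_and_rate <- function(run, crossing = NULL, n_blocks = 10L,
                          burn_in = NULL) {
  stopifnot(inherits(run, "permex_run"))
  j0m <- which(run$ranks == -1L); j0p <- which(run$ranks == 0L)
  if (length(j0m) != 1L)
    stop_permex("flux unavailable: no [0-] ensemble in this run",
                "permex_undefined_error")
  if (is.null(burn_in)) burn_in <- run$config$burn_in
  if (is.null(crossing)) crossing <- crossing_analysis(run, n_blocks, burn_in)
  mean_dur <- function(j) {
    win <- chunk_window(run, j, burn_in)
    dur <- run$records$dur[j, win]; mass <- run$records$mass[j, win]
    m <- sum(dur) / sum(mass)
    err <- if (length(win) >= 2L * n_blocks)
      block_error(dur / pmax(mass, .Machine$double.xmin), mass, n_blocks)
    else NA_real_
    c(m, err)
  }
  d0m <- mean_dur(j0m); d0p <- mean_dur(j0p)
  denom <- d0m[1L] + d0p[1L]
  flux <- 1 / denom
  eflux <- sqrt((d0m[1L] * d0m[2L])^2 + (d0p[1L] * d0p[2L])^2) / denom
  rate <- flux * crossing$p_cross
  structure(list(local_probs = crossing$local, p_cross = crossing$p_cross,
                 flux = flux, rate = rate,
                 rel_err_pcross = crossing$rel_err, rel_err_flux = eflux,
                 rel_err = sqrt(crossing$rel_err^2 + eflux^2)),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("flux = %.4g /s   P_cross = %.4g   rate = %.4g /s (rel. err %.3g)\n",
              x$flux, x$p_cross, x$rate, x$rel_err))
  invisible(x)
}

#' Computational efficiency of a run
#'
#' Efficiency is the inverse computer time to reach an overall relative
#' error of 1: `1 / (T * eps^2)`, with T either the virtual wall-clock
#' time or the summed worker busy (CPU) time.
#'
#' @param run a `permex_run`.
#' @param rel_err overall relative error (default: from
#'   [crossing_analysis()]).
#' @return List with `wall`, `cpu`, `rel_err`, `wall_time`, `cpu_time`.
#' @export
efficiency <- function(run, rel_err = NULL) {
  stopifnot(inherits(run, "permex_run"))
  if (is.null(rel_err)) rel_err <- crossing_analysis(run)$rel_err
  list(wall = 1 / (run$clock * rel_err^2),
       cpu = 1 / (run$busy_time * rel_err^2),
       rel_err = rel_err, wall_time = run$clock, cpu_time = run$busy_time)
}

#' Per-ensemble marginal state distribution of a run
#'
#' Available when the system supplies a small discrete state index (the
#' discrete validation toy): the accumulated fractional sample mass per
#' (ensemble, state), normalised per ensemble.
#'
#' @param run a `permex_run`.
#' @return Matrix (ensembles x states) of sampled marginals.
#' @export
sampled_marginals <- function(run) {
  m <- run$records$marginal
  if (is.null(m))
    stop_permex("run has no discrete marginal tallies", "permex_undefined_error")
  sw <- rowSums(m)
  sweep(m, 1L, pmax(sw, .Machine$double.xmin), "/")
}
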