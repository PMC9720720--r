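# The noncohort replica-exchange engine.
#
# K workers perform CPU-intensive standard moves on K of the N ensembles in
# parallel; parallelism is emulated on a deterministic discrete-event
# virtual clock (a move's cost in virtual seconds is reported by the
# system).  Whenever a worker finishes, states are redistributed among the
# currently unoccupied ensembles: in finite mode by a geometric number of
# random pair swaps, in infinite mode by sampling all state-to-ensemble
# permutations at once through the permanent-based P-matrix.  Occupied
# ensembles never participate in swaps and are never sampled.
#
# Record accumulation note: per-ensemble tallies are reduced on the fly
# into event-indexed chunks (sums of weight, weight*crossed, weight*dur,
# weight/ha) held in plain local matrices, so memory stays constant and
# writes are in place; block errors are computed from the chunk sums.

#' Scheduler configuration
#'
#' @param n_workers K, number of workers, `1 <= K <= N`.
#' @param mode `"infinite"` (permanent-based infinite swapping) or
#'   `"finite"` (explicit pair swaps).
#' @param p_re finite mode only: probability of doing (another) replica
#'   exchange pair swap after a move completes; `0 <= p_re < 1`.
#' @param stop_time virtual-time budget in seconds (run until the clock
#'   passes it), or `NULL`.
#' @param stop_moves move-count budget (number of completed CPU moves), or
#'   `NULL`.  Exactly one of `stop_time`/`stop_moves` must be given.
#' @param seed integer seed for the single engine-owned random stream.
#' @param null_move finite mode: after each swap attempt, also resample the
#'   uninvolved free ensembles (does not reduce statistical uncertainty;
#'   default off).
#' @param burn_in fraction of the record stream discarded by the analysis
#'   (default 0.1).
#' @param p_point_exchange probability that a worker assigned to `[0-]` or
#'   `[0+]` (with the partner ensemble free) performs the reactant-side
#'   point-exchange move instead of a shooting move, for systems that
#'   support it.
#' @param record `"tally"` (chunked accumulators, constant memory) or
#'   `"trace"` (full sample-record stream kept as a data frame; small runs
#'   only).
#' @param chunk_events events per accumulator chunk for the block analysis.
#' @param bbfg_cap dimension cap for generic BBFG permanents.
#' @return Object of class `scheduler_config`.
#' @export
scheduler_config <- function(n_workers, mode = c("infinite", "finite"),
                             p_re = 0.5, stop_time = NULL, stop_moves = NULL,
                             seed = 1L, null_move = FALSE, burn_in = 0.1,
                             p_point_exchange = 0.25,
                             record = c("tally", "trace"),
                             chunk_events = NULL, bbfg_cap = 20L) {
  mode <- match.arg(mode)
  record <- match.arg(record)
  if (is.null(stop_time) == is.null(stop_moves))
    stop_permex("give exactly one of stop_time or stop_moves",
                "permex_contract_error")
  if (p_re < 0 || p_re >= 1)
    stop_permex("p_re must satisfy 0 <= p_re < 1", "permex_contract_error")
  if (burn_in < 0 || burn_in >= 1)
    stop_permex("burn_in must be in [0, 1)", "permex_contract_error")
  if (is.null(chunk_events))
    chunk_events <- if (!is.null(stop_moves))
      max(1L, as.integer(ceiling(stop_moves / 2000))) else 50L
  structure(list(n_workers = as.integer(n_workers), mode = mode, p_re = p_re,
                 stop_time = stop_time, stop_moves = stop_moves,
                 seed = as.integer(seed), null_move = isTRUE(null_move),
                 burn_in = burn_in, p_point_exchange = p_point_exchange,
                 record = record, chunk_events = as.integer(chunk_events),
                 bbfg_cap = as.integer(bbfg_cap)),
            class = "scheduler_config")
}

#' Pick a uniform random unordered pair of free ensembles
#'
#' @param free vector of free ensemble indices.
#' @return A length-2 vector, or `NULL` when fewer than two ensembles are
#'   free (signals skip-swap).
#' @export
pick_free_pair <- function(free) {
  if (length(free) < 2L) return(NULL)
  free[sample.int(length(free), 2L)]
}

#' Pick a uniform random free ensemble for the next worker assignment
#'
#' @param free nonempty vector of free ensemble indices.
#' @return One ensemble index.
#' @export
assign_worker <- function(free) {
  if (length(free) < 1L)
    stop_permex("no free ensemble to assign", "permex_internal_error")
  free[sample.int(length(free), 1L)]
}

# internal: W-matrix entries over pool x ensembles via the system's
# vectorised builder when available, else the generic closure route.
w_entries <- function(system, pool, ens) {
  if (!is.null(system$w_matrix_entries)) return(system$w_matrix_entries(pool, ens))
  n <- length(pool); m <- length(ens)
  W <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n))
    W[i, j] <- ens_weight(ens[[j]], pool[[i]])
  W
}

#' Run the asynchronous replica-exchange engine
#'
#' Executes the discrete-event loop until the stop criterion: pop the
#' earliest finish event (ties broken by worker index), accept or reject
#' the finished move, free its ensemble(s), redistribute states among the
#' free ensembles (finite mode: a geometric number of random pair swaps,
#' each recorded; infinite mode: fractional sample records for every free
#' ensemble from the columns of the permanent-based P-matrix), then assign
#' the worker to a uniformly random free ensemble and schedule its next
#' standard move with the system-reported duration.
#'
#' @param system a system list (see [msvs_system()], [discrete_toy()],
#'   [langevin_double_well()]).
#' @param config a [scheduler_config()].
#' @return Object of class `permex_run`: counters, chunked per-ensemble
#'   record accumulators, optional marginal tallies and trace.
#' @export
run_scheduler <- function(system, config) {
  stopifnot(inherits(config, "scheduler_config"))
  ens <- system$ensembles
  N <- length(ens)
  K <- config$n_workers
  if (K < 1L || K > N)
    stop_permex("need 1 <= n_workers <= n_ensembles", "permex_contract_error")
  set.seed(config$seed)

  ranks <- vapply(ens, function(e) e$rank, 1L)
  ids <- vapply(ens, function(e) e$id, "")
  cross_thr <- if (!is.null(system$cross_thresholds)) system$cross_thresholds else
    rep(Inf, N)
  cross_val <- system$cross_value
  ha_all_default <- all(vapply(ens, function(e)
    isTRUE(attr(e$ha_weight, "default")), TRUE))
  inv_ha_of <- function(j, state)
    if (ha_all_default) 1 else 1 / ens[[j]]$ha_weight(state)

  states <- initialize_states(system, ens)
  next_id <- N + 1L
  for (i in seq_len(N)) states[[i]]$id <- i

  # --- record accumulators (plain locals; written in place) ----------------
  chunk_events <- config$chunk_events
  chunk_cap <- 256L
  ch_num <- matrix(0, N, chunk_cap); ch_den <- matrix(0, N, chunk_cap)
  ch_dur <- matrix(0, N, chunk_cap); ch_mass <- matrix(0, N, chunk_cap)
  has_marg <- !is.null(system$state_index)
  marg <- if (has_marg) matrix(0, N, system$n_states) else NULL
  burn_ev <- if (!is.null(config$stop_moves))
    floor(config$burn_in * config$stop_moves) else 0L
  do_trace <- config$record == "trace"
  if (do_trace) {
    tr <- matrix(0, 4096L, 7L)
    tr_n <- 0L
  }

  # worker event slots
  ev_time <- rep(Inf, K)
  ev_ens <- vector("list", K)
  ev_payload <- vector("list", K)
  ev_kind <- character(K)
  ev_dur <- numeric(K)

  occupied <- rep(FALSE, N)
  clock <- 0
  events <- 0L
  ci <- 1L                       # current chunk column
  moves_started <- integer(N)
  moves_completed <- integer(N)
  rejected_capped <- 0L
  swap_attempts <- 0L; swap_accepts <- 0L; pe_moves <- 0L
  busy_time <- 0

  launch_std <- function(w, gj, state) {
    pr <- system$propose(state, ens[[gj]])
    ev_time[w] <<- clock + pr$duration
    ev_ens[[w]] <<- gj
    ev_payload[[w]] <<- pr
    ev_kind[w] <<- "std"
    ev_dur[w] <<- pr$duration
    occupied[gj] <<- TRUE
    moves_started[gj] <<- moves_started[gj] + 1L
  }
  launch_pe <- function(w, g0m, g0p, s0m, s0p) {
    res <- system$point_exchange(s0m, s0p)
    res$old0m <- s0m; res$old0p <- s0p
    ev_time[w] <<- clock + res$duration
    ev_ens[[w]] <<- c(g0m, g0p)
    ev_payload[[w]] <<- res
    ev_kind[w] <<- "pe"
    ev_dur[w] <<- res$duration
    occupied[c(g0m, g0p)] <<- TRUE
    moves_started[g0m] <<- moves_started[g0m] + 1L
    pe_moves <<- pe_moves + 1L
  }
  maybe_pe <- function(gj, free_now) {
    if (is.null(system$point_exchange)) return(NA_integer_)
    rk <- ranks[gj]
    if (rk != -1L && rk != 0L) return(NA_integer_)
    partner <- which(ranks == (if (rk == -1L) 0L else -1L))
    if (length(partner) != 1L || !(partner %in% free_now)) return(NA_integer_)
    if (stats::runif(1) >= config$p_point_exchange) return(NA_integer_)
    partner
  }

  # nested fast path: indicator-only memberships ordered by a scalar rank
  # value (the MSVS case) admit a staircase closed form with no W-matrix
  use_fast <- config$mode == "infinite" && isTRUE(system$nested) &&
    !is.null(cross_val) && !do_trace && ha_all_default &&
    is.null(system$point_exchange)

  # --- initial assignment: K workers on K random ensembles -----------------
  init_occ <- sort(sample.int(N, K))
  free <- setdiff(seq_len(N), init_occ)
  if (config$mode == "infinite") {
    pool <- states[-init_occ]
    if (use_fast) {
      pool_val <- vapply(pool, cross_val, 1)
      pool_dur <- vapply(pool, function(s) s$duration, 1)
    }
  }
  for (w in seq_len(K)) launch_std(w, init_occ[w], states[[init_occ[w]]])

  stop_now <- function() {
    if (!is.null(config$stop_moves)) events >= config$stop_moves
    else clock >= config$stop_time
  }

  # --- event loop ----------------------------------------------------------
  repeat {
    w <- which.min(ev_time)
    t <- ev_time[w]
    if (!is.null(config$stop_time) && t > config$stop_time) break
    clock <- t
    e_set <- ev_ens[[w]]
    busy_time <- busy_time + ev_dur[w]
    ev_time[w] <- Inf
    incoming <- list()
    if (ev_kind[w] == "std") {
      pr <- ev_payload[[w]]
      acc <- metropolis_accept(pr$proposal)
      if (acc) {
        st <- pr$proposal$new_state
        st$id <- next_id; next_id <- next_id + 1L
      } else {
        st <- pr$proposal$old_state
        if (isTRUE(pr$capped)) rejected_capped <- rejected_capped + 1L
      }
      incoming <- list(st)
    } else {
      res <- ev_payload[[w]]
      if (res$accepted) {
        a <- res$new0m; a$id <- next_id; next_id <- next_id + 1L
        b <- res$new0p; b$id <- next_id; next_id <- next_id + 1L
        incoming <- list(a, b)
      } else incoming <- list(res$old0m, res$old0p)
    }
    moves_completed[e_set[1L]] <- moves_completed[e_set[1L]] + 1L
    occupied[e_set] <- FALSE
    free <- c(free, e_set)
    events <- events + 1L
    ci <- 1L + (events - 1L) %/% chunk_events
    if (ci > chunk_cap) {
      grow <- function(m) cbind(m, matrix(0, N, chunk_cap))
      ch_num <- grow(ch_num); ch_den <- grow(ch_den)
      ch_dur <- grow(ch_dur); ch_mass <- grow(ch_mass)
      chunk_cap <- 2L * chunk_cap
    }

    if (config$mode == "infinite") {
      pool <- c(pool, incoming)
      if (use_fast) {
        pool_val <- c(pool_val, vapply(incoming, cross_val, 1))
        pool_dur <- c(pool_dur, vapply(incoming, function(s) s$duration, 1))
      }
      nf <- length(free)
      if (nf != length(pool))
        stop_permex("free-ensemble and pool sizes diverged", "permex_internal_error")

      if (use_fast) {
        free_sorted <- free[order(ranks[free])]
        rks <- ranks[free_sorted]
        counts <- findInterval(pool_val, rks)
        if (any(counts == 0L))
          stop_permex("state fits no free ensemble: matching infeasible",
                      "permex_infeasible_error")
        ord <- order(counts)
        res <- cpp_staircase_tally(counts[ord], pool_val[ord],
                                   cross_thr[free_sorted], pool_dur[ord])
        fi <- cbind(free_sorted, ci)
        ch_num[fi] <- ch_num[fi] + res$num
        ch_den[fi] <- ch_den[fi] + 1
        ch_dur[fi] <- ch_dur[fi] + res$dur
        ch_mass[fi] <- ch_mass[fi] + 1
        if (stop_now()) break
        jc <- sample.int(nf, 1L)
        gj <- free_sorted[jc]
        ir <- sample.int(nf, 1L, prob = res$P[, jc])
        ipool <- ord[ir]
        launch_std(w, gj, pool[[ipool]])
        pool <- pool[-ipool]
        pool_val <- pool_val[-ipool]
        pool_dur <- pool_dur[-ipool]
        free <- setdiff(free, gj)
        next
      }

      bw <- build_w_matrix(pool, ens[free], builder = function(p, e)
        w_entries(system, p, e))
      P <- p_matrix(bw$W, cap = config$bbfg_cap)
      free_sorted <- free[order(ranks[free])]
      pool_ord <- pool[bw$rows]
      durs <- vapply(pool_ord, function(s) s$duration, 1)
      inv_ha <- if (ha_all_default) matrix(1, nf, nf) else {
        m <- matrix(1, nf, nf)
        for (j in seq_len(nf)) for (i in seq_len(nf))
          if (P[i, j] > 0) m[i, j] <- 1 / bw$ens[[j]]$ha_weight(pool_ord[[i]])
        m
      }
      crossed <- if (!is.null(cross_val)) {
        vals <- vapply(pool_ord, cross_val, 1)
        outer(vals, cross_thr[free_sorted], ">=") + 0
      } else matrix(0, nf, nf)
      PI <- P * inv_ha
      fi <- cbind(free_sorted, ci)
      ch_num[fi] <- ch_num[fi] + colSums(PI * crossed)
      ch_den[fi] <- ch_den[fi] + colSums(PI)
      ch_dur[fi] <- ch_dur[fi] + colSums(P * durs)
      ch_mass[fi] <- ch_mass[fi] + colSums(P)
      if (has_marg && events > burn_ev) {
        sidx <- vapply(pool_ord, system$state_index, 1L)
        Sm <- matrix(0, nf, ncol(marg))
        Sm[cbind(seq_len(nf), sidx)] <- 1
        marg[free_sorted, ] <- marg[free_sorted, ] + crossprod(P, Sm)
      }
      if (do_trace) {
        sid <- vapply(pool_ord, function(s) s$id, 1L)
        for (j in seq_len(nf)) {
          nzr <- which(P[, j] > 0)
          nn <- length(nzr)
          while (tr_n + nn > nrow(tr)) {
            tr2 <- matrix(0, 2L * nrow(tr), 7L)
            tr2[seq_len(tr_n), ] <- tr[seq_len(tr_n), ]
            tr <- tr2
          }
          rows <- tr_n + seq_len(nn)
          tr[rows, ] <- cbind(clock, free_sorted[j], sid[nzr], P[nzr, j],
                              crossed[nzr, j], durs[nzr], inv_ha[nzr, j])
          tr_n <- tr_n + nn
        }
      }
      if (stop_now()) break
      jc <- sample.int(nf, 1L)
      gj <- free_sorted[jc]
      ir <- sample.int(nf, 1L, prob = P[, jc])
      st <- pool_ord[[ir]]
      pe_partner <- maybe_pe(gj, free)
      if (!is.na(pe_partner)) {
        jp <- which(free_sorted == pe_partner)
        ip <- sample.int(nf, 1L, prob = P[, jp])
        sp <- pool_ord[[ip]]
        if (ranks[gj] == -1L) launch_pe(w, gj, pe_partner, st, sp)
        else launch_pe(w, pe_partner, gj, sp, st)
        pool <- pool[-bw$rows[c(ir, ip)]]
        free <- setdiff(free, c(gj, pe_partner))
      } else {
        launch_std(w, gj, st)
        pool <- pool[-bw$rows[ir]]
        free <- setdiff(free, gj)
      }
    } else {
      # ------------------------------- finite mode -------------------------
      for (i in seq_along(e_set)) states[[e_set[i]]] <- incoming[[i]]
      # recording is inlined (not a closure) so the accumulator matrices are
      # modified in place
      rec_idx <- e_set
      repeat {
        st <- states[rec_idx]
        durs <- vapply(st, function(s) s$duration, 1)
        inv <- vapply(seq_along(rec_idx), function(i)
          inv_ha_of(rec_idx[i], st[[i]]), 1)
        crs <- if (!is.null(cross_val))
          (vapply(st, cross_val, 1) >= cross_thr[rec_idx]) + 0
        else rep(0, length(rec_idx))
        fi <- cbind(rec_idx, ci)
        ch_num[fi] <- ch_num[fi] + inv * crs
        ch_den[fi] <- ch_den[fi] + inv
        ch_dur[fi] <- ch_dur[fi] + durs
        ch_mass[fi] <- ch_mass[fi] + 1
        if (has_marg && events > burn_ev) {
          sidx <- vapply(st, system$state_index, 1L)
          marg[cbind(rec_idx, sidx)] <- marg[cbind(rec_idx, sidx)] + 1
        }
        if (do_trace) {
          sid <- vapply(st, function(s) s$id, 1L)
          nn <- length(rec_idx)
          while (tr_n + nn > nrow(tr)) {
            tr2 <- matrix(0, 2L * nrow(tr), 7L)
            tr2[seq_len(tr_n), ] <- tr[seq_len(tr_n), ]
            tr <- tr2
          }
          tr[tr_n + seq_len(nn), ] <- cbind(clock, rec_idx, sid, 1, crs, durs, inv)
          tr_n <- tr_n + nn
        }
        # geometric swap loop (steps 4-6): each pass records the ensembles
        # involved in the attempt (or all free ones with the null move)
        if (length(free) < 2L) break
        if (stats::runif(1) > config$p_re) break
        pair <- pick_free_pair(free)
        swap_attempts <- swap_attempts + 1L
        if (swap_accept(states[[pair[1L]]], states[[pair[2L]]],
                        ens[[pair[1L]]], ens[[pair[2L]]])) {
          tmp <- states[[pair[1L]]]
          states[[pair[1L]]] <- states[[pair[2L]]]
          states[[pair[2L]]] <- tmp
          swap_accepts <- swap_accepts + 1L
        }
        rec_idx <- if (config$null_move) free else pair
      }
      if (stop_now()) break
      gj <- assign_worker(free)
      pe_partner <- maybe_pe(gj, free)
      if (!is.na(pe_partner)) {
        g0m <- if (ranks[gj] == -1L) gj else pe_partner
        g0p <- if (ranks[gj] == -1L) pe_partner else gj
        launch_pe(w, g0m, g0p, states[[g0m]], states[[g0p]])
        free <- setdiff(free, c(g0m, g0p))
      } else {
        launch_std(w, gj, states[[gj]])
        free <- setdiff(free, gj)
      }
    }
  }

  used <- seq_len(min(ci, chunk_cap))
  records <- list(num = ch_num[, used, drop = FALSE],
                  den = ch_den[, used, drop = FALSE],
                  dur = ch_dur[, used, drop = FALSE],
                  mass = ch_mass[, used, drop = FALSE],
                  nchunk = rep(length(used), N),
                  marginal = marg)
  if (do_trace) {
    trace <- as.data.frame(tr[seq_len(tr_n), , drop = FALSE])
    names(trace) <- c("clock", "ensemble", "state_id", "weight", "crossed",
                      "duration", "inv_ha")
    records$trace <- trace
  }

  structure(list(
    config = config, system_name = system$name, n_ensembles = N,
    ensemble_ids = ids, ranks = ranks, clock = clock, events = events,
    moves_started = moves_started, moves_completed = moves_completed,
    swap_attempts = swap_attempts, swap_accepts = swap_accepts,
    pe_moves = pe_moves, rejected_capped = rejected_capped,
    busy_time = busy_time,
    records = records
  ), class = "permex_run")
}

#' @export
print.permex_run <- function(x, ...) {
  cat(sprintf("<permex_run> %s: N = %d ensembles, K = %d workers, %s mode\n",
              x$system_name, x$n_ensembles, x$config$n_workers, x$config$mode))
  cat(sprintf("  events: %d   virtual clock: %.3g s   worker busy time: %.3g s\n",
              x$events, x$clock, x$busy_time))
  if (x$swap_attempts > 0)
    cat(sprintf("  pair swaps: %d attempted, %d accepted\n",
                x$swap_attempts, x$swap_accepts))
  if (x$pe_moves > 0)
    cat(sprintf("  point-exchange moves: %d\n", x$pe_moves))
  invisible(x)
}

#' @export
summary.permex_run <- function(object, ...) {
  pc <- tryCatch(crossing_analysis(object), error = function(e) NULL)
  out <- list(run = object, crossing = pc)
  class(out) <- "summary.permex_run"
  out
}

#' @export
print.summary.permex_run <- function(x, ...) {
  print(x$run)
  if (!is.null(x$crossing)) {
    cat("\nLocal conditional crossing probabilities:\n")
    print(x$crossing$local, digits = 4)
    cat(sprintf("\nOverall crossing probability: %.4g (rel. err %.3g)\n",
                x$crossing$p_cross, x$crossing$rel_err))
  }
  invisible(x)
}
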