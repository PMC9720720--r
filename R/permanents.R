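# Exact matrix permanents and permanent-based swap-probability matrices.
#
# The permanent perm(W) = sum over permutations sigma of prod_i W[i, sigma(i)]
# counts weighted perfect matchings between states (rows) and ensembles
# (columns).  The swap-probability matrix P with
#   P_ij = W_ij * perm(W minus row i, column j) / perm(W)
# is doubly stochastic and gives the probability of finding state i in
# ensemble j under infinite swapping.  Three evaluation routes are provided:
# a first-row minor expansion (oracle, factorial cost), the
# Balasubramanian-Bax-Franklin-Glynn (BBFG) formula at O(2^n * n), and a
# polynomial closed form for "staircase" 0/1 matrices whose rows are runs of
# leading ones.  Block decomposition reduces any matrix with exploitable zero
# structure to smaller independent problems.

stop_permex <- function(msg, class) {
  stop(structure(class = c(class, "permex_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_square <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop_permex("matrix must be square", "permex_structural_error")
  if (any(!is.finite(M)) || any(M < 0))
    stop_permex("matrix entries must be finite and nonnegative",
                "permex_structural_error")
  invisible(M)
}

#' Permanent by recursive first-row minor expansion
#'
#' Reference implementation with factorial cost, intended as an independent
#' oracle for [permanent_bbfg()] on small matrices.
#'
#' @param M square nonnegative numeric matrix, at most 10 x 10.
#' @return The permanent of `M` (nonnegative scalar).
#' @seealso [permanent_bbfg()] for the production algorithm.
#' @export
permanent_naive <- function(M) {
  check_square(M)
  n <- nrow(M)
  if (n > 10L)
    stop_permex("permanent_naive is an oracle for n <= 10", "permex_capacity_error")
  rec <- function(A) {
    m <- nrow(A)
    if (m == 1L) return(A[1L, 1L])
    acc <- 0
    for (j in seq_len(m)) {
      if (A[1L, j] == 0) next
      acc <- acc + A[1L, j] * rec(A[-1L, -j, drop = FALSE])
    }
    acc
  }
  rec(M)
}

#' Permanent by the Balasubramanian-Bax-Franklin-Glynn formula
#'
#' Evaluates the permanent exactly in O(2^n * n) using Gray-code iteration
#' over the sign vectors of the Glynn expansion
#' \deqn{perm(M) = 2^{1-n} \sum_{\delta} \Big(\prod_i \delta_i\Big)
#'       \prod_j \sum_i \delta_i M_{ij}, \quad \delta \in \{1,-1\}^n,\ \delta_1 = 1.}
#' Rows are normalised by their maximum entry and the accumulated scale is
#' carried in log space, so the result is invariant to row magnitudes.
#'
#' @param M square nonnegative numeric matrix.
#' @param cap maximum accepted dimension; moves above this take exponential
#'   time and are refused (default 20).
#' @return The permanent of `M`.
#' @export
permanent_bbfg <- function(M, cap = 20L) {
  check_square(M)
  n <- nrow(M)
  if (n > cap)
    stop_permex(sprintf("matrix dimension %d exceeds the BBFG cap of %d", n, cap),
                "permex_capacity_error")
  if (n == 1L) return(M[1L, 1L])
  # row scaling: permanent is linear in each row
  rmax <- apply(M, 1L, max)
  if (any(rmax == 0)) return(0)
  Ms <- M / rmax
  logscale <- sum(log(rmax))
  cpp_permanent_bbfg(Ms) * exp(logscale)
}

# internal: best exact permanent (blocks, then staircase or BBFG per block)
perm_exact <- function(M, cap = 20L) {
  check_square(M)
  n <- nrow(M)
  if (n == 0L) return(1)
  bd <- block_decompose(M)
  Mp <- M[bd$row_order, bd$col_order, drop = FALSE]
  val <- 1
  for (blk in bd$blocks) {
    B <- Mp[blk, blk, drop = FALSE]
    sc <- to_staircase(B)
    if (!is.null(sc)) {
      val <- val * staircase_permanent(sc) * sc$scale
    } else {
      val <- val * permanent_bbfg(B, cap = cap)
    }
    if (val == 0) return(0)
  }
  val
}

# ---------------------------------------------------------------------------
# Block decomposition
# ---------------------------------------------------------------------------

# internal: maximum bipartite matching rows -> columns via augmenting paths.
# Returns for each column the matched row (NA if unmatched).
bipartite_matching <- function(nz) {
  n <- nrow(nz)
  match_col <- rep(NA_integer_, n)  # column -> row
  for (r in seq_len(n)) {
    seen <- rep(FALSE, n)
    augment <- function(row) {
      for (j in which(nz[row, ] & !seen)) {
        seen[j] <<- TRUE
        if (is.na(match_col[j]) || augment(match_col[j])) {
          match_col[j] <<- row
          return(TRUE)
        }
      }
      FALSE
    }
    augment(r)
  }
  match_col
}

# internal: Tarjan strongly connected components of a column digraph given as
# adjacency list; returns components in reverse topological order.
tarjan_scc <- function(adj) {
  n <- length(adj)
  index <- rep(NA_integer_, n); low <- integer(n); onstack <- rep(FALSE, n)
  stack <- integer(0); counter <- 0L; comps <- list()
  strongconnect <- function(v) {
    counter <<- counter + 1L
    index[v] <<- counter; low[v] <<- counter
    stack <<- c(stack, v); onstack[v] <<- TRUE
    for (w in adj[[v]]) {
      if (is.na(index[w])) {
        strongconnect(w)
        low[v] <<- min(low[v], low[w])
      } else if (onstack[w]) {
        low[v] <<- min(low[v], index[w])
      }
    }
    if (low[v] == index[v]) {
      comp <- integer(0)
      repeat {
        w <- stack[length(stack)]
        stack <<- stack[-length(stack)]
        onstack[w] <<- FALSE
        comp <- c(comp, w)
        if (w == v) break
      }
      comps[[length(comps) + 1L]] <<- sort(comp)
    }
  }
  for (v in seq_len(n)) if (is.na(index[v])) strongconnect(v)
  comps
}

#' Decompose a weight matrix into independent diagonal blocks
#'
#' Finds row and column permutations bringing the matrix into block
#' lower-triangular form: every entry to the right of and above a diagonal
#' block is zero, so the permanent factorises into the product of the block
#' permanents.  A matrix with no exploitable zero structure returns a single
#' block.
#'
#' The decomposition is the fine block-triangular form obtained from a
#' bipartite perfect matching followed by strongly connected components of
#' the matching-directed column graph.  If no perfect matching exists the
#' permanent is zero and a single all-inclusive block is returned (callers
#' detect perm = 0 downstream).
#'
#' @param W square nonnegative matrix.
#' @return list with `row_order`, `col_order` (permutations of `1:n`) and
#'   `blocks`, a list of index vectors into the *reordered* matrix.
#' @export
block_decompose <- function(W) {
  check_square(W)
  n <- nrow(W)
  if (n == 0L)
    return(list(row_order = integer(0), col_order = integer(0), blocks = list()))
  tol <- 1e-12 * max(W, 1e-300)
  nz <- W > tol
  match_col <- bipartite_matching(nz)
  if (anyNA(match_col))
    return(list(row_order = seq_len(n), col_order = seq_len(n),
                blocks = list(seq_len(n))))
  # digraph on columns: j -> j' if row matched to j has a nonzero in column j'
  adj <- lapply(seq_len(n), function(j) setdiff(which(nz[match_col[j], ]), j))
  comps <- tarjan_scc(adj)  # reverse topological order
  # Tarjan emits a component before all components it points to; ordering the
  # blocks in emission order puts all cross-component nonzeros below-left.
  col_order <- unlist(comps)
  row_order <- match_col[col_order]
  blocks <- list(); at <- 0L
  for (comp in comps) {
    blocks[[length(blocks) + 1L]] <- at + seq_along(comp)
    at <- at + length(comp)
  }
  list(row_order = row_order, col_order = col_order, blocks = blocks)
}

# ---------------------------------------------------------------------------
# Staircase fast path
# ---------------------------------------------------------------------------

#' Recognise a staircase weight matrix
#'
#' A staircase matrix has, after per-row positive scaling, rows that are a
#' run of ones followed by zeros (columns are assumed already ordered by
#' ensemble rank).  Such matrices arise whenever ensemble membership is
#' nested, as with interface-crossing path ensembles under indicator-only
#' weights.  Rows are sorted ascending by their count of leading ones
#' (stable, ties broken by original row index).
#'
#' @param W square nonnegative matrix.
#' @param tol an entry counts as zero when below `tol` times its row maximum.
#' @return An object of class `staircase_spec` with fields `counts` (sorted
#'   ascending), `row_order` (original row index per sorted row), `n`, and
#'   `scale` (product of the row scaling factors divided out), or `NULL`
#'   ("not staircase") if the structure is absent.
#' @export
to_staircase <- function(W, tol = 1e-12) {
  check_square(W)
  n <- nrow(W)
  if (n == 0L) return(NULL)
  counts <- integer(n)
  scale <- 1
  for (i in seq_len(n)) {
    row <- W[i, ]
    m <- max(row)
    if (m == 0) return(NULL)
    z <- row < tol * m
    k <- which(z)
    cnt <- if (length(k) == 0L) n else k[1L] - 1L
    if (cnt == 0L) return(NULL)                    # leading zero
    if (cnt < n && !all(z[(cnt + 1L):n])) return(NULL)  # one after a zero
    lead <- row[seq_len(cnt)]
    if (max(lead) / min(lead) - 1 > 1e-9) return(NULL)  # unequal "ones"
    scale <- scale * mean(lead)
    counts[i] <- cnt
  }
  ord <- order(counts)  # stable in R: ties keep original index order
  structure(list(counts = counts[ord], row_order = ord, n = n, scale = scale),
            class = "staircase_spec")
}

#' Permanent of a staircase 0/1 matrix
#'
#' For sorted leading-one counts \eqn{n_1 \le \dots \le n_n} the permanent is
#' \eqn{\prod_i (n_i + 1 - i)}: row i must occupy one of its \eqn{n_i}
#' admissible columns not already taken by the i - 1 rows before it.
#'
#' @param spec a `staircase_spec` (from [to_staircase()]) or an integer
#'   vector of counts sorted ascending.
#' @return The permanent of the corresponding 0/1 matrix (the `scale` of a
#'   spec is *not* applied).
#' @export
staircase_permanent <- function(spec) {
  counts <- if (inherits(spec, "staircase_spec")) spec$counts else as.integer(spec)
  if (is.unsorted(counts))
    stop_permex("staircase counts must be sorted ascending", "permex_contract_error")
  n <- length(counts)
  factors <- counts + 1L - seq_len(n)
  if (any(factors <= 0L)) return(0)
  prod(factors)
}

#' Swap-probability matrix of a staircase matrix in polynomial time
#'
#' Fills the doubly stochastic matrix row by row (rows sorted ascending by
#' leading-one count): within row i, every admissible column j \eqn{\le n_i}
#' receives the column mass not yet spent by earlier rows, shared equally
#' over the \eqn{n_i - i + 1} columns still effectively open,
#' \deqn{P_{ij} = \frac{1 - \sum_{k < i} P_{kj}}{n_i - i + 1}, \quad j \le n_i.}
#' The result equals the permanent-ratio definition applied to the 0/1
#' matrix, at O(1) amortised work per entry.
#'
#' @param spec a `staircase_spec` or sorted integer counts.
#' @return A doubly stochastic matrix in the *original* row order of the
#'   spec (identity order when raw counts are given).
#' @export
staircase_p_matrix <- function(spec) {
  counts <- if (inherits(spec, "staircase_spec")) spec$counts else as.integer(spec)
  if (is.unsorted(counts))
    stop_permex("staircase counts must be sorted ascending", "permex_contract_error")
  n <- length(counts)
  if (staircase_permanent(counts) == 0)
    stop_permex("staircase permanent is zero: no state-ensemble matching exists",
                "permex_infeasible_error")
  P <- matrix(0, n, n)
  colspent <- numeric(n)
  for (i in seq_len(n)) {
    ni <- counts[i]
    j <- seq_len(ni)
    P[i, j] <- (1 - colspent[j]) / (ni - i + 1L)
    colspent[j] <- colspent[j] + P[i, j]
  }
  if (inherits(spec, "staircase_spec")) {
    out <- matrix(0, n, n)
    out[spec$row_order, ] <- P
    out
  } else P
}

# ---------------------------------------------------------------------------
# P-matrix
# ---------------------------------------------------------------------------

# internal: direct permanent-ratio evaluation for n <= 3 (hot in the
# scheduler for small free pools)
p_matrix_small <- function(W) {
  n <- nrow(W)
  if (n == 1L) {
    if (W[1L, 1L] <= 0)
      stop_permex("weight matrix permanent is zero: no state-ensemble matching exists",
                  "permex_infeasible_error")
    return(matrix(1, 1L, 1L))
  }
  if (n == 2L) {
    a <- W[1L, 1L] * W[2L, 2L]; b <- W[1L, 2L] * W[2L, 1L]
    total <- a + b
    if (total <= 0)
      stop_permex("weight matrix permanent is zero: no state-ensemble matching exists",
                  "permex_infeasible_error")
    return(matrix(c(a, b, b, a), 2L, 2L) / total)
  }
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  P <- matrix(0, 3L, 3L)
  total <- 0
  for (s in perms) {
    wprod <- W[1L, s[1L]] * W[2L, s[2L]] * W[3L, s[3L]]
    if (wprod == 0) next
    total <- total + wprod
    P[cbind(1:3, s)] <- P[cbind(1:3, s)] + wprod
  }
  if (total <= 0)
    stop_permex("weight matrix permanent is zero: no state-ensemble matching exists",
                "permex_infeasible_error")
  P / total
}

# internal: Eq.-5 P-matrix of one irreducible block via BBFG permanents
p_matrix_bbfg <- function(B, cap = 20L) {
  n <- nrow(B)
  if (n == 1L) return(matrix(1, 1L, 1L))
  # row scaling leaves P invariant and stabilises the permanent ratios
  rmax <- apply(B, 1L, max)
  if (any(rmax == 0))
    stop_permex("weight matrix permanent is zero: no state-ensemble matching exists",
                "permex_infeasible_error")
  Bs <- B / rmax
  total <- permanent_bbfg(Bs, cap = cap)
  if (total <= 0)
    stop_permex("weight matrix permanent is zero: no state-ensemble matching exists",
                "permex_infeasible_error")
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (Bs[i, j] == 0) next
    P[i, j] <- Bs[i, j] * permanent_bbfg(Bs[-i, -j, drop = FALSE], cap = cap) / total
  }
  P
}

#' Doubly stochastic swap-probability matrix of a weight matrix
#'
#' Computes \eqn{P_{ij} = W_{ij}\,\mathrm{perm}(W^{\{ij\}}) / \mathrm{perm}(W)},
#' the probability that state i ends up in ensemble j when all
#' state-to-ensemble permutations are sampled with their stationary weights
#' (infinite swapping).  The matrix is computed blockwise after
#' [block_decompose()]; each block takes the polynomial staircase route when
#' [to_staircase()] recognises it and exact BBFG permanents otherwise.
#'
#' @param W square nonnegative matrix with perm(W) > 0.
#' @param cap BBFG dimension cap, passed through.
#' @return Doubly stochastic matrix of the same shape, with `P[i, j] = 0`
#'   wherever `W[i, j] = 0`.
#' @export
p_matrix <- function(W, cap = 20L) {
  check_square(W)
  n <- nrow(W)
  if (n == 0L) return(matrix(0, 0L, 0L))
  if (n <= 3L) return(p_matrix_small(W))
  sc <- to_staircase(W)
  if (!is.null(sc)) return(staircase_p_matrix(sc))
  bd <- block_decompose(W)
  Wp <- W[bd$row_order, bd$col_order, drop = FALSE]
  P <- matrix(0, n, n)
  for (blk in bd$blocks) {
    B <- Wp[blk, blk, drop = FALSE]
    sc <- to_staircase(B)
    Pb <- if (!is.null(sc)) staircase_p_matrix(sc) else p_matrix_bbfg(B, cap = cap)
    P[blk, blk] <- Pb
  }
  out <- matrix(0, n, n)
  out[bd$row_order, bd$col_order] <- P
  out
}
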