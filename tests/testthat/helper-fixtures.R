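# Shared fixtures built in code.

# random nonnegative matrix with optional zero entries, guaranteed perm > 0
# (diagonal kept positive)
random_w <- function(n, p_zero = 0.3) {
  W <- matrix(stats::runif(n * n, 0.1, 2), n, n)
  mask <- matrix(stats::runif(n * n) < p_zero, n, n)
  diag(mask) <- FALSE
  W[mask] <- 0
  W
}

# random valid staircase counts: sorted ascending with counts[i] >= i
random_staircase_counts <- function(n) {
  counts <- sort(sample.int(n, n, replace = TRUE))
  counts <- pmax(counts, seq_len(n))
  sort(counts)
}

staircase_01 <- function(counts) {
  n <- length(counts)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, seq_len(counts[i])] <- 1
  W
}

# random block-lower-triangular matrix from given block sizes, then a random
# row/column shuffle
random_block_matrix <- function(sizes) {
  n <- sum(sizes)
  W <- matrix(0, n, n)
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    W[idx, idx] <- matrix(stats::runif(s * s, 0.2, 1), s, s)
    if (at > 0L) {
      below <- (at + 1L):n
      # cross-block entries allowed below-left only
      W[idx, seq_len(at)] <- matrix(stats::runif(s * at) *
                                      (stats::runif(s * at) < 0.4), s, at)
    }
    at <- at + s
  }
  W[sample.int(n), sample.int(n), drop = FALSE]
}

# synthetic path states for indicator tests
fake_plus_path <- function(lambda_max, valid = TRUE, duration = 1)
  list(x = NULL, v = NULL, kind = "plus", valid = valid,
       lambda_max = lambda_max, L = 10L, duration = duration)

fake_minus_path <- function(valid = TRUE, duration = 1)
  list(x = NULL, v = NULL, kind = "minus", valid = valid,
       lambda_max = -0.8, L = 10L, duration = duration)

# a fast Langevin parameter set for tests
test_lv_params <- function() langevin_params(barrier = 2, gamma = 1,
                                             temperature = 1, dt = 0.05)
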