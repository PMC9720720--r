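test_that("naive permanent matches hand values and rejects bad input", {
  expect_equal(permanent_naive(matrix(7, 1, 1)), 7)
  expect_equal(permanent_naive(matrix(1, 2, 2)), 2)
  expect_equal(permanent_naive(diag(4)), 1)
  expect_error(permanent_naive(matrix(1, 2, 3)), class = "permex_structural_error")
  expect_error(permanent_naive(matrix(-1, 1, 1)), class = "permex_structural_error")
})

test_that("BBFG permanent agrees with the minor-expansion oracle", {
  expect_equal(permanent_bbfg(rbind(c(2, 1), c(1, 1))), 3)
  set.seed(101)
  M <- matrix(runif(49), 7, 7)
  expect_equal(permanent_bbfg(M), permanent_naive(M), tolerance = 1e-12)
  Z <- matrix(runif(16), 4, 4); Z[2, ] <- 0
  expect_equal(permanent_bbfg(Z), 0)
  expect_error(permanent_bbfg(diag(5), cap = 4L), "cap of 4",
               class = "permex_capacity_error")
})

test_that("BBFG equals the oracle on random matrices up to n = 7", {
  set.seed(202)
  for (rep in 1:500) {
    n <- sample(1:7, 1)
    M <- matrix(runif(n * n), n, n)
    if (runif(1) < 0.3) M[runif(n * n) < 0.3] <- 0
    pn <- permanent_naive(M)
    expect_lt(abs(permanent_bbfg(M) - pn) / max(1, pn), 1e-9)
  }
})

test_that("block decomposition reproduces the canonical zero patterns", {
  set.seed(7)
  W <- matrix(runif(16) + 0.5, 4, 4)
  W[1:3, 4] <- 0                       # one 3x3 and one 1x1 block
  bd <- block_decompose(W)
  expect_setequal(vapply(bd$blocks, length, 1L), c(3L, 1L))
  W2 <- matrix(runif(16) + 0.5, 4, 4)
  W2[1:2, 3:4] <- 0                    # two 2x2 blocks
  expect_equal(vapply(block_decompose(W2)$blocks, length, 1L), c(2L, 2L))
  dense <- matrix(runif(9) + 0.5, 3, 3)
  expect_length(block_decompose(dense)$blocks, 1L)
})

test_that("blockwise permanents equal whole-matrix BBFG on random block structures", {
  set.seed(303)
  for (rep in 1:200) {
    nb <- sample(1:3, 1)
    sizes <- sample(1:4, nb, replace = TRUE)
    if (sum(sizes) > 10) sizes <- sizes[1]
    W <- random_block_matrix(sizes)
    expect_equal(permex:::perm_exact(W), permanent_bbfg(W),
                 tolerance = 1e-9)
  }
})

test_that("P-matrix matches the permanent-ratio definition on hand cases", {
  expect_equal(p_matrix(diag(2)), diag(2))
  n <- 5
  expect_equal(p_matrix(matrix(1, n, n)), matrix(1 / n, n, n))
  expect_equal(p_matrix(rbind(c(2, 1), c(1, 1))),
               rbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3)))
  expect_error(p_matrix(rbind(c(1, 0), c(1, 0))),
               class = "permex_infeasible_error")
})

test_that("P-matrices are bistochastic with zeros preserved", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:7, 1)
    W <- random_w(n)
    P <- p_matrix(W)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_lt(max(abs(colSums(P) - 1)), 1e-10)
    expect_true(all(P[W == 0] == 0))
  }
})

test_that("P-matrix is invariant to row scaling and equivariant to permutation", {
  set.seed(505)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    W <- random_w(n)
    P <- p_matrix(W)
    W2 <- W
    i <- sample.int(n, 1)
    W2[i, ] <- W2[i, ] * runif(1, 0.01, 100)
    expect_lt(max(abs(p_matrix(W2) - P)), 1e-10)
    rp <- sample.int(n); cp <- sample.int(n)
    expect_lt(max(abs(p_matrix(W[rp, cp]) - P[rp, cp])), 1e-10)
    expect_equal(permanent_bbfg(W[rp, cp]), permanent_bbfg(W), tolerance = 1e-9)
  }
})

test_that("staircase recognition sorts counts and refuses non-staircase rows", {
  W <- rbind(c(1, 1, 0), c(1, 1, 1), c(1, 0, 0))
  sc <- to_staircase(W)
  expect_equal(sc$counts, c(1L, 2L, 3L))
  expect_equal(sc$row_order, c(3L, 1L, 2L))
  expect_null(to_staircase(rbind(c(1, 0, 1), c(1, 1, 1), c(1, 1, 1))))
  # per-row positive scaling is divided out
  W2 <- rbind(c(3, 3, 0), c(1, 1, 0), c(2, 2, 2))
  sc2 <- to_staircase(W2)
  expect_equal(sc2$counts, c(2L, 2L, 3L))
  expect_equal(sc2$scale, 3 * 1 * 2)
})

test_that("staircase permanent is the product of (n_i + 1 - i)", {
  expect_equal(staircase_permanent(c(2, 2, 3)), 2)
  n <- 5
  expect_equal(staircase_permanent(rep(n, n)), factorial(n))
  expect_equal(staircase_permanent(c(1, 1)), 0)
  expect_error(staircase_permanent(c(3, 2)), class = "permex_contract_error")
})

test_that("fast staircase P-matrix equals the permanent-ratio definition", {
  expect_equal(staircase_p_matrix(c(1, 2)), diag(2))
  expect_equal(staircase_p_matrix(c(2, 2)), matrix(0.5, 2, 2))
  expect_equal(staircase_p_matrix(c(2, 2, 3)),
               permex:::p_matrix_bbfg(staircase_01(c(2, 2, 3))))
  expect_error(staircase_p_matrix(c(1, 1)), class = "permex_infeasible_error")
})

test_that("staircase closed forms equal BBFG on random specs up to n = 12", {
  set.seed(606)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    counts <- random_staircase_counts(n)
    W <- staircase_01(counts)
    expect_equal(staircase_permanent(counts), permanent_bbfg(W),
                 tolerance = 1e-9)
    expect_lt(max(abs(staircase_p_matrix(counts) -
                      permex:::p_matrix_bbfg(W))), 1e-10)
  }
})
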