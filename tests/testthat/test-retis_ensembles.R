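test_that("interface sets must be strictly increasing", {
  expect_silent(interface_set(c(-1, 0, 1)))
  expect_error(interface_set(c(0, 0, 1)), class = "permex_contract_error")
  expect_error(interface_set(0.5), class = "permex_contract_error")
})

test_that("path indicators implement the start/end/crossing conditions", {
  ens <- path_ensembles(interface_set(c(-0.8, -0.4, 0, 0.4, 0.8)))
  expect_equal(vapply(ens, function(e) e$id, ""),
               c("[0-]", "[0+]", "[1+]", "[2+]", "[3+]"))
  # lambda_max between lambda_2 and lambda_3: in [0+], [1+], [2+], not [3+]
  p <- fake_plus_path(lambda_max = 0.2)
  ind <- vapply(ens, function(e) path_indicator(p, e), 1L)
  expect_equal(ind, c(0L, 1L, 1L, 1L, 0L))
  # [0-] paths fit only [0-]
  m <- fake_minus_path()
  expect_equal(vapply(ens, function(e) path_indicator(m, e), 1L),
               c(1L, 0L, 0L, 0L, 0L))
  # failing the structural start condition excludes every [k+]
  bad <- fake_plus_path(lambda_max = 0.9, valid = FALSE)
  expect_equal(sum(vapply(ens, function(e) path_indicator(bad, e), 1L)), 0L)
})

test_that("indicator membership is monotone in rank for random paths", {
  set.seed(31)
  ens <- path_ensembles(interface_set(seq(-0.8, 0.8, length.out = 6)))
  for (rep in 1:200) {
    p <- if (runif(1) < 0.2) fake_minus_path() else
      fake_plus_path(lambda_max = runif(1, -0.8, 1.2))
    ind <- vapply(ens, function(e) path_indicator(p, e), 1L)
    plus <- ind[-1]
    expect_true(all(diff(plus) <= 0))        # monotone across ranks
    expect_true(ind[1] == 0 || all(plus == 0))  # [0-] exclusive
  }
})

test_that("W-matrix assembly orders columns by rank and yields the staircase", {
  # pool with crossing ranks (>=1, >=3, >=1) over free [0+], [1+], [2+]
  ifs <- interface_set(c(0, 1, 2, 3))
  ens <- path_ensembles(ifs)[2:4]
  pool <- list(fake_plus_path(1.5), fake_plus_path(3.0), fake_plus_path(1.2))
  bw <- build_w_matrix(pool, ens)
  sc <- to_staircase(bw$W)
  expect_equal(sc$counts, c(2L, 2L, 3L))
  # a free [0-] forms a 1x1 block
  ens4 <- path_ensembles(ifs)[1:4]
  pool4 <- c(list(fake_minus_path()), pool)
  bw4 <- build_w_matrix(pool4, ens4)
  bd <- block_decompose(bw4$W)
  expect_true(1L %in% vapply(bd$blocks, length, 1L))
  P <- p_matrix(bw4$W)
  expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  expect_error(build_w_matrix(pool, ens4), class = "permex_contract_error")
})

test_that("shooting moves reject trials that miss the target interface", {
  set.seed(32)
  p <- test_lv_params()
  lam <- c(-0.75, -0.45, -0.15, 0.15, 0.6)
  dyn <- list(params = p, lambdas = lam)
  ens <- path_ensembles(interface_set(lam))
  seed_path <- permex:::ramp_path(lam[1], lam[2], p$dt, "plus")
  # shoot repeatedly in the top ensemble [3+]: most trials fall back early
  top <- ens[[5]]
  start <- permex:::ramp_path(lam[1], lam[5], p$dt, "plus")
  wr <- replicate(60, shooting_move(start, top, dyn)$proposal$weight_ratio)
  expect_true(any(wr == 0))     # some trials fail the crossing condition
  # every nonzero weight ratio is the slice-count ratio
  mv <- shooting_move(seed_path, ens[[2]], dyn)
  if (mv$proposal$weight_ratio > 0) {
    expect_equal(mv$proposal$weight_ratio,
                 length(seed_path$x) / length(mv$proposal$new_state$x))
  }
  expect_gt(mv$duration, 0)
})

test_that("shooting within [0+] keeps a valid stationary ensemble", {
  set.seed(33)
  p <- test_lv_params()
  lam <- c(-0.75, -0.45, -0.15, 0.15, 0.6)
  dyn <- list(params = p, lambdas = lam)
  e0p <- path_ensembles(interface_set(lam))[[2]]
  path <- permex:::ramp_path(lam[1], lam[2], p$dt, "plus")
  acc <- 0L
  for (i in 1:300) {
    mv <- shooting_move(path, e0p, dyn)
    if (metropolis_accept(mv$proposal)) {
      path <- mv$proposal$new_state
      acc <- acc + 1L
    }
    expect_equal(path_indicator(path, e0p), 1L)
  }
  expect_gt(acc, 0L)
  expect_lt(acc, 300L)   # acceptance strictly between 0 and 1
})

test_that("point exchange produces structurally valid partner paths", {
  set.seed(34)
  p <- test_lv_params()
  lam <- c(-0.75, -0.45, -0.15, 0.15, 0.6)
  dyn <- list(params = p, lambdas = lam)
  ens <- path_ensembles(interface_set(lam))
  # build genuine incumbents by shooting from the ramps
  p0m <- permex:::ramp_path(lam[1], lam[1] - 0.4, p$dt, "minus")
  p0p <- permex:::ramp_path(lam[1], lam[2], p$dt, "plus")
  for (i in 1:20) {
    mv <- shooting_move(p0m, ens[[1]], dyn)
    if (metropolis_accept(mv$proposal)) p0m <- mv$proposal$new_state
    mv <- shooting_move(p0p, ens[[2]], dyn)
    if (metropolis_accept(mv$proposal)) p0p <- mv$proposal$new_state
  }
  pe <- point_exchange_move(p0m, p0p, dyn)
  expect_true(pe$accepted)
  expect_equal(path_indicator(pe$new0m, ens[[1]]), 1L)
  expect_equal(path_indicator(pe$new0p, ens[[2]]), 1L)
  # the new [0-] path lies below lambda_0 except at its endpoints
  interior <- pe$new0m$x[-c(1, length(pe$new0m$x))]
  expect_true(all(interior < lam[1]))
  expect_gte(pe$new0m$x[1], lam[1])
  expect_gte(pe$new0m$x[length(pe$new0m$x)], lam[1])
  # MSVS has no [0-]: the move is not offered
  expect_null(msvs_system()$point_exchange)
})

test_that("initial states satisfy their ensemble indicators for all systems", {
  for (sys in list(msvs_system(msvs_params(n_local = 5L)), discrete_toy(),
                   langevin_double_well(test_lv_params()))) {
    init <- initialize_states(sys)
    ok <- vapply(seq_along(init), function(i)
      sys$ensembles[[i]]$indicator(init[[i]]), 1L)
    expect_equal(ok, rep(1L, length(init)))
  }
})
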