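test_that("free-pair picks are uniform over unordered pairs", {
  set.seed(41)
  expect_null(pick_free_pair(7L))
  expect_setequal(pick_free_pair(c(2L, 9L)), c(2L, 9L))
  free <- c(1L, 2L, 3L)
  n <- 3e4
  draws <- replicate(n, paste(sort(pick_free_pair(free)), collapse = "-"))
  tab <- table(draws) / n
  expect_equal(length(tab), 3L)
  expect_lt(max(abs(tab - 1 / 3)), 4 * sqrt((1 / 3) * (2 / 3) / n))
})

test_that("worker assignment is uniform over the free ensembles", {
  set.seed(42)
  expect_equal(assign_worker(5L), 5L)
  n <- 2e4
  draws <- replicate(n, assign_worker(c(4L, 8L)))
  f <- mean(draws == 4L)
  expect_lt(abs(f - 0.5), 4 * sqrt(0.25 / n))
  expect_error(assign_worker(integer(0)), class = "permex_internal_error")
})

test_that("K = N leaves no room for swaps and reduces to independent chains", {
  toy <- discrete_toy()
  run <- run_scheduler(toy, scheduler_config(3L, "finite", p_re = 0.9,
                                             stop_moves = 5000L, seed = 43))
  expect_equal(run$swap_attempts, 0L)
  marg <- sampled_marginals(run)
  expect_lt(max(abs(marg - toy$exact_marginals)), 0.05)
})

test_that("runs are bit-reproducible for identical config and seed", {
  toy <- discrete_toy()
  cfg <- scheduler_config(2L, "infinite", stop_moves = 1500L, seed = 44,
                          record = "trace")
  a <- run_scheduler(toy, cfg)
  b <- run_scheduler(toy, cfg)
  expect_identical(a$records$trace, b$records$trace)
  expect_identical(a$clock, b$clock)
  c2 <- run_scheduler(toy, scheduler_config(2L, "infinite",
                                            stop_moves = 1500L, seed = 45,
                                            record = "trace"))
  expect_false(identical(a$records$trace, c2$records$trace))
})

test_that("two identical ensembles share the pooled states equally", {
  # two ensembles with identical weights over two states: by symmetry each
  # ensemble's accumulated fractional mass per state tends to 1/2
  set.seed(46)
  toy <- discrete_toy(weights = rbind(c(1, 1), c(1, 1)))
  run <- run_scheduler(toy, scheduler_config(1L, "infinite",
                                             stop_moves = 2e4, seed = 46))
  marg <- sampled_marginals(run)
  expect_lt(max(abs(marg - 0.5)), 4 * sqrt(0.25 / (run$events / 2)))
})

test_that("finite mode with p_re = 0 keeps exact per-ensemble marginals", {
  toy <- discrete_toy()
  run <- run_scheduler(toy, scheduler_config(2L, "finite", p_re = 0,
                                             stop_moves = 3e4, seed = 47))
  expect_equal(run$swap_attempts, 0L)
  marg <- sampled_marginals(run)
  expect_lt(max(abs(marg - toy$exact_marginals)), 0.03)
})

test_that("finite and infinite modes agree on the toy marginals", {
  toy <- discrete_toy()
  fin <- run_scheduler(toy, scheduler_config(1L, "finite", p_re = 0.9,
                                             stop_moves = 3e4, seed = 48))
  inf <- run_scheduler(toy, scheduler_config(1L, "infinite",
                                             stop_moves = 3e4, seed = 48))
  expect_lt(max(abs(sampled_marginals(fin) - sampled_marginals(inf))), 0.03)
  expect_lt(max(abs(sampled_marginals(inf) - toy$exact_marginals)), 0.03)
})

test_that("fractional weights per (event, ensemble) sum to one", {
  toy <- discrete_toy()
  run <- run_scheduler(toy, scheduler_config(1L, "infinite",
                                             stop_moves = 800L, seed = 49,
                                             record = "trace"))
  tr <- run$records$trace
  sums <- tapply(tr$weight, interaction(tr$clock, tr$ensemble, drop = TRUE), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  # and per (event, state): each pooled state lands somewhere (row sums)
  sums2 <- tapply(tr$weight, interaction(tr$clock, tr$state_id, drop = TRUE), sum)
  expect_lt(max(abs(sums2 - 1)), 1e-10)
})

test_that("the state count is conserved across a run", {
  # pool plus in-flight states always total N: indirectly asserted by the
  # engine's internal consistency check, and the run completes
  sys <- msvs_system(msvs_params(n_local = 8L))
  run <- run_scheduler(sys, scheduler_config(3L, "infinite",
                                             stop_moves = 4000L, seed = 50))
  expect_equal(run$events, 4000L)
  expect_equal(sum(run$moves_completed), 4000L)
  # every ensemble got sampled
  expect_true(all(rowSums(run$records$mass) > 0))
})

test_that("consumed MD time scales linearly with worker count on MSVS", {
  sys <- msvs_system()
  ks <- c(1L, 5L, 10L, 15L)
  busy <- vapply(ks, function(k) {
    run_scheduler(sys, scheduler_config(k, "infinite", stop_time = 300,
                                        seed = 51))$busy_time
  }, 1)
  fit <- lm(busy ~ ks)
  expect_gt(summary(fit)$r.squared, 0.99)
})
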