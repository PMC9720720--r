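# minimal hand-built run object for estimator arithmetic
fake_run <- function(num, den, dur, mass, ranks, burn_in = 0) {
  structure(list(
    config = list(burn_in = burn_in), ranks = ranks,
    ensemble_ids = paste0("e", seq_along(ranks)),
    clock = 1, busy_time = 1, events = ncol(num),
    records = list(num = num, den = den, dur = dur, mass = mass,
                   nchunk = rep(ncol(num), nrow(num)), marginal = NULL)
  ), class = "permex_run")
}

test_that("local crossing probability is the weighted crossed fraction", {
  # hand-built 4-record set: weights (0.5, 0.5, 1, 1), crossings (1, 0, 1, 0)
  df <- data.frame(weight = c(0.5, 0.5, 1, 1), crossed = c(1, 0, 1, 0))
  expect_equal(local_crossing_probability(df)$p, 0.5)
  all1 <- data.frame(weight = rep(1, 5), crossed = rep(1, 5))
  expect_equal(local_crossing_probability(all1)$p, 1)
  expect_error(local_crossing_probability(df[0, ]),
               class = "permex_undefined_error")
  # 1/w reweighting: inverse high-acceptance weights shift the average
  dfw <- data.frame(weight = c(1, 1), crossed = c(1, 0), inv_ha = c(3, 1))
  expect_equal(local_crossing_probability(dfw)$p, 0.75)
})

test_that("overall crossing probability is the product with quadrature errors", {
  expect_equal(overall_crossing_probability(c(0.5, 0.5))$p_cross, 0.25)
  expect_equal(overall_crossing_probability(0.37)$p_cross, 0.37)
  ov <- overall_crossing_probability(c(0.1, 0.1), rel_errs = c(0.3, 0.4))
  expect_equal(ov$rel_err, 0.5)
})

test_that("flux and rate combine mean path durations and P_cross", {
  k <- 20
  run <- fake_run(num = rbind(rep(0, k), rep(0.1, k)),
                  den = rbind(rep(1, k), rep(1, k)),
                  dur = rbind(rep(2, k), rep(3, k)),
                  mass = rbind(rep(1, k), rep(1, k)),
                  ranks = c(-1L, 0L))
  rr <- flux_and_rate(run, crossing = list(local = NULL, p_cross = 0.1,
                                           rel_err = 0))
  expect_equal(rr$flux, 1 / 5)
  expect_equal(rr$rate, 0.02)
  # doubling both mean durations halves the flux
  run2 <- fake_run(num = rbind(rep(0, k), rep(0.1, k)),
                   den = rbind(rep(1, k), rep(1, k)),
                   dur = rbind(rep(4, k), rep(6, k)),
                   mass = rbind(rep(1, k), rep(1, k)),
                   ranks = c(-1L, 0L))
  rr2 <- flux_and_rate(run2, crossing = list(local = NULL, p_cross = 0.1,
                                             rel_err = 0))
  expect_equal(rr2$flux, rr$flux / 2)
  # MSVS-like runs without [0-] have no flux
  run3 <- fake_run(num = matrix(0.1, 1, k), den = matrix(1, 1, k),
                   dur = matrix(1, 1, k), mass = matrix(1, 1, k), ranks = 0L)
  expect_error(flux_and_rate(run3), class = "permex_undefined_error")
})

test_that("block errors match the i.i.d. closed form and shrink with length", {
  expect_equal(block_error(rep(3, 100)), 0)
  expect_error(block_error(1:5, n_blocks = 10L), class = "permex_contract_error")
  set.seed(61)
  mu <- 10; n <- 1000; reps <- 200
  errs <- replicate(reps, block_error(rnorm(n, mu, 1)))
  expected <- 1 / (mu * sqrt(n))
  expect_lt(abs(mean(errs) - expected), 4 * sd(errs) / sqrt(reps))
  # doubling the series length shrinks the error by ~ sqrt(2)
  errs2 <- replicate(reps, block_error(rnorm(2 * n, mu, 1)))
  expect_lt(abs(mean(errs) / mean(errs2) - sqrt(2)), 0.15)
})

test_that("unit weights make weighted and unweighted estimates identical", {
  set.seed(62)
  x <- rbinom(500, 1, 0.3)
  df <- data.frame(weight = rep(1, 500), crossed = x, inv_ha = rep(1, 500))
  expect_identical(local_crossing_probability(df)$p, mean(x))
})

test_that("efficiency is the inverse of time times squared error", {
  run <- fake_run(num = matrix(0.1, 1, 20), den = matrix(1, 1, 20),
                  dur = matrix(1, 1, 20), mass = matrix(1, 1, 20), ranks = 0L)
  run$clock <- 1; run$busy_time <- 1
  eff <- efficiency(run, rel_err = 1)
  expect_equal(eff$wall, 1)
  expect_equal(eff$cpu, 1)
  # busy time across K workers never exceeds K times the wall clock
  sys <- msvs_system(msvs_params(n_local = 10L))
  r <- run_scheduler(sys, scheduler_config(4L, "infinite",
                                           stop_moves = 2000L, seed = 63))
  e <- efficiency(r, rel_err = 0.5)
  expect_lte(e$wall / e$cpu, 4 + 1e-9)
  expect_gte(e$wall / e$cpu, 1 - 1e-9)
})

test_that("MSVS engine estimates recover the per-rank crossing probability", {
  sys <- msvs_system(msvs_params(n_local = 6L))
  run <- run_scheduler(sys, scheduler_config(2L, "infinite",
                                             stop_moves = 2e4, seed = 64))
  ca <- crossing_analysis(run)
  expect_equal(nrow(ca$local), 6L)
  for (i in seq_len(6)) {
    se <- ca$local$p_local[i] * ca$local$rel_err[i]
    expect_lt(abs(ca$local$p_local[i] - 0.1), 4 * max(se, 0.004))
  }
  expect_equal(ca$p_cross, prod(ca$local$p_local))
})
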