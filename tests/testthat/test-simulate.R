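test_that("gillespie terminates immediately in an absorbing state", {
  r <- rates_1d(make_symmetric_game("neutral"), chain_params(20, 0.1, 0))
  tr <- gillespie(r, 0, seed = 1)
  expect_true(tr$absorbed)
  expect_identical(tr$time, 0)
  expect_identical(tr$events, 0)
})

test_that("a fixed seed reproduces a bit-identical trajectory", {
  r <- rates_1d(make_symmetric_game("dominance"), chain_params(50, 0.1, 0.1))
  tr1 <- gillespie(r, 25, seed = 77, record_path = TRUE)
  tr2 <- gillespie(r, 25, seed = 77, record_path = TRUE)
  expect_identical(tr1$times, tr2$times)
  expect_identical(tr1$states, tr2$states)
  # event times strictly increase; states move by unit steps
  expect_true(all(diff(tr1$times) > 0))
  expect_true(all(abs(diff(tr1$states)) == 1))
})

test_that("censoring by time horizon and by event cap is flagged distinctly", {
  r <- rates_1d(make_symmetric_game("coexistence"), chain_params(200, 0.1, 0.2))
  tr_t <- gillespie(r, 100, seed = 5, t_max = 1)
  expect_true(tr_t$censored)
  expect_false(tr_t$absorbed)
  expect_identical(tr_t$time, 1)
  tr_e <- gillespie(r, 100, seed = 5, max_events = 100)
  expect_true(tr_e$censored)
  expect_identical(tr_e$events, 100)
})

test_that("neutral chain fixes at n = N with probability n0/N", {
  r <- rates_1d(make_symmetric_game("neutral"), chain_params(50, 0.1, 0))
  ens <- simulate_ensemble(r, 25, 2000, seed = 11)
  mc <- mc_fixation_stats(ens)
  expect_identical(mc$n_censored, 0L)
  expect_lt(abs(mc$fixation_prob_upper - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("every replicate of the 1D chain absorbs in finite time", {
  for (gn in names(fixture_games())) {
    r <- rates_1d(make_symmetric_game(gn), chain_params(100, 0.1, 0.2))
    ens <- simulate_ensemble(r, 50, 500, seed = 13, max_events = 1e8)
    expect_true(all(ens$absorbed))
    expect_false(any(ens$censored))
  }
})

test_that("ensemble mean path approaches the deterministic flow as N grows", {
  g <- make_symmetric_game("coexistence")
  p <- dyn_params(lam = 0.2)
  tg <- seq(0.1, 5, length.out = 25)
  ode <- integrate_flow(function(x) sc_flow_1d(g, x, p), 0.2, 5, n_out = 500)
  x_det <- stats::approx(ode$t, ode$x, tg)$y
  sup_err <- vapply(c(100, 1000), function(N) {
    r <- rates_1d(g, chain_params(N, 0.1, 0.2))
    ens <- simulate_ensemble(r, round(0.2 * N), 200, seed = 33,
                             sample_times = tg)
    max(abs(colMeans(ens$samples / N) - x_det))
  }, numeric(1))
  expect_lt(sup_err[2], sup_err[1])
})

test_that("triplet microsimulation refuses the entropic regime", {
  expect_error(triplet_microsim(make_symmetric_game("neutral"),
                                chain_params(50, 0.1, 0.2), 25, 100),
               "lam = 0 only")
})

test_that("triplet microsimulation reproduces the birth-death rates", {
  # neutral game: up and down frequencies agree at every visited state
  tn <- triplet_microsim(make_symmetric_game("neutral"),
                         chain_params(60, 0.1, 0, seed = 2), 30, 5e5,
                         restart_on_absorption = TRUE)
  vis <- which(tn$attempts >= 500)
  expect_gt(length(vis), 10)
  p_pool <- (tn$ups[vis] + tn$downs[vis]) / (2 * tn$attempts[vis])
  z <- (tn$up_freq[vis] - tn$down_freq[vis]) /
    sqrt(2 * p_pool * (1 - p_pool) / tn$attempts[vis])
  expect_lt(mean(abs(z) > 3), 0.05)

  # dominance fixture: per-state frequencies match T+-/N predictions
  ts <- triplet_microsim(make_symmetric_game("dominance"),
                         chain_params(100, 0.1, 0, seed = 1), 50, 1e6,
                         restart_on_absorption = TRUE)
  vis <- which(ts$attempts >= 500)
  expect_gt(length(vis), 20)
  z_up <- binom_z(ts$up_freq[vis], ts$up_pred[vis], ts$attempts[vis])
  z_dn <- binom_z(ts$down_freq[vis], ts$down_pred[vis], ts$attempts[vis])
  zs <- c(z_up, z_dn)
  # per-state 3-se check with a multiplicity allowance across ~100 states
  expect_lt(mean(abs(zs) > 3), 0.05)
  expect_true(all(abs(zs) < 4.5))
})
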