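test_that("single-transient-state chain has the exact escape time", {
  r <- rates_1d(make_symmetric_game("neutral"), chain_params(2, 0.1, 0))
  expect_equal(r$Tplus[2], 0.25)
  cf <- fixation_closed_form_1d(r, 1)
  expect_equal(cf$mean_time, 2)  # 1 / (T+ + T-)
  expect_equal(cf$fixation_prob_upper, 0.5)
})

test_that("neutral fixation probability is n0/N and tau matches the diffusion limit", {
  N <- 200
  r <- rates_1d(make_symmetric_game("neutral"), chain_params(N, 0.1, 0))
  cf <- fixation_closed_form_1d(r, 0:N)
  expect_equal(cf$fixation_prob_upper, (0:N) / N, tolerance = 1e-12)
  # backward diffusion equation with sigma^2 = (T+ + T-)/N^2 = x(1-x)/N:
  # (sigma^2/2) tau'' = -1 gives tau(1/2) = 2 N ln 2
  expect_lt(abs(cf$tau[N / 2 + 1] - 2 * N * log(2)) / (2 * N * log(2)), 0.02)
})

test_that("closed form and backward-equation solve agree to 1e-8", {
  for (gn in names(fixture_games())) for (lam in c(0, 0.2)) {
    r <- rates_1d(make_symmetric_game(gn), chain_params(100, 0.1, lam))
    cf <- fixation_closed_form_1d(r, 50)
    ls <- fixation_linear_solve(r)
    expect_identical(ls$tau[c(1, 101)], c(0, 0))
    expect_lt(max(abs(cf$tau - ls$tau) / pmax(cf$tau, 1)), 1e-8)
  }
})

test_that("monte-carlo statistics track the exact solver", {
  r <- rates_1d(make_symmetric_game("dominance"), chain_params(100, 0.1, 0.2))
  cf <- fixation_closed_form_1d(r, 50)
  ens <- simulate_ensemble(r, 50, 500, seed = 1)
  mc <- mc_fixation_stats(ens)
  expect_lt(abs(mc$mean_time - cf$mean_time), 3 * mc$se)
  expect_identical(mc$n_absorbed, 500L)
  # degenerate ensemble: already absorbed
  ens0 <- simulate_ensemble(r, 0, 5, seed = 1)
  mc0 <- mc_fixation_stats(ens0)
  expect_identical(mc0$mean_time, 0)
  expect_identical(mc0$se, 0)
})

test_that("coordination fixation goes overwhelmingly to n = N above the barrier", {
  g <- make_symmetric_game("coordination")
  r <- rates_1d(g, chain_params(200, 0.1, 0.2))
  # initial condition above the interior unstable point (x ~ 0.27)
  ens <- simulate_ensemble(r, 100, 400, seed = 21)
  mc <- mc_fixation_stats(ens)
  expect_gte(mc$fixation_prob_upper, 0.95)
})

test_that("coexistence fixation time grows approximately exponentially in lambda", {
  g <- make_symmetric_game("coexistence")
  lams <- seq(0.02, 0.5, length.out = 13)
  tau <- vapply(lams, function(l) {
    fixation_closed_form_1d(rates_1d(g, chain_params(200, 0.1, l)), 100)$mean_time
  }, numeric(1))
  expect_true(all(diff(tau) > 0))
  fit <- summary(stats::lm(log(tau) ~ lams))
  expect_gt(fit$r.squared, 0.98)
})

test_that("2D backward solve: zero at corners, MP heat map peaks at the centre", {
  mp <- make_asymmetric_game("matching_pennies")
  N <- 30
  r <- rates_2d(mp, chain_params(N, 0.1, 0.3))
  fx <- fixation_linear_solve(r)
  expect_equal(fx$tau[1, 1], 0)
  expect_equal(fx$tau[N + 1, N + 1], 0)
  expect_equal(fx$tau[1, N + 1], 0)
  expect_equal(fx$tau[N + 1, 1], 0)
  expect_true(all(fx$tau[2:N, 2:N] > 0))
  am <- which(fx$tau == max(fx$tau), arr.ind = TRUE) - 1L
  expect_lte(max(abs(am - N / 2)), 3)
  # cross-check against Monte Carlo from the centre
  ens <- simulate_ensemble(r, c(15, 15), 400, seed = 3)
  mc <- mc_fixation_stats(ens)
  expect_lt(abs(mc$mean_time - fx$tau[16, 16]), 3 * mc$se)
})

test_that("scaling fits recover synthetic laws and report their windows", {
  Ns <- c(50, 100, 200, 400, 800)
  # exact synthetic laws: lm warns about the perfect fit, which is the point
  suppressWarnings({
    f_pow <- fit_scaling(Ns, 3 * Ns, "power_law")
    f_exp <- fit_scaling(Ns, 2 * exp(0.01 * Ns), "exponential")
    f_log <- fit_scaling(Ns, 5 + 2 * log(Ns), "logarithmic")
    cmp <- compare_scaling(Ns, 3 * Ns)
  })
  expect_equal(f_pow$slope, 1, tolerance = 1e-10)
  expect_equal(f_pow$window, c(50, 800))
  expect_equal(f_exp$slope, 0.01, tolerance = 1e-10)
  expect_equal(f_log$slope, 2, tolerance = 1e-10)
  expect_error(fit_scaling(Ns, c(-1, 1, 1, 1, 1), "power_law"), "positive")
  expect_error(fit_scaling(1:3, 1:3, "power_law"))
  expect_identical(attr(cmp, "best"), "power_law")
})

test_that("an unbiased two-population random walk has diffusion exponent 1/2", {
  zg <- make_asymmetric_game(list(a = rep(0, 4), b = rep(0, 4)))
  fit <- diffusion_exponent(zg, chain_params(200, 0.1, 0, seed = 43),
                            n_reps = 100)
  expect_lt(abs(fit$exponent - 0.5), 0.1)
  expect_gte(fit$window_points, 10)
})

test_that("memory loss removes the diffusive window: distance saturates", {
  mp <- make_asymmetric_game("matching_pennies")
  r <- rates_2d(mp, chain_params(200, 0.1, 0.3))
  tg <- exp(seq(log(0.05), log(100), length.out = 40))
  ens <- simulate_ensemble(r, c(100, 100), 100, seed = 17, sample_times = tg)
  d <- sqrt(colMeans((ens$samples / 200 - 0.5)^2 +
                       (ens$samples_m / 200 - 0.5)^2))
  # the late-time RMS distance stays on a metastable plateau below the
  # diffusive saturation scale instead of growing towards the corners
  late <- tg > 20
  expect_lt(max(d[late]), 0.25)
  expect_lt(stats::sd(d[late]) / mean(d[late]), 0.2)
})
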