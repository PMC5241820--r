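test_that("average payoffs are the stated linear forms", {
  id <- make_symmetric_game(c(1, 0, 0, 1))
  expect_equal(unname(avg_payoff_1d(id, 0.5)[1, ]), c(0.5, 0.5))
  expect_equal(unname(avg_payoff_1d(make_symmetric_game("coordination"), 1)[1, ]),
               c(2, 0))
  expect_equal(unname(avg_payoff_1d(make_symmetric_game("coexistence"), 0.25)[1, ]),
               c(1.75, 1.25))
  expect_error(avg_payoff_1d(id, 1.2))

  mp <- make_asymmetric_game("matching_pennies")
  p <- avg_payoff_2d(mp, c(0.5, 0.5))
  expect_true(all(p == p[1]))  # zero-sum symmetry at the centre
  p2 <- avg_payoff_2d(mp, c(0.3, 1))
  expect_equal(unname(p2[c("piA1", "piA2")]), c(mp$A[1, 1], mp$A[2, 1]))
  zg <- make_asymmetric_game(list(a = rep(0, 4), b = rep(0, 4)))
  expect_equal(unname(avg_payoff_2d(zg, c(0.2, 0.8))), rep(0, 4))
})

test_that("modified fitness is payoff minus lambda log-frequency", {
  expect_equal(modified_fitness(1.3, 0.2, 0), 1.3)
  expect_equal(modified_fitness(0, 0.5, 1), log(2))
  # equal frequencies: entropic terms cancel in the difference
  f1 <- modified_fitness(2, 0.5, 0.7)
  f2 <- modified_fitness(1, 0.5, 0.7)
  expect_equal(f1 - f2, 1)
  expect_error(modified_fitness(1, 0, 0.5), "diverges")
})

test_that("boundaries are fixed points of the 1D flow for every game and lambda", {
  games <- c(random_games(10), fixture_games())
  for (g in games) for (lam in c(0, 0.1, 0.5, 2)) {
    p <- dyn_params(lam = lam)
    expect_identical(sc_flow_1d(g, 0, p), 0)
    expect_identical(sc_flow_1d(g, 1, p), 0)
  }
})

test_that("entropic force pushes the neutral game toward the mixed state", {
  g <- make_symmetric_game("neutral")
  p <- dyn_params(lam = 0.3)
  expect_gt(sc_flow_1d(g, 0.25, p), 0)
  expect_lt(sc_flow_1d(g, 0.75, p), 0)
})

test_that("lambda = 0 flow equals Gamma times the replicator velocity", {
  xs <- seq(0, 1, length.out = 101)
  for (g in c(fixture_games(), random_games(5, seed = 7))) {
    pis <- avg_payoff_1d(g, xs)
    repl <- xs * (1 - xs) * (pis[, "pi1"] - pis[, "pi2"])
    expect_equal(sc_flow_1d(g, xs, dyn_params(Gamma = 0.1, lam = 0)),
                 0.1 * repl, tolerance = 1e-14)
  }
})

test_that("two-population flow vanishes at corners and at the MP centre", {
  mp <- make_asymmetric_game("matching_pennies")
  p0 <- dyn_params(lam = 0)
  expect_equal(sc_flow_2d(mp, c(0.5, 0.5), p0), c(0, 0))
  for (g in list(mp, make_asymmetric_game("hyperbolic"))) {
    for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      expect_equal(sc_flow_2d(g, corner, dyn_params(lam = 0.4)), c(0, 0))
    }
  }
})

test_that("matching pennies orbits at lambda = 0 are closed", {
  mp <- make_asymmetric_game("matching_pennies")
  fl <- function(s) sc_flow_2d(mp, s, dyn_params(lam = 0))
  start <- c(0.7, 0.5)
  tr <- integrate_flow(fl, start, 120, n_out = 4001)
  d <- sqrt((tr$xA - start[1])^2 + (tr$xB - start[2])^2)
  late <- which(tr$t > 20)
  period <- tr$t[late[which.min(d[late])]]
  tr2 <- integrate_flow(fl, start, period + 1, n_out = 50001)
  d2 <- sqrt((tr2$xA - start[1])^2 + (tr2$xB - start[2])^2)
  expect_lt(min(d2[tr2$t > period - 1]), 1e-4)
})

test_that("replicator-mutator flow has no absorbing boundary for u > 0", {
  g <- make_symmetric_game("neutral")
  pu <- dyn_params(u = 0.1)
  expect_equal(replicator_mutator_flow(g, 0, pu), 0.1)
  expect_equal(replicator_mutator_flow(g, 1, pu), -0.1)
  # u = 0 reduces to the replicator flow on a grid
  xs <- seq(0, 1, 0.02)
  gc <- make_symmetric_game("coordination")
  expect_equal(replicator_mutator_flow(gc, xs, dyn_params(u = 0)),
               sc_flow_1d(gc, xs, dyn_params(lam = 0)))
  # neutral game with mutation: unique interior fixed point at 1/2
  fp <- find_fixed_points_rm(g, dyn_params(u = 0.05))
  expect_equal(fp$x, 0.5)
  expect_identical(fp$stability, "stable")
})

test_that("flow integration reproduces the qualitative flow diagrams", {
  # constant zero flow stays put
  tr0 <- integrate_flow(function(x) 0 * x, 0.3, 5)
  expect_true(all(tr0$x == 0.3))
  # coordination, lambda = 0, start above the interior unstable point -> x = 1
  gc <- make_symmetric_game("coordination")
  tr <- integrate_flow(function(x) sc_flow_1d(gc, x, dyn_params(lam = 0)),
                       0.5, 2000)
  expect_lt(abs(tr$x[length(tr$x)] - 1), 1e-6)
  # dominance: monotone approach to 1 with an exponential tail
  gd <- make_symmetric_game("dominance")
  tr2 <- integrate_flow(function(x) sc_flow_1d(gd, x, dyn_params(lam = 0)),
                        0.5, 150, n_out = 301)
  expect_true(all(diff(tr2$x) > 0))
  tail_i <- tr2$t > 50 & tr2$x < 1
  fit <- summary(stats::lm(log(1 - tr2$x[tail_i]) ~ tr2$t[tail_i]))
  expect_gt(fit$r.squared, 0.99)
  expect_lt(stats::coef(fit)[2, 1], 0)
})
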