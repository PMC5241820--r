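test_that("coordination game: five fixed points at small lambda, three beyond", {
  g <- make_symmetric_game("coordination")
  for (lam in c(0.05, 0.1)) {
    fp <- find_fixed_points_1d(g, dyn_params(lam = lam))
    expect_identical(nrow(fp), 5L)
    expect_identical(fp$stability[fp$boundary], c("unstable", "unstable"))
    # stable / unstable / stable pattern in the interior
    expect_identical(fp$stability[!fp$boundary],
                     c("stable", "unstable", "stable"))
  }
  fp3 <- find_fixed_points_1d(g, dyn_params(lam = 0.4))
  expect_identical(nrow(fp3), 3L)
  expect_identical(fp3$stability[fp3$boundary], c("unstable", "unstable"))
  expect_identical(fp3$stability[!fp3$boundary], "stable")
})

test_that("lambda = 0 recovers the replicator fixed-point structure", {
  fp <- find_fixed_points_1d(make_symmetric_game("coordination"),
                             dyn_params(lam = 0))
  expect_identical(nrow(fp), 3L)
  expect_equal(fp$x[!fp$boundary], 1 / 3, tolerance = 1e-9)
  expect_identical(fp$stability, c("stable", "unstable", "stable"))

  fp2 <- find_fixed_points_1d(make_symmetric_game("coexistence"),
                              dyn_params(lam = 0))
  expect_equal(fp2$x[!fp2$boundary], 0.5, tolerance = 1e-9)
  expect_identical(fp2$stability, c("unstable", "stable", "unstable"))
})

test_that("attracting fixed points are interior whenever lambda > 0", {
  for (g in fixture_games()) for (lam in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    fp <- find_fixed_points_1d(g, dyn_params(lam = lam))
    expect_true(all(!fp$boundary[fp$stability == "stable"]))
    expect_identical(fp$stability[fp$boundary], c("unstable", "unstable"))
  }
})

test_that("strong memory loss drives the stable point to the mixed state", {
  for (g in fixture_games()) {
    fp <- find_fixed_points_1d(g, dyn_params(lam = 1000))
    stab <- fp[fp$stability == "stable", ]
    expect_identical(nrow(stab), 1L)
    expect_lt(abs(stab$x - 0.5), 1e-3)
  }
})

test_that("matching pennies centre: cyclic at lambda = 0, attracting beyond", {
  mp <- make_asymmetric_game("matching_pennies")
  fp0 <- find_fixed_points_2d(mp, dyn_params(lam = 0))
  ctr <- fp0[fp0$kind == "interior", ]
  expect_identical(nrow(ctr), 1L)
  expect_equal(c(ctr$xA, ctr$xB), c(0.5, 0.5), tolerance = 1e-10)
  expect_identical(ctr$stability, "center")
  expect_equal(Re(ctr$eig1), 0, tolerance = 1e-12)
  expect_false(Im(ctr$eig1) == 0)

  fp3 <- find_fixed_points_2d(mp, dyn_params(lam = 0.3))
  ctr3 <- fp3[fp3$kind == "interior", ]
  expect_identical(ctr3$stability, "stable")
  expect_equal(c(ctr3$xA, ctr3$xB), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("asymmetric dominance at lambda = 0 has four corner points, one stable", {
  fp <- find_fixed_points_2d(make_asymmetric_game("asym_dominance"),
                             dyn_params(lam = 0))
  expect_identical(nrow(fp), 4L)
  expect_true(all(fp$kind == "corner"))
  expect_identical(sum(fp$stability == "stable"), 1L)
  stable <- fp[fp$stability == "stable", ]
  expect_equal(c(stable$xA, stable$xB), c(1, 1))
})

test_that("hyperbolic game merges two stable points and the saddle at lambda_c", {
  hy <- make_asymmetric_game("hyperbolic")
  fp0 <- find_fixed_points_2d(hy, dyn_params(lam = 0))
  int0 <- fp0[fp0$kind == "interior", ]
  expect_identical(int0$stability, "saddle")
  expect_identical(sum(fp0$stability == "stable" & fp0$kind == "corner"), 2L)

  fp_mid <- find_fixed_points_2d(hy, dyn_params(lam = 0.3))
  expect_identical(sum(fp_mid$kind == "interior" &
                         fp_mid$stability == "stable"), 2L)
  expect_identical(sum(fp_mid$kind == "interior" &
                         fp_mid$stability == "saddle"), 1L)

  fp_hi <- find_fixed_points_2d(hy, dyn_params(lam = 0.8))
  int_hi <- fp_hi[fp_hi$kind == "interior", ]
  expect_identical(nrow(int_hi), 1L)
  expect_identical(int_hi$stability, "stable")

  bs <- bifurcation_scan(hy, dyn_params(), seq(0.3, 0.7, length.out = 17))
  expect_length(bs$lam_c, 1L)
  expect_lt(bs$bracket[1, 2] - bs$bracket[1, 1], 1e-4 + 1e-12)
})

test_that("bifurcation scan: coordination has one saddle-node, coexistence none", {
  bs <- bifurcation_scan(make_symmetric_game("coordination"), dyn_params(),
                         seq(0.01, 0.6, length.out = 24))
  expect_length(bs$lam_c, 1L)
  expect_identical(as.integer(bs$count_change[1, ]), c(5L, 3L))
  expect_true(bs$lam_c > 0.25 && bs$lam_c < 0.4)

  bs2 <- bifurcation_scan(make_symmetric_game("coexistence"), dyn_params(),
                          seq(0.01, 0.6, length.out = 16))
  expect_length(bs2$lam_c, 0L)
  # the stable interior branch moves monotonically toward 1/2
  xs <- vapply(bs2$branches, function(fp) {
    fp$x[fp$stability == "stable" & !fp$boundary]
  }, numeric(1))
  expect_true(all(diff(abs(xs - 0.5)) <= 1e-12))
})
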