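test_that("right-hand side is linear and matches the event bookkeeping", {
  p <- ref_params()
  expect_equal(ng_rhs(p, ng_state(0, 0, 0, 0, 0)), setNames(rep(0, 5), c("c1", "c2", "c3", "c4", "c5")))
  r <- ng_rhs(p, ref_state())
  expect_equal(r[["c1"]], -0.23 * 10000)
  expect_equal(r[["c2"]], 0.378 * 10000 - 1.2 * 5000)
  expect_equal(r[["c3"]], 2.1 * 5000 - 1.9 * 15000)
  expect_equal(r[["c4"]], 1.5 * 15000 - 0.05 * 350000)
  expect_equal(r[["c5"]], 0.552 * 10000 - 0.05 * 100000)
  # no asymmetric divisions: no stem influx into progenitors
  expect_equal(ng_rhs(ng_params(a1 = 1, theta1 = 1), ref_state())[["c2"]],
               -1.2 * 5000)
})

test_that("closed-form stem curve matches its exponential solution", {
  p <- ref_params()
  expect_equal(closed_form_c1(p, 10000, 0), 10000)
  expect_equal(closed_form_c1(p, 10000, 1), 7945.33602503, tolerance = 1e-10)
  # balanced self-renewal: constant stem pool
  expect_equal(closed_form_c1(ng_params(a1 = 0.625, theta1 = 0.8), 123, c(0, 5, 50)),
               rep(123, 3))
  expect_error(closed_form_c1(p, 100, -1), class = "ng_invalid_time")
})

test_that("closed-form progenitor curve matches the cascade solution", {
  p <- ref_params()
  expect_equal(closed_form_c2(p, 10000, 5000, 0), 5000)
  expect_equal(closed_form_c2(p, 10000, 5000, 1), 3428.46889094, tolerance = 1e-10)
  # decoupled compartments when kappa = 0
  p0 <- ng_params(kappa = 0)
  expect_equal(closed_form_c2(p0, 10000, 5000, 2), 5000 * exp(-1.2 * 2))
})

test_that("equal-rate degeneracy uses the secular limiting form", {
  # lambda1 = lambda2 = -0.23 (bit-identical: same float expression)
  p_eq <- ng_params(a2 = 0.55, theta2 = 0.7, p2 = 1, d2 = 0)
  dr <- derived_rates(p_eq)
  expect_identical(dr$lambda1, dr$lambda2)
  t <- c(0, 1, 3)
  expect_equal(closed_form_c2(p_eq, 10000, 5000, t),
               (5000 + dr$k12 * 10000 * t) * exp(dr$lambda2 * t))
  # and the numeric solver agrees with the limit
  traj <- ng_solve(p_eq, ref_state(), times = seq(0, 3, by = 0.5))
  expect_equal(traj$c2, closed_form_c2(p_eq, 10000, 5000, traj$time),
               tolerance = 1e-8)
})

test_that("numeric solver agrees with the closed forms to tight tolerance", {
  p <- ref_params()
  times <- seq(0, 30, length.out = 121)
  traj <- ng_solve(p, ref_state(), times)
  expect_equal(traj$c1, closed_form_c1(p, 10000, times), tolerance = 1e-8)
  expect_equal(traj$c2, closed_form_c2(p, 10000, 5000, times), tolerance = 1e-8)
  expect_equal(unlist(traj[1, -1]), as.numeric(ref_state()), ignore_attr = TRUE)
})

test_that("zero initial state stays identically zero", {
  traj <- ng_solve(ref_params(), ng_state(0, 0, 0, 0, 0), seq(0, 10, by = 1))
  expect_true(all(as.matrix(traj[, -1]) == 0))
})

test_that("compartments stay nonnegative for random parameters and states", {
  withr::with_seed(42, {
    for (i in 1:10) {
      p <- sample_regime_params()
      init <- ng_state(runif(1, 0, 2e4), runif(1, 0, 1e4), runif(1, 0, 2e4),
                       runif(1, 0, 4e5), runif(1, 0, 1e5))
      traj <- ng_solve(p, init, seq(0, 30, length.out = 61))
      expect_true(all(as.matrix(traj[, -1]) >= 0))
    }
  })
})

test_that("solutions superpose: solving summed initial states equals summed solutions", {
  p <- ref_params()
  times <- seq(0, 10, length.out = 21)
  a <- ng_state(10000, 0, 500, 0, 1000)
  b <- ng_state(300, 5000, 0, 350000, 0)
  ab <- ng_state(10300, 5000, 500, 350000, 1000)
  sum_sol <- as.matrix(ng_solve(p, a, times)[, -1]) +
    as.matrix(ng_solve(p, b, times)[, -1])
  expect_equal(as.matrix(ng_solve(p, ab, times)[, -1]), sum_sol,
               tolerance = 1e-9)
})

test_that("stem count is monotone iff the decline condition holds", {
  times <- seq(0, 20, length.out = 201)
  declining <- ng_solve(ref_params(), ref_state(), times)$c1
  expect_true(all(diff(declining) < 0))
  expanding <- ng_solve(ng_params(a1 = 0.9, theta1 = 0.9), ref_state(), times)$c1
  expect_false(check_stem_decline(ng_params(a1 = 0.9, theta1 = 0.9))$declining)
  expect_true(all(diff(expanding) > 0))
  flat <- ng_solve(ng_params(a1 = 0.625, theta1 = 0.8), ref_state(), times)$c1
  expect_equal(flat, rep(10000, length(times)), tolerance = 1e-9)
})

test_that("invalid time grids are rejected", {
  expect_error(ng_solve(ref_params(), ref_state(), c(1, 2)),
               class = "ng_invalid_time")
  expect_error(ng_solve(ref_params(), ref_state(), c(0, 2, 2)),
               class = "ng_invalid_time")
})
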