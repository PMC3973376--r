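test_that("division fraction is the exponential-lifetime CDF", {
  expect_equal(division_fraction(1, 0), 0)
  expect_equal(division_fraction(0, 5), 0)
  expect_equal(division_fraction(1, 0.1), 0.095162581964, tolerance = 1e-10)
  # monotone in delta, approaching 1 from below
  d <- c(0.1, 1, 2, 5)
  f <- division_fraction(2, d)
  expect_true(all(diff(f) > 0))
  expect_lt(max(f), 1)
  expect_equal(f[4], 1, tolerance = 1e-4)
})

test_that("initial labels follow the division-fraction construction", {
  p <- ref_params()
  l <- initial_labels(p, ref_state(), delta = 0.1)
  expect_equal(l$l1, 732.751881123, tolerance = 1e-10)
  expect_equal(l$l2, 979.072367224, tolerance = 1e-10)
  expect_equal(l$l3, 265.439060314, tolerance = 1e-10)
  expect_equal(l$l4, 0)
  expect_equal(l$l5, 239.809706549, tolerance = 1e-10)
  # no exposure, no labels
  expect_equal(unlist(initial_labels(p, ref_state(), 0)),
               setNames(rep(0, 5), c("l1", "l2", "l3", "l4", "l5")))
})

test_that("no labelled neurons at the end of exposure, for any parameters", {
  withr::with_seed(7, {
    for (i in 1:10) {
      p <- sample_regime_params()
      st <- ng_state(runif(1, 0, 1e4), runif(1, 0, 1e4), runif(1, 0, 1e4),
                     runif(1, 0, 1e5), runif(1, 0, 1e5))
      expect_equal(initial_labels(p, st, runif(1, 0.01, 1))$l4, 0)
    }
  })
})

test_that("labels never exceed the two-daughters-per-division bound", {
  withr::with_seed(8, {
    for (i in 1:10) {
      p <- sample_regime_params()
      st <- ng_state(runif(1, 0, 1e4), runif(1, 0, 1e4), 0, 0, 0)
      l <- initial_labels(p, st, runif(1, 0.01, 2))
      expect_lte(l$l1, 2 * st[["c1"]])
      expect_lte(l$l2, 2 * (st[["c1"]] + st[["c2"]]))
      expect_lte(l$l3, 2 * st[["c2"]])
      expect_lte(l$l5, 2 * st[["c1"]])
    }
  })
})

test_that("labels scale linearly with delta as the exposure shrinks", {
  p <- ref_params()
  st <- ref_state()
  rate1 <- unlist(initial_labels(p, st, 1e-3)) / 1e-3
  rate2 <- unlist(initial_labels(p, st, 5e-4)) / 5e-4
  # halving delta moves l/delta closer to the instantaneous production rate
  B <- neurodyn:::label_creation_matrix(p)
  inst <- unname(drop(B %*% as.numeric(st)))
  expect_equal(unname(rate2), inst, tolerance = 1e-3)
  expect_true(all(abs(rate2 - inst)[inst > 0] < abs(rate1 - inst)[inst > 0]))
})

test_that("labelled cells follow the compartment dynamics during the chase", {
  p <- ref_params()
  tau <- seq(0, 5, by = 0.5)
  # zero labels stay zero
  z <- labeled_trajectory(p, rep(0, 5), tau)
  expect_true(all(as.matrix(z[, -1]) == 0))
  # labelling the entire population reproduces the count dynamics exactly
  full <- labeled_trajectory(p, as.numeric(ref_state()), tau)
  counts <- ng_solve(p, ref_state(), tau)
  expect_equal(as.matrix(full[, -1]), as.matrix(counts[, -1]),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("BrdU-incorporating series is the label formula along the solution", {
  p <- ref_params()
  times <- seq(0, 10, by = 1)
  lp <- brdu_series(p, ref_state(), times, delta = 0.1)
  expect_equal(lp$l1[1], 732.751881123, tolerance = 1e-10)
  expect_equal(lp$l4, rep(0, length(times)))
  # l5+/l1+ constant in time (both proportional to c1)
  ratio <- lp$l5 / lp$l1
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-9)
  # consistency with initial_labels applied at a later time point
  traj <- ng_solve(p, ref_state(), times)
  at5 <- initial_labels(p, unlist(traj[traj$time == 5, -1]), 0.1)
  expect_equal(unlist(lp[lp$time == 5, -1]), unlist(at5), tolerance = 1e-9)
})

test_that("window master equation quantifies the fraction-formula error", {
  p <- ref_params()
  st <- ref_state()
  exact <- unlist(window_label_mean(p, st, 0.05))
  approx <- unlist(initial_labels(p, st, 0.05))
  # agreement at first order in delta; discrepancy shrinks when delta halves
  rel1 <- abs(exact - approx)[approx > 0] / approx[approx > 0]
  exact2 <- unlist(window_label_mean(p, st, 0.025))
  approx2 <- unlist(initial_labels(p, st, 0.025))
  rel2 <- abs(exact2 - approx2)[approx2 > 0] / approx2[approx2 > 0]
  expect_true(all(rel2 < rel1))
  # labelled neurons at window end are a higher-order trickle, not zero
  expect_gt(window_label_mean(p, st, 0.05)$l4, 0)
  expect_lt(window_label_mean(p, st, 0.05)$l4 / sum(exact), 0.01)
  expect_equal(unlist(window_label_mean(p, st, 0)),
               setNames(rep(0, 5), c("l1", "l2", "l3", "l4", "l5")))
})

test_that("labelling protocols are validated", {
  expect_error(labeling_protocol(t_hat = -1), class = "ng_invalid_protocol")
  expect_error(labeling_protocol(delta = Inf), class = "ng_invalid_protocol")
  expect_error(labeling_protocol(tau = c(0, -2)), class = "ng_invalid_protocol")
})
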