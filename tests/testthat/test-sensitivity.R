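test_that("count sensitivities start at zero and match hand-derived values", {
  p <- ref_params()
  s <- sensitivity(p, ref_state(), "a1", times = seq(0, 1, by = 0.5))
  expect_equal(unlist(s[1, -1]), setNames(rep(0, 5), c("c1", "c2", "c3", "c4", "c5")))
  # d c1/d a1 = 2 theta1 p1 t c1(t), by differentiating the exponential
  expect_equal(s$c1[s$time == 1], 11123.470435, tolerance = 1e-8)
  # c1 never depends on kappa or downstream rates
  for (par in c("kappa", "a2", "theta2", "p2", "d2", "p3", "d3", "d4", "d5")) {
    sk <- sensitivity(p, ref_state(), par, times = c(0, 1, 5))
    expect_equal(sk$c1, rep(0, 3))
  }
})

test_that("forward sensitivities agree with the analytic closed forms", {
  p <- ref_params()
  times <- seq(0, 30, length.out = 301)
  for (par in c("a1", "theta1", "p1", "kappa")) {
    fw <- sensitivity(p, ref_state(), par, times)
    for (q in c("c1", "c2")) {
      an <- analytic_sensitivity(p, ref_state(), par, times, q)
      denom <- max(abs(an))
      if (denom == 0) {
        expect_lt(max(abs(fw[[q]])), 1e-8)
      } else {
        expect_lt(max(abs(fw[[q]] - an)) / denom, 1e-6)
      }
    }
  }
})

test_that("forward sensitivities agree with central finite differences", {
  p <- ref_params()
  times <- seq(0, 30, length.out = 61)
  for (par in c("a1", "theta1", "p1", "kappa", "p2", "d4")) {
    fw <- sensitivity(p, ref_state(), par, times)
    fd <- fd_sensitivity(p, ref_state(), par, times)
    for (q in c("c1", "c2", "c3", "c4", "c5")) {
      denom <- max(abs(fw[[q]]))
      if (denom < 1e-9) {
        expect_lt(max(abs(fd[[q]])), 1e-2)  # pure solver round-off over 2h
      } else {
        expect_lt(max(abs(fw[[q]] - fd[[q]])) / denom, 1e-4)
      }
    }
  }
})

test_that("central differences converge at second order in the step", {
  p <- ref_params()
  times <- c(0, 2, 10)
  fw <- sensitivity(p, ref_state(), "a1", times)$c2[3]
  err <- function(h) {
    abs(fd_sensitivity(p, ref_state(), "a1", times, h = h)$c2[3] - fw)
  }
  e1 <- err(2e-3)
  e2 <- err(1e-3)
  expect_gt(e1 / e2, 3)  # halving h shrinks the error ~4x
  expect_lt(e1 / e2, 5)
})

test_that("BrdU-incorporating sensitivities are non-zero at time zero for stem parameters", {
  p <- ref_params()
  times <- c(0, 1, 5)
  bs <- brdu_sensitivity(p, ref_state(), "a1", times, delta = 0.1)
  expect_equal(bs$l1[1], 1332.2761475, tolerance = 1e-9)
  for (par in c("a1", "p1", "theta1")) {
    b0 <- brdu_sensitivity(p, ref_state(), par, times, delta = 0.1)
    expect_gt(abs(b0$l1[1]), 0)
    # but labelled neurons are identically zero at the window end
    expect_equal(b0$l4, rep(0, 3))
  }
  # cross-check against finite differences of the incorporating series
  fd <- fd_sensitivity(p, ref_state(), "a1", times, quantity = "brdu", delta = 0.1)
  for (q in c("l1", "l2", "l3", "l5")) {
    expect_equal(bs[[q]], fd[[q]], tolerance = 1e-5)
  }
})

test_that("pulse-chase label sensitivities chain through all three stages", {
  p <- ref_params()
  tau <- seq(0, 10, length.out = 101)
  pr <- labeling_protocol(t_hat = 2, delta = 0.1, tau = tau)
  ls <- label_sensitivity(p, ref_state(), "p1", pr)
  # finite-difference verification of the full pipeline
  h <- 1e-6
  run <- function(p1val) {
    pp <- ng_params(p1 = p1val)
    c_hat <- unlist(ng_solve(pp, ref_state(), c(0, 2))[2, -1])
    l0 <- initial_labels(pp, c_hat, 0.1)
    as.matrix(labeled_trajectory(pp, l0, tau)[, -1])
  }
  fd <- (run(1 + h) - run(1 - h)) / (2 * h)
  for (i in 1:5) {
    denom <- max(abs(fd[, i]), 1)
    expect_lt(max(abs(ls[[i + 1]] - fd[, i])) / denom, 1e-4)
  }
  # tau = 0 labelled-neuron derivative vanishes for every parameter
  pr0 <- labeling_protocol(t_hat = 1, delta = 0.1, tau = c(0, 1))
  for (par in c("a1", "p1", "theta1")) {
    expect_equal(label_sensitivity(p, ref_state(), par, pr0)$l4[1], 0,
                 tolerance = 1e-12)
  }
})

test_that("finite knockout responses match the derivative at first order", {
  p <- ref_params()
  times <- seq(0, 10, length.out = 41)
  kr <- ko_response(p, ref_state(), "a1", 1e-4, times = times)
  fw <- sensitivity(p, ref_state(), "a1", times)
  for (q in c("c1", "c2", "c5")) {
    expect_lt(max(abs(kr[[q]] / 1e-4 - fw[[q]])) / max(abs(fw[[q]])), 0.01)
  }
  # zero perturbation: identically zero differences
  k0 <- ko_response(p, ref_state(), "a1", 0, times = times)
  expect_true(all(as.matrix(k0[, -1]) == 0))
  # a higher proliferation rate depletes the stem pool at all t > 0
  kp <- ko_response(p, ref_state(), "p1", 0.01, times = times)
  expect_true(all(kp$c1[-1] < 0))
  # perturbations leaving the domain are rejected
  expect_error(ko_response(p, ref_state(), "a1", 0.7, times = times),
               class = "ng_invalid_parameter")
})

test_that("knockout effects on progenitors fade with the stem-pool decline", {
  # every response curve is c1(t) times an affine-bounded factor, so effects
  # decay once the stem pool has emptied
  p <- ref_params()
  times <- seq(0, 60, length.out = 1201)
  s2 <- sensitivity(p, ref_state(), "a1", times)$c2
  peak <- max(abs(s2))
  expect_lt(abs(s2[times == 30]) / peak, 0.05)
  expect_lt(abs(s2[times == 60]) / peak, 1e-3)
})

test_that("invalid parameter names are rejected", {
  expect_error(sensitivity(ref_params(), ref_state(), "bogus", c(0, 1)),
               class = "ng_invalid_parameter")
})
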