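truth_composites <- c(lambda1 = -0.23, lambda2 = -1.2, K = 3780,
                      n1 = 10000, n2 = 5000)

test_that("weighted SSR is zero at the generating truth and additive per observation", {
  d <- generate_age_series(age_series_design(cv = 0, seed = 1))
  expect_equal(weighted_ssr(truth_composites, d, "c1_c2"), 0, tolerance = 1e-18)
  expect_equal(weighted_ssr(truth_composites, d, "c1_ratio"), 0, tolerance = 1e-18)
  # one extra observation with residual r and error s adds (r/s)^2
  extra <- dplyr::bind_rows(d, tibble::tibble(
    age = 12, compartment = "stem",
    mean = closed_form_c1(ref_params(), 10000, 12) + 30, sem = 10
  ))
  expect_equal(weighted_ssr(truth_composites, extra, "c1_c2"), 9)
  # zero standard errors are rejected
  bad <- d
  bad$sem[1] <- 0
  expect_error(weighted_ssr(truth_composites, bad, "c1_c2"),
               class = "ng_invalid_data")
})

test_that("SSR at the truth matches its sampling expectation under 5% noise", {
  # each standardised residual is a t statistic with replicates - 1 = 3
  # degrees of freedom (s.e.m. estimated from 4 replicates), so its second
  # moment is 3/(3 - 2) = 3 per observation, not 1
  withr::with_seed(42, {
    ssrs <- replicate(20, {
      d <- generate_age_series(age_series_design(cv = 0.05))
      weighted_ssr(truth_composites, d, "c1_c2")
    })
  })
  n_obs <- 20
  expect_gt(mean(ssrs), n_obs * 1.5)
  expect_lt(mean(ssrs), n_obs * 6)
})

test_that("noiseless data are recovered essentially exactly in both modes", {
  d <- generate_age_series(age_series_design(cv = 0, seed = 1))
  for (mode in c("c1_c2", "c1_ratio")) {
    fit <- fit_age_series(d, mode, n_starts = 15, seed = 1)
    expect_equal(fit$composites[["lambda1"]], -0.23, tolerance = 1e-3)
    expect_equal(fit$composites[["lambda2"]], -1.2, tolerance = 1e-2)
    expect_equal(fit$composites[["n1"]], 10000, tolerance = 1e-3)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("fits are deterministic given the seed", {
  d <- generate_age_series(age_series_design(cv = 0.05, seed = 9))
  f1 <- fit_age_series(d, "c1_c2", n_starts = 8, seed = 5)
  f2 <- fit_age_series(d, "c1_c2", n_starts = 8, seed = 5)
  expect_identical(f1$composites, f2$composites)
  expect_identical(f1$ssr, f2$ssr)
})

test_that("weighted R^2 degrades as noise grows", {
  r2 <- purrr::map_dbl(c(0.02, 0.10, 0.25), function(cv) {
    mean(purrr::map_dbl(1:5, function(i) {
      d <- generate_age_series(age_series_design(cv = cv, seed = 100 + i))
      fit_age_series(d, "c1_c2", n_starts = 5, seed = 1)$r_squared
    }))
  })
  expect_true(all(diff(r2) < 0))
  expect_equal(r2[1], 1, tolerance = 0.05)
})

test_that("tidy and glance expose the composites and fit quality", {
  d <- generate_age_series(age_series_design(cv = 0, seed = 2))
  fit <- fit_age_series(d, "c1_c2", n_starts = 5, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("lambda1", "lambda2", "K", "n1", "n2"))
  gl <- glance(fit)
  expect_named(gl, c("ssr", "r.squared", "mode", "n_starts", "converged"))
  expect_true(gl$converged)
})

test_that("a saturating stem pool exposes the mode disagreement on progenitors", {
  # late-age stem counts floored (residual quiescent pool): the exponential
  # model cannot describe both the stem curve and the ratio, so the
  # stem+ratio fit describes progenitors much worse than the direct fit
  d <- generate_age_series(age_series_design(cv = 0.03, saturation_floor = 320,
                                             seed = 4))
  f_ratio <- fit_age_series(d, "c1_ratio", n_starts = 20, seed = 1)
  f_direct <- fit_age_series(d, "c1_c2", n_starts = 20, seed = 1)
  ssr_prog_ratio <- compartment_ssr(f_ratio, d, "progenitor")
  ssr_prog_direct <- compartment_ssr(f_direct, d, "progenitor")
  expect_gt(ssr_prog_ratio, 2 * ssr_prog_direct)
  # and conversely the direct fit describes the ratio worse
  expect_gt(compartment_ssr(f_direct, d, "ratio"),
            compartment_ssr(f_ratio, d, "ratio"))
  # exponential-fit residuals concentrate at late ages where the floor binds
  stem <- d[d$compartment == "stem", ]
  pred <- f_direct$composites[["n1"]] *
    exp(f_direct$composites[["lambda1"]] * stem$age)
  resid <- abs(pred - stem$mean) / stem$sem
  expect_gt(mean(resid[stem$age >= 16]), mean(resid[stem$age <= 8]))
})

test_that("degenerate inputs are rejected", {
  d <- generate_age_series(age_series_design(cv = 0, seed = 1))
  short <- d[d$age < 6 | d$compartment != "stem", ]
  expect_error(fit_age_series(short, "c1_c2", n_starts = 2),
               class = "ng_invalid_data")
})
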