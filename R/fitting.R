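ng_composite_names <- c("lambda1", "lambda2", "K", "n1", "n2")

#' Age-series observations
#'
#' Validates a table of age-decline observations: one row per (age,
#' compartment) with the replicate mean and its standard error. Compartments
#' are `"stem"`, `"progenitor"` and optionally `"ratio"` (stem/progenitor).
#'
#' @param data A data frame with columns `age`, `compartment`, `mean`, `sem`.
#' @return The validated tibble (class `ng_age_series`).
#' @export
as_age_series <- function(data) {
  data <- as_tibble(data)
  need <- c("age", "compartment", "mean", "sem")
  if (!all(need %in% names(data))) {
    abort(sprintf("age series needs columns: %s", paste(need, collapse = ", ")),
          class = "ng_invalid_data")
  }
  if (!all(data$compartment %in% c("stem", "progenitor", "ratio"))) {
    abort("`compartment` must be one of stem, progenitor, ratio",
          class = "ng_invalid_data")
  }
  if (any(data$age < 0)) abort("ages must be >= 0", class = "ng_invalid_data")
  if (any(!is.finite(data$sem) | data$sem <= 0)) {
    abort("every `sem` must be finite and > 0 (zero standard errors are rejected)",
          class = "ng_invalid_data")
  }
  class(data) <- unique(c("ng_age_series", class(data)))
  data
}

# model curves from the identifiable composites:
# stem: n1 exp(lambda1 t); progenitor: cascade solution with K = k12 * n1
composite_curves <- function(composites, age) {
  with(as.list(composites), list(
    stem = n1 * exp(lambda1 * age),
    progenitor = closed_c2_composite(lambda1, lambda2, K, n2, age)
  ))
}

# observations actually entering the objective for a fitting mode; ratio rows
# are synthesised from stem/progenitor rows (first-order error propagation)
# when not supplied in the data
fit_observations <- function(data, mode) {
  data <- as_age_series(data)
  if (mode == "c1_c2") {
    obs <- dplyr::filter(data, .data$compartment %in% c("stem", "progenitor"))
  } else {
    stem <- dplyr::filter(data, .data$compartment == "stem")
    ratio <- dplyr::filter(data, .data$compartment == "ratio")
    if (nrow(ratio) == 0) {
      prog <- dplyr::filter(data, .data$compartment == "progenitor")
      both <- dplyr::inner_join(stem, prog, by = "age",
                                suffix = c("_s", "_p"))
      ratio <- tibble(
        age = both$age, compartment = "ratio",
        mean = both$mean_s / both$mean_p,
        sem = (both$mean_s / both$mean_p) *
          sqrt((both$sem_s / both$mean_s)^2 + (both$sem_p / both$mean_p)^2)
      )
    }
    obs <- dplyr::bind_rows(stem, ratio)
  }
  if (nrow(obs) == 0) abort("no usable observations for this mode",
                            class = "ng_invalid_data")
  obs
}

# fast numeric view of the observations for the optimiser hot loop
obs_vectors <- function(obs) {
  list(age = obs$age,
       kind = match(obs$compartment, c("stem", "progenitor", "ratio")),
       mean = obs$mean, sem = obs$sem)
}

ssr_vectors <- function(lambda1, lambda2, K, n1, n2, v) {
  stem <- n1 * exp(lambda1 * v$age)
  prog <- closed_c2_composite(lambda1, lambda2, K, n2, v$age)
  model <- ifelse(v$kind == 1L, stem, ifelse(v$kind == 2L, prog, stem / prog))
  sum(((model - v$mean) / v$sem)^2)
}

#' Error-weighted sum of squared residuals
#'
#' The fitting objective: `sum(((model - observed) / sem)^2)` over the
#' observations used by the given mode. Mode `"c1_c2"` fits the stem and
#' progenitor counts; mode `"c1_ratio"` fits the stem count and the
#' stem/progenitor ratio (taking ratio rows from the data when present,
#' otherwise propagating the component standard errors to first order).
#'
#' @param composites Named vector or list with entries `lambda1`, `lambda2`
#'   (net per-capita rates), `K` (`k12 * n1` flux composite), `n1`, `n2`
#'   (initial counts) — the combinations identifiable from stem/progenitor
#'   data.
#' @param data An age-series table (see [as_age_series()]).
#' @param mode `"c1_c2"` or `"c1_ratio"`.
#' @return Scalar weighted SSR.
#' @examples
#' d <- generate_age_series(age_series_design(cv = 0, seed = 1))
#' truth <- c(lambda1 = -0.23, lambda2 = -1.2, K = 3780, n1 = 10000, n2 = 5000)
#' weighted_ssr(truth, d, "c1_c2")
#' @export
weighted_ssr <- function(composites, data, mode = c("c1_c2", "c1_ratio")) {
  mode <- match.arg(mode)
  v <- obs_vectors(fit_observations(data, mode))
  comp <- as.list(composites)
  ssr_vectors(comp$lambda1, comp$lambda2, comp$K, comp$n1, comp$n2, v)
}

#' Fit the age-decline model to observed cell counts
#'
#' Weighted nonlinear least squares of the closed-form stem/progenitor
#' solutions against an age series, with weights equal to the inverse
#' squared standard errors. Only the composites `lambda1`, `lambda2`,
#' `K = k12 * n1`, `n1`, `n2` are identifiable from stem/progenitor data, so
#' the optimiser works on `(lambda1, lambda2, log K, log n1, log n2)`.
#' Optimisation is multi-start: data-driven initial values (log-linear
#' regression of each compartment) plus `n_starts - 1` random perturbations,
#' each polished by derivative-free Nelder-Mead. Deterministic for a given
#' `seed`.
#'
#' @inheritParams weighted_ssr
#' @param n_starts Number of optimisation starts (default 100).
#' @param seed Integer seed controlling the random starts.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @return An object of class `ng_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' d <- generate_age_series(age_series_design(cv = 0, seed = 1))
#' fit <- fit_age_series(d, mode = "c1_c2", n_starts = 10, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
fit_age_series <- function(data, mode = c("c1_c2", "c1_ratio"),
                           n_starts = 100, seed = 1, maxit = 10000) {
  mode <- match.arg(mode)
  data <- as_age_series(data)
  obs <- fit_observations(data, mode)
  stem <- dplyr::filter(data, .data$compartment == "stem")
  prog <- dplyr::filter(data, .data$compartment == "progenitor")
  if (length(unique(stem$age)) < 4) {
    abort("need at least 4 stem-cell time points for an identifiable fit",
          class = "ng_invalid_data")
  }

  loglin <- function(df) {
    f <- lm(log(pmax(mean, 1e-12)) ~ age, data = df)
    c(rate = unname(coef(f)[2]), n0 = exp(unname(coef(f)[1])))
  }
  s0 <- loglin(stem)
  p0 <- if (nrow(prog) >= 2) loglin(prog) else c(rate = s0[["rate"]] * 2,
                                                 n0 = s0[["n0"]] / 2)
  base <- c(
    lambda1 = s0[["rate"]], lambda2 = p0[["rate"]],
    logK = log(max(s0[["n0"]] * 0.3, 1e-6)),
    logn1 = log(max(s0[["n0"]], 1e-6)), logn2 = log(max(p0[["n0"]], 1e-6))
  )

  v <- obs_vectors(obs)
  objective <- function(theta) {
    val <- ssr_vectors(theta[[1]], theta[[2]], exp(theta[[3]]),
                       exp(theta[[4]]), exp(theta[[5]]), v)
    if (!is.finite(val)) 1e300 else val
  }

  runs <- withr::with_seed(seed, {
    starts <- c(list(base), purrr::map(seq_len(max(n_starts, 1) - 1), function(i) {
      base + c(
        base[["lambda1"]] * runif(1, -0.75, 0.75),
        base[["lambda2"]] * runif(1, -0.75, 0.75),
        runif(1, -2, 2), runif(1, -0.5, 0.5), runif(1, -0.5, 0.5)
      )
    }))
    purrr::map(starts, function(th) {
      res <- optim(th, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-14))
      tries <- 0L
      while (res$convergence != 0L && tries < 3L) {  # restart the simplex
        res <- optim(res$par, objective, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-14))
        tries <- tries + 1L
      }
      res
    })
  })
  values <- purrr::map_dbl(runs, "value")
  best <- runs[[which.min(values)]]
  if (!any(purrr::map_int(runs, "convergence") == 0L)) {
    abort("no optimisation start converged",
          class = "ng_fit_failure", trace = values)
  }
  theta <- best$par
  composites <- c(lambda1 = theta[[1]], lambda2 = theta[[2]],
                  K = exp(theta[[3]]), n1 = exp(theta[[4]]),
                  n2 = exp(theta[[5]]))
  ssr <- best$value
  # weighted R^2 on the same residual scale as the objective
  wmean <- sum(obs$mean / obs$sem^2) / sum(1 / obs$sem^2)
  tss <- sum(((obs$mean - wmean) / obs$sem)^2)
  structure(list(
    composites = composites, ssr = ssr,
    r_squared = 1 - ssr / tss, mode = mode,
    n_starts = n_starts, seed = seed,
    convergence = best$convergence,
    trace = tibble(start = seq_along(values), value = values,
                   convergence = purrr::map_int(runs, "convergence")),
    data = data
  ), class = "ng_fit")
}

#' @export
print.ng_fit <- function(x, ...) {
  cat("<ng_fit> mode:", x$mode, "\n")
  print(tidy(x))
  cat(sprintf("weighted SSR %.6g, weighted R^2 %.6g (%d starts, seed %d)\n",
              x$ssr, x$r_squared, x$n_starts, x$seed))
  invisible(x)
}

#' @rdname fit_age_series
#' @param x An `ng_fit` object.
#' @param ... Unused.
#' @export
tidy.ng_fit <- function(x, ...) {
  tibble(term = names(x$composites), estimate = unname(x$composites))
}

#' @rdname fit_age_series
#' @export
glance.ng_fit <- function(x, ...) {
  tibble(ssr = x$ssr, r.squared = x$r_squared, mode = x$mode,
         n_starts = x$n_starts, converged = x$convergence == 0L)
}

#' Fitted curves of an age-series fit on a dense grid
#'
#' @param fit An `ng_fit` object.
#' @param age Ages at which to evaluate the fitted curves (default: 200
#'   points spanning the observed range).
#' @return A tibble with `age`, `compartment` (stem, progenitor, ratio) and
#'   `fitted`.
#' @export
fitted_curves <- function(fit, age = NULL) {
  stopifnot(inherits(fit, "ng_fit"))
  age <- age %||% seq(min(fit$data$age), max(fit$data$age), length.out = 200)
  cv <- composite_curves(fit$composites, age)
  dplyr::bind_rows(
    tibble(age = age, compartment = "stem", fitted = cv$stem),
    tibble(age = age, compartment = "progenitor", fitted = cv$progenitor),
    tibble(age = age, compartment = "ratio", fitted = cv$stem / cv$progenitor)
  )
}

#' Weighted residual sum for one compartment under a fitted model
#'
#' Useful for judging how well a fit describes a compartment it was not
#' directly fitted to (e.g. progenitors under the stem+ratio mode).
#'
#' @inheritParams fitted_curves
#' @param data An age-series table.
#' @param compartment `"stem"`, `"progenitor"` or `"ratio"`.
#' @return Scalar weighted SSR over that compartment's observations.
#' @export
compartment_ssr <- function(fit, data, compartment) {
  data <- as_age_series(data)
  obs <- dplyr::filter(data, .data$compartment == !!compartment)
  if (compartment == "ratio" && nrow(obs) == 0) {
    obs <- fit_observations(data, "c1_ratio") |>
      dplyr::filter(.data$compartment == "ratio")
  }
  if (nrow(obs) == 0) abort("no observations for that compartment",
                            class = "ng_invalid_data")
  cv <- composite_curves(fit$composites, obs$age)
  model <- switch(compartment, stem = cv$stem, progenitor = cv$progenitor,
                  ratio = cv$stem / cv$progenitor)
  sum(((model - obs$mean) / obs$sem)^2)
}
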