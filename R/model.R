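#' System matrix of the linear compartment model
#'
#' The cell-count dynamics are `dc/dt = A c` with the constant matrix `A`
#' assembled from [derived_rates()]:
#' \deqn{c_1' = \lambda_1 c_1}
#' \deqn{c_2' = k_{12} c_1 + \lambda_2 c_2}
#' \deqn{c_3' = k_{23} c_2 - (p_3 + d_3) c_3}
#' \deqn{c_4' = p_3 c_3 - d_4 c_4}
#' \deqn{c_5' = k_{15} c_1 - d_5 c_5}
#'
#' @inheritParams derived_rates
#' @return A 5 x 5 numeric matrix with dimnames `c1..c5`.
#' @examples
#' ng_matrix(ng_params())
#' @export
ng_matrix <- function(params) {
  params <- as_ng_params(params)
  dr <- derived_rates(params)
  A <- matrix(0, 5, 5, dimnames = list(.ng_compartments, .ng_compartments))
  A[1, 1] <- dr$lambda1
  A[2, 1] <- dr$k12
  A[2, 2] <- dr$lambda2
  A[3, 2] <- dr$k23
  A[3, 3] <- -(params$p3 + params$d3)
  A[4, 3] <- params$p3
  A[4, 4] <- -params$d4
  A[5, 1] <- dr$k15
  A[5, 5] <- -params$d5
  A
}

#' Instantaneous rates of change of the compartment counts
#'
#' @inheritParams derived_rates
#' @param state An [ng_state()] vector (or coercible named vector) of
#'   nonnegative counts.
#' @return Named numeric vector of the five time-derivatives.
#' @examples
#' ng_rhs(ng_params(), ng_state())
#' @export
ng_rhs <- function(params, state) {
  state <- as_ng_state(state)
  drop(ng_matrix(params) %*% as.numeric(state))
}

#' Closed-form stem-cell count
#'
#' The stem compartment is autonomous, so `c1(t) = n1 * exp(lambda1 * t)`:
#' an exponential curve, declining whenever `a1 * theta1 < 1/2`.
#'
#' @inheritParams derived_rates
#' @param n1 Initial stem-cell count (>= 0).
#' @param t Vector of nonnegative times (model time units).
#' @return Numeric vector of stem-cell counts, same length as `t`.
#' @examples
#' closed_form_c1(ng_params(), n1 = 10000, t = c(0, 1, 5))
#' @export
closed_form_c1 <- function(params, n1, t) {
  stopifnot(n1 >= 0)
  if (any(t < 0)) abort("`t` must be nonnegative", class = "ng_invalid_time")
  dr <- derived_rates(as_ng_params(params))
  n1 * exp(dr$lambda1 * t)
}

#' Closed-form progenitor count
#'
#' Solution of the two-compartment cascade:
#' `c2(t) = n2 exp(lambda2 t) + k12 n1 (exp(lambda1 t) - exp(lambda2 t)) / (lambda1 - lambda2)`.
#' In the degenerate equal-rate case `lambda1 == lambda2` the limiting form
#' `n2 exp(lambda t) + k12 n1 t exp(lambda t)` is used (it is also used when
#' the rates are equal to within ~1e-12 relative, for numerical stability).
#'
#' @inheritParams closed_form_c1
#' @param n2 Initial progenitor count (>= 0).
#' @return Numeric vector of progenitor counts.
#' @examples
#' closed_form_c2(ng_params(), n1 = 10000, n2 = 5000, t = 1)
#' @export
closed_form_c2 <- function(params, n1, n2, t) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (any(t < 0)) abort("`t` must be nonnegative", class = "ng_invalid_time")
  dr <- derived_rates(as_ng_params(params))
  closed_c2_composite(dr$lambda1, dr$lambda2, dr$k12 * n1, n2, t)
}

# composite-parameter form shared with the fitting module:
# c2 = n2 e^(l2 t) + K (e^(l1 t) - e^(l2 t)) / (l1 - l2), K = k12 * n1
closed_c2_composite <- function(lambda1, lambda2, K, n2, t) {
  gap <- lambda1 - lambda2
  scale <- max(abs(lambda1), abs(lambda2), 1e-300)
  if (abs(gap) <= 1e-12 * scale) {
    n2 * exp(lambda2 * t) + K * t * exp(lambda2 * t)
  } else {
    n2 * exp(lambda2 * t) + K * (exp(lambda1 * t) - exp(lambda2 * t)) / gap
  }
}

#' Solve the compartment model on a time grid
#'
#' Numerically integrates the linear system with a stiff-capable adaptive
#' integrator (`deSolve::lsoda`, rtol 1e-10, atol 1e-12 by default) and
#' returns the trajectory as a tibble. For the stem and progenitor
#' compartments the result agrees with [closed_form_c1()] and
#' [closed_form_c2()] to solver tolerance.
#'
#' @inheritParams ng_rhs
#' @param times Numeric vector of output times starting at 0, strictly
#'   increasing.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `ng_trajectory` with columns `time`, `c1..c5`,
#'   carrying the parameter set and solver settings as attributes `params`
#'   and `solver`.
#' @examples
#' traj <- ng_solve(ng_params(), ng_state(), times = seq(0, 5, by = 0.5))
#' head(traj)
#' @export
ng_solve <- function(params, state, times, rtol = 1e-10, atol = 1e-12) {
  params <- as_ng_params(params)
  state <- as_ng_state(state)
  check_time_grid(times)
  A <- ng_matrix(params)
  out <- linear_ode_solve(A, as.numeric(state), times, rtol, atol)
  colnames(out) <- .ng_compartments
  res <- tibble(time = times) |> dplyr::bind_cols(as_tibble(out))
  new_trajectory(res, params, list(method = "lsoda", rtol = rtol, atol = atol))
}

check_time_grid <- function(times) {
  if (length(times) < 1L || times[1] != 0) {
    abort("time grid must start at 0", class = "ng_invalid_time")
  }
  if (any(diff(times) <= 0)) {
    abort("time grid must be strictly increasing", class = "ng_invalid_time")
  }
  invisible(times)
}

# integrate y' = A y on `times`; returns matrix without the time column.
# Negative round-off (below ~10 * atol) is clamped to zero.
linear_ode_solve <- function(A, y0, times, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) list(parms %*% y)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = deriv, parms = A,
    rtol = rtol, atol = atol, jacfunc = function(t, y, parms) parms,
    jactype = "fullusr"
  )
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf(
      "ODE solver failed (istate = %d; method lsoda, rtol %g, atol %g)",
      attr(sol, "istate")[1], rtol, atol
    ), class = "ng_solver_failure")
  }
  out <- unname(sol[, -1, drop = FALSE])
  tiny <- out < 0 & out > -1e4 * atol
  out[tiny] <- 0
  out
}

new_trajectory <- function(df, params, solver) {
  structure(df,
    class = c("ng_trajectory", class(tibble())),
    params = params, solver = solver
  )
}
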