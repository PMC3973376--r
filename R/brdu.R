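#' BrdU pulse-chase protocol
#'
#' Describes one labelling experiment relative to the time of the knockout:
#' BrdU is administered at time `t_hat` after the knockout, stays in the
#' organism for a duration `delta` (labelling every cell that divides during
#' that window), and labelled cells are counted `tau` time units after the
#' window ends.
#'
#' @param t_hat Time of BrdU administration after the knockout (>= 0).
#' @param delta Exposure duration (> 0 for any labelling to occur).
#' @param tau Chase time(s) after labelling ends (>= 0); may be a vector.
#' @return A list of class `ng_protocol`.
#' @examples
#' labeling_protocol(t_hat = 0, delta = 0.1, tau = seq(0, 10, by = 0.5))
#' @export
labeling_protocol <- function(t_hat = 0, delta = 0.1, tau = 0) {
  if (!is.finite(t_hat) || t_hat < 0) {
    abort("`t_hat` must be finite and >= 0", class = "ng_invalid_protocol")
  }
  if (!is.finite(delta) || delta < 0) {
    abort("`delta` must be finite and >= 0", class = "ng_invalid_protocol")
  }
  if (any(!is.finite(tau)) || any(tau < 0)) {
    abort("`tau` must be finite and >= 0", class = "ng_invalid_protocol")
  }
  structure(list(t_hat = t_hat, delta = delta, tau = tau),
            class = "ng_protocol")
}

#' Fraction of cells undergoing an event during an exposure window
#'
#' Event waiting times are exponential, so the fraction of cells that undergo
#' at least one event (division or transformation) during a window of length
#' `delta` is `1 - exp(-rate * delta)`.
#'
#' @param rate Per-cell event rate (>= 0).
#' @param delta Window duration (>= 0).
#' @return Fraction in `[0, 1)`, vectorised over both arguments.
#' @examples
#' division_fraction(rate = 1, delta = 0.1)
#' @export
division_fraction <- function(rate, delta) {
  stopifnot(all(rate >= 0), all(delta >= 0))
  -expm1(-rate * delta)
}

# linear map from compartment counts at the moment of BrdU injection to
# labelled counts at the end of the exposure window: l = M(params, delta) c.
# Only divisions label (transformations involve no DNA synthesis), so a
# fraction F_i = 1 - exp(-p_i delta) of cells undergoes an event, theta_i of
# those divide, and each division contributes on average 2*a (same-fate) and
# 2*(1-a) (other-fate) labelled daughters. Neurons arise by transformation
# only, hence row 4 is zero.
label_matrix <- function(params, delta) {
  params <- as_ng_params(params)
  F1 <- division_fraction(params$p1, delta)
  F2 <- division_fraction(params$p2, delta)
  M <- matrix(0, 5, 5, dimnames = list(.ng_labels, .ng_compartments))
  M[1, 1] <- F1 * params$theta1 * 2 * params$a1
  M[2, 1] <- F1 * params$theta1 * 2 * (1 - params$a1) * params$kappa
  M[2, 2] <- F2 * params$theta2 * 2 * params$a2
  M[3, 2] <- F2 * params$theta2 * 2 * (1 - params$a2)
  M[5, 1] <- F1 * params$theta1 * 2 * (1 - params$a1) * (1 - params$kappa)
  M
}

#' Labelled cells at the end of the BrdU exposure window
#'
#' Computes the initial labelled pools from the compartment counts present at
#' the moment of BrdU injection. A fraction `1 - exp(-p_i * delta)` of cells
#' undergoes an event during the window; of those, a fraction `theta_i`
#' divides, each division contributing on average `2*a_i` same-fate and
#' `2*(1 - a_i)` other-fate labelled daughters. Direct transformations do
#' not label (no DNA synthesis), so there are no labelled neurons at the end
#' of the exposure (`l4 = 0`). Multiple divisions of the same lineage inside
#' one window are neglected (an `O(delta^2)` error, quantified by the
#' stochastic oracle [simulate_brdu()]).
#'
#' @inheritParams ng_rhs
#' @param state Compartment counts at the moment of injection.
#' @param delta Exposure duration (>= 0).
#' @return A one-row tibble with columns `l1..l5`.
#' @examples
#' initial_labels(ng_params(), ng_state(), delta = 0.1)
#' @export
initial_labels <- function(params, state, delta) {
  state <- as_ng_state(state)
  l <- drop(label_matrix(params, delta) %*% as.numeric(state))
  as_tibble(as.list(l))
}

# per-capita rate at which divisions of an UNLABELLED cell of compartment j
# create labelled cells of compartment i during the exposure window; the
# small-delta limit of label_matrix is B * delta
label_creation_matrix <- function(params) {
  p <- as_ng_params(params)
  B <- matrix(0, 5, 5, dimnames = list(.ng_labels, .ng_compartments))
  B[1, 1] <- 2 * p$a1 * p$theta1 * p$p1
  B[2, 1] <- 2 * (1 - p$a1) * p$theta1 * p$kappa * p$p1
  B[5, 1] <- 2 * (1 - p$a1) * p$theta1 * (1 - p$kappa) * p$p1
  B[2, 2] <- 2 * p$a2 * p$theta2 * p$p2
  B[3, 2] <- 2 * (1 - p$a2) * p$theta2 * p$p2
  B
}

#' Exact expected labelled counts at the end of the exposure window
#'
#' The fraction-based [initial_labels()] formula anchors all divisions at
#' the injection-time counts and ignores everything that happens to cells
#' *during* the window. Under the exact event-level dynamics the expected
#' labelled counts instead solve the linear system
#' `dL/dt = A L + B (c - L)` with `L = 0` at the start of the window, where
#' `A` is the compartment matrix and `B` the per-capita labelled-daughter
#' creation matrix (`label_matrix` is `B * delta` to first order). This
#' function integrates that system over the window and therefore gives the
#' exact mean of the stochastic simulator [simulate_brdu()] at `tau = 0`.
#' The difference from [initial_labels()] quantifies the error of the
#' fraction construction: within-window population drift, label migration
#' between compartments (e.g. labelled progenitors transforming into
#' neuroblasts, giving labelled neuroblasts and even a handful of labelled
#' neurons already at `tau = 0`), and repeat divisions.
#'
#' @inheritParams initial_labels
#' @return A one-row tibble with columns `l1..l5`.
#' @examples
#' window_label_mean(ng_params(), ng_state(), delta = 0.05)
#' initial_labels(ng_params(), ng_state(), delta = 0.05)
#' @export
window_label_mean <- function(params, state, delta) {
  params <- as_ng_params(params)
  state <- as_ng_state(state)
  if (delta == 0) {
    return(as_tibble(as.list(setNames(rep(0, 5), .ng_labels))))
  }
  A <- ng_matrix(params)
  B <- label_creation_matrix(params)
  blk <- rbind(cbind(A, matrix(0, 5, 5)), cbind(B, A - B))
  out <- linear_ode_solve(blk, c(as.numeric(state), rep(0, 5)), c(0, delta))
  as_tibble(as.list(setNames(out[2, 6:10], .ng_labels)))
}

#' Chase-phase dynamics of BrdU-labelled cells
#'
#' After the exposure window ends, labelled cells of each type follow the
#' same linear dynamics as their compartments (all progeny of a labelled
#' cell are labelled; BrdU dilution is ignored). This simply integrates the
#' compartment system from the labelled initial pools over the chase times.
#'
#' @inheritParams ng_solve
#' @param labels0 Labelled counts at the end of exposure: a one-row tibble or
#'   named vector `l1..l5` (e.g. from [initial_labels()]).
#' @param tau Chase-time grid starting at 0.
#' @return An `ng_trajectory` tibble with columns `time` (chase time tau) and
#'   `l1..l5`.
#' @examples
#' l0 <- initial_labels(ng_params(), ng_state(), delta = 0.1)
#' labeled_trajectory(ng_params(), l0, tau = seq(0, 5, by = 0.5))
#' @export
labeled_trajectory <- function(params, labels0, tau, rtol = 1e-10, atol = 1e-12) {
  l0 <- unlist(labels0)[if (all(.ng_labels %in% names(unlist(labels0)))) .ng_labels else seq_len(5)]
  traj <- ng_solve(params, setNames(as.numeric(l0), .ng_compartments), tau,
                   rtol = rtol, atol = atol)
  names(traj) <- c("time", .ng_labels)
  traj
}

#' BrdU-incorporating cells as a function of the injection time
#'
#' The number of BrdU-incorporating cells of compartment `i` is the labelled
#' count at the end of an exposure that started at time `t` after the
#' knockout, i.e. the labelled pools [initial_labels()] evaluated on the
#' running solution: `l_i_plus(t) = l_i(t_hat = t, tau = 0)`. Because every
#' labelled pool is a fixed linear combination of `c1(t)` and `c2(t)`,
#' ratios such as `l5_plus / l1_plus` are constant in `t`, and
#' `l4_plus(t) = 0` for all `t`.
#'
#' @inheritParams ng_solve
#' @param delta Exposure duration.
#' @return A tibble with columns `time` and `l1..l5`.
#' @examples
#' brdu_series(ng_params(), ng_state(), times = seq(0, 10, by = 1), delta = 0.1)
#' @export
brdu_series <- function(params, state, times, delta, rtol = 1e-10, atol = 1e-12) {
  traj <- ng_solve(params, state, times, rtol = rtol, atol = atol)
  M <- label_matrix(params, delta)
  counts <- as.matrix(traj[, .ng_compartments])
  lab <- counts %*% t(M)
  colnames(lab) <- .ng_labels
  dplyr::bind_cols(tibble(time = times), as_tibble(lab))
}
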