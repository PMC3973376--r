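#' Kinetic parameters of the neurogenesis model
#'
#' Construct and validate the twelve kinetic parameters of the five-compartment
#' neurogenesis model. Stem cells divide (probability `theta1`) or transform
#' directly into astrocytes (probability `1 - theta1`) at per-cell rate `p1`;
#' a division is symmetric (two stem daughters) with probability `2*a1 - 1`
#' and asymmetric otherwise, the non-stem daughter being a progenitor with
#' probability `kappa` or an astrocyte with probability `1 - kappa`.
#' Progenitors behave analogously (`a2`, `theta2`, `p2`), their transformation
#' and asymmetric-division output being neuroblasts, and die at rate `d2`.
#' Neuroblasts mature into neurons at rate `p3` and die at rate `d3`; neurons
#' and astrocytes die at rates `d4` and `d5`. Stem cells have no independent
#' death term: their only loss channel is astrocytic transformation.
#'
#' The defaults are the reference simulation set used throughout the package
#' documentation and tests. Time units are abstract ("model time units").
#'
#' @param a1,a2 Fractions of self-renewal, in `[1/2, 1]`: probability that a
#'   daughter cell has the same fate as its mother. `2*a - 1` is the
#'   symmetric-division probability.
#' @param theta1,theta2 Division probabilities, in `[0, 1]`: probability that
#'   the next event of a cell is a division rather than a transformation.
#' @param p1,p2 Proliferation rates (> 0, per model time unit): per-cell rate
#'   of undergoing an event (division or transformation).
#' @param kappa Probability, in `[0, 1]`, that the non-stem daughter of an
#'   asymmetric stem division is a progenitor rather than an astrocyte.
#' @param p3 Neuroblast maturation rate (> 0).
#' @param d2,d3,d4,d5 Death rates (>= 0) of progenitors, neuroblasts, neurons
#'   and astrocytes.
#'
#' @return An object of class `ng_params`: a validated named list with the
#'   twelve entries above.
#' @examples
#' pars <- ng_params()
#' derived_rates(pars)
#' @export
ng_params <- function(a1 = 0.55, theta1 = 0.7, p1 = 1, kappa = 0.6,
                      a2 = 0.7, theta2 = 0.4, p2 = 2.5, d2 = 0.1,
                      p3 = 1.5, d3 = 0.4, d4 = 0.05, d5 = 0.05) {
  pars <- list(
    a1 = a1, theta1 = theta1, p1 = p1, kappa = kappa,
    a2 = a2, theta2 = theta2, p2 = p2, d2 = d2,
    p3 = p3, d3 = d3, d4 = d4, d5 = d5
  )
  validate_ng_params(pars)
  structure(pars, class = "ng_params")
}

validate_ng_params <- function(pars) {
  chk <- function(name, ok, rule) {
    v <- pars[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || !ok(v)) {
      abort(
        sprintf("invalid parameter `%s` = %s (must satisfy %s)",
                name, format(pars[[name]]), rule),
        class = "ng_invalid_parameter",
        parameter = name
      )
    }
  }
  chk("a1", function(v) v >= 0.5 && v <= 1, "1/2 <= a1 <= 1")
  chk("a2", function(v) v >= 0.5 && v <= 1, "1/2 <= a2 <= 1")
  chk("theta1", function(v) v >= 0 && v <= 1, "0 <= theta1 <= 1")
  chk("theta2", function(v) v >= 0 && v <= 1, "0 <= theta2 <= 1")
  chk("kappa", function(v) v >= 0 && v <= 1, "0 <= kappa <= 1")
  chk("p1", function(v) v > 0, "p1 > 0")
  chk("p2", function(v) v > 0, "p2 > 0")
  chk("p3", function(v) v > 0, "p3 > 0")
  for (d in c("d2", "d3", "d4", "d5")) chk(d, function(v) v >= 0, paste(d, ">= 0"))
  invisible(pars)
}

#' @export
print.ng_params <- function(x, ...) {
  cat("<ng_params>\n")
  cat("  stem:       a1 =", x$a1, " theta1 =", x$theta1, " p1 =", x$p1,
      " kappa =", x$kappa, "\n")
  cat("  progenitor: a2 =", x$a2, " theta2 =", x$theta2, " p2 =", x$p2,
      " d2 =", x$d2, "\n")
  cat("  downstream: p3 =", x$p3, " d3 =", x$d3, " d4 =", x$d4,
      " d5 =", x$d5, "\n")
  dr <- derived_rates(x)
  cat("  net rates:  lambda1 =", signif(dr$lambda1, 6),
      " lambda2 =", signif(dr$lambda2, 6), "\n")
  invisible(x)
}

#' Initial cell counts per compartment
#'
#' The defaults are the reference initial state used in the package's
#' simulations: 10000 stem cells, 5000 progenitors, 15000 neuroblasts,
#' 350000 neurons and 100000 astrocytes.
#'
#' @param c1,c2,c3,c4,c5 Nonnegative cell counts for stem cells, progenitors,
#'   neuroblasts, neurons and astrocytes.
#' @return A named numeric vector of class `ng_state`.
#' @examples
#' ng_state()
#' ng_state(c1 = 100, c2 = 0, c3 = 0, c4 = 0, c5 = 0)
#' @export
ng_state <- function(c1 = 10000, c2 = 5000, c3 = 15000, c4 = 350000,
                     c5 = 100000) {
  state <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  if (!all(is.finite(state)) || any(state < 0)) {
    bad <- .ng_compartments[which(!is.finite(state) | state < 0)[1]]
    abort(sprintf("invalid cell count `%s`: counts must be finite and >= 0", bad),
          class = "ng_invalid_state", compartment = bad)
  }
  structure(state, class = c("ng_state", "numeric"))
}

as_ng_state <- function(x) {
  if (inherits(x, "ng_state")) return(x)
  x <- unlist(x)
  if (is.null(names(x))) names(x) <- .ng_compartments
  do.call(ng_state, as.list(x[.ng_compartments]))
}

#' Net rates and flux coefficients implied by a parameter set
#'
#' Collapses the division bookkeeping into the coefficients of the linear
#' system: net per-capita rates `lambda1 = (2*a1*theta1 - 1)*p1` (stem) and
#' `lambda2 = (2*a2*theta2 - 1)*p2 - d2` (progenitor), flux coefficients
#' `k12` (stem to progenitor, via asymmetric divisions), `k23` (progenitor to
#' neuroblast, via asymmetric divisions and transformations) and `k15` (stem
#' to astrocyte, via transformations and asymmetric divisions), and the
#' expected net change of the stem-cell count per stem event,
#' `2*a1*theta1 - 1 = lambda1 / p1`.
#'
#' @param params An [ng_params()] object.
#' @return A one-row tibble with columns `lambda1`, `lambda2`, `k12`, `k23`,
#'   `k15`, `net_event_change`.
#' @examples
#' derived_rates(ng_params())
#' @export
derived_rates <- function(params) {
  params <- as_ng_params(params)
  with(params, tibble(
    lambda1 = (2 * a1 * theta1 - 1) * p1,
    lambda2 = (2 * a2 * theta2 - 1) * p2 - d2,
    k12 = 2 * (1 - a1) * theta1 * kappa * p1,
    k23 = (2 * (1 - a2) * theta2 + (1 - theta2)) * p2,
    k15 = ((1 - theta1) + 2 * (1 - a1) * theta1 * (1 - kappa)) * p1,
    net_event_change = 2 * a1 * theta1 - 1
  ))
}

as_ng_params <- function(x) {
  if (inherits(x, "ng_params")) return(x)
  if (is.list(x) || is.numeric(x)) return(do.call(ng_params, as.list(x)))
  abort("cannot interpret `params`; use ng_params()", class = "ng_invalid_parameter")
}

#' Does the stem-cell pool decline?
#'
#' The stem-cell count is non-increasing for all times if and only if
#' symmetric self-renewing divisions are no more likely than astrocytic
#' transformations, i.e. `a1 * theta1 <= 1/2`. Equality is the balanced
#' boundary at which the stem pool stays constant.
#'
#' @inheritParams derived_rates
#' @return A one-row tibble with `declining` (logical), `margin`
#'   (`1/2 - a1*theta1`; positive means strict decline) and `boundary`
#'   (logical, `a1*theta1 == 1/2`).
#' @examples
#' check_stem_decline(ng_params())
#' @export
check_stem_decline <- function(params) {
  params <- as_ng_params(params)
  margin <- 0.5 - params$a1 * params$theta1
  tibble(declining = margin >= 0, margin = margin, boundary = margin == 0)
}

#' Long-time limit of the stem/progenitor ratio
#'
#' As time grows, the ratio of stem cells to progenitors converges to 0 when
#' the stem pool depletes faster (`lambda1 < lambda2`), and to the positive
#' constant `(lambda1 - lambda2) / k12` when progenitors deplete faster.
#' With no stem-to-progenitor flux (`k12 = 0`) but `lambda1 > lambda2` the
#' ratio diverges and `Inf` is returned. In the degenerate equal-rate case
#' the limit is 0 (the progenitor pool gains a secular `t * exp(lambda*t)`
#' term) and the result is flagged with attribute `degenerate = TRUE`.
#'
#' @inheritParams derived_rates
#' @return A scalar limit value (possibly `Inf`), with attribute
#'   `degenerate` when `lambda1 == lambda2`.
#' @examples
#' asymptotic_ratio(ng_params())
#' @export
asymptotic_ratio <- function(params) {
  params <- as_ng_params(params)
  dr <- derived_rates(params)
  if (dr$lambda1 == dr$lambda2) {
    return(structure(if (dr$k12 > 0) 0 else Inf, degenerate = TRUE))
  }
  if (dr$lambda1 < dr$lambda2) return(0)
  if (dr$k12 == 0) return(Inf)
  (dr$lambda1 - dr$lambda2) / dr$k12
}

#' Check the declining-niche parameter regime
#'
#' The analytic sign results for knockout responses require two conditions:
#' the stem pool declines (`a1*theta1 < 1/2`) and the net depletion rate of
#' progenitors exceeds that of stem cells (`lambda2 < lambda1`).
#'
#' @inheritParams derived_rates
#' @return A one-row tibble with logicals `stem_decline` and
#'   `progenitor_depletes_faster`, and `holds` (their conjunction).
#' @examples
#' check_assumption(ng_params())
#' @export
check_assumption <- function(params) {
  params <- as_ng_params(params)
  dr <- derived_rates(params)
  a <- params$a1 * params$theta1 < 0.5
  b <- dr$lambda2 - dr$lambda1 < 0
  tibble(stem_decline = a, progenitor_depletes_faster = b, holds = a && b)
}
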