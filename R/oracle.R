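ng_pars_vector <- function(params) {
  params <- as_ng_params(params)
  unlist(params[ng_param_names])
}

check_integer_counts <- function(state) {
  state <- as_ng_state(state)
  if (any(state != round(state))) {
    abort("stochastic simulation requires integer initial counts",
          class = "ng_invalid_state")
  }
  state
}

#' Exact stochastic simulation of the cell population
#'
#' Event-driven (Gillespie) simulation of the individual cell rules whose
#' mean-field limit is the compartment ODE system: stem events at rate
#' `p1 * N1` resolve into symmetric/asymmetric divisions or astrocytic
#' transformation, progenitor events at rate `p2 * N2` into divisions or
#' transformation to neuroblast, plus the linear death and maturation
#' channels. Ensemble means of replicate runs converge to [ng_solve()]
#' solutions. Simulation is population-level (propensity-based), which is
#' distributionally exact for these linear rates.
#'
#' @inheritParams ng_solve
#' @param state Integer initial counts.
#' @param times Output time grid starting at 0.
#' @param n_rep Number of replicate runs.
#' @param seed Optional integer seed (R RNG stream); identical seeds give
#'   identical event sequences.
#' @param max_events Guard against runaway populations; the simulation stops
#'   with an error beyond this many events in one replicate.
#' @return A tibble with columns `replicate`, `time`, `c1..c5`.
#' @examples
#' sim <- simulate_population(ng_params(), ng_state(c1 = 100, c2 = 50, c3 = 0,
#'                                                 c4 = 0, c5 = 0),
#'                            times = c(0, 1), n_rep = 5, seed = 1)
#' @export
simulate_population <- function(params, state, times, n_rep = 1, seed = NULL,
                                max_events = 1e7) {
  state <- check_integer_counts(state)
  check_time_grid(times)
  pars <- ng_pars_vector(params)
  run <- function() {
    purrr::map(seq_len(n_rep), function(r) {
      m <- sim_gillespie_cpp(pars, as.numeric(state), rep(0, 5),
                             0, 0, times, max_events)
      colnames(m) <- c(.ng_compartments, .ng_labels)
      dplyr::bind_cols(tibble(replicate = r, time = times),
                       as_tibble(m[, .ng_compartments, drop = FALSE]))
    }) |> purrr::list_rbind()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Stochastic simulation of a BrdU pulse-chase experiment
#'
#' As [simulate_population()], but every division completing during the
#' exposure window `[t_hat, t_hat + delta]` marks both daughters as
#' labelled; labels are heritable and transformations never create a label.
#' Labelled counts are recorded at the protocol's chase times `tau`
#' (measured from the end of the window), so there are never labelled
#' neurons at `tau = 0`.
#'
#' @inheritParams simulate_population
#' @param protocol A [labeling_protocol()].
#' @return A tibble with columns `replicate`, `tau`, totals `c1..c5` and
#'   labelled counts `l1..l5`.
#' @examples
#' pr <- labeling_protocol(t_hat = 0, delta = 0.05, tau = c(0, 1))
#' sim <- simulate_brdu(ng_params(), ng_state(c1 = 200, c2 = 100, c3 = 0,
#'                                            c4 = 0, c5 = 0),
#'                      pr, n_rep = 5, seed = 1)
#' @export
simulate_brdu <- function(params, state, protocol, n_rep = 1, seed = NULL,
                          max_events = 1e7) {
  state <- check_integer_counts(state)
  stopifnot(inherits(protocol, "ng_protocol"))
  pars <- ng_pars_vector(params)
  out_times <- protocol$t_hat + protocol$delta + protocol$tau
  run <- function() {
    purrr::map(seq_len(n_rep), function(r) {
      m <- sim_gillespie_cpp(pars, as.numeric(state), rep(0, 5),
                             protocol$t_hat, protocol$delta, out_times,
                             max_events)
      colnames(m) <- c(.ng_compartments, .ng_labels)
      dplyr::bind_cols(tibble(replicate = r, tau = protocol$tau), as_tibble(m))
    }) |> purrr::list_rbind()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Ensemble mean and Monte-Carlo standard error per compartment
#'
#' @param sim Output of [simulate_population()] or [simulate_brdu()].
#' @return A long tibble with columns `time` (or `tau`), `quantity`
#'   (`c1..c5`, `l1..l5`), `mean`, `se`, `n_rep`.
#' @export
ensemble_summary <- function(sim) {
  timecol <- if ("tau" %in% names(sim)) "tau" else "time"
  sim |>
    tidyr::pivot_longer(dplyr::any_of(c(.ng_compartments, .ng_labels)),
                        names_to = "quantity", values_to = "count") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(timecol, "quantity")))) |>
    dplyr::summarise(
      mean = mean(.data$count),
      se = sd(.data$count) / sqrt(dplyr::n()),
      n_rep = dplyr::n(), .groups = "drop"
    )
}
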