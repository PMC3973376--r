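#' Design of a synthetic age-decline study
#'
#' Describes how to generate an age series of stem and progenitor counts
#' emulating stereological count tables (per-age means with standard
#' errors). Counts at each age are `replicates` noisy evaluations of the
#' closed-form model curves; the reported mean is the replicate average and
#' the s.e.m. the replicate standard deviation over `sqrt(replicates)`.
#'
#' Defaults: 10 ages spanning `[0, 24]` model time units (evoking months of
#' adult age), multiplicative lognormal noise with a 5% coefficient of
#' variation, and 4 replicates per age — plausible for stereological
#' counting studies.
#'
#' @param ages Increasing observation ages.
#' @param params True kinetic parameters.
#' @param state True initial counts.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates Animals per age (>= 2 unless `cv = 0`).
#' @param noise `"lognormal"` (mean-preserving) or `"truncnorm"`
#'   (normal with sd `cv * mean`, truncated at 0).
#' @param saturation_floor Optional floor (in cells) applied to the true
#'   late-age stem counts before noise, emulating a residual quiescent pool
#'   that a pure exponential decline cannot describe.
#' @param sem_floor Standard error reported when `cv = 0` (noise-free data
#'   still need positive weights).
#' @param seed Optional integer seed.
#' @return A list of class `ng_design`.
#' @export
age_series_design <- function(ages = seq(0, 24, length.out = 10),
                              params = ng_params(), state = ng_state(),
                              cv = 0.05, replicates = 4,
                              noise = c("lognormal", "truncnorm"),
                              saturation_floor = NULL, sem_floor = 1,
                              seed = NULL) {
  noise <- match.arg(noise)
  if (cv < 0) abort("`cv` must be >= 0", class = "ng_invalid_design")
  if (replicates < 1 || (cv > 0 && replicates < 2)) {
    abort("`replicates` must be >= 2 when the s.e.m. is derived from replicates",
          class = "ng_invalid_design")
  }
  if (any(ages < 0) || any(diff(ages) <= 0)) {
    abort("`ages` must be nonnegative and increasing", class = "ng_invalid_design")
  }
  structure(list(
    ages = ages, params = as_ng_params(params), state = as_ng_state(state),
    cv = cv, replicates = replicates, noise = noise,
    saturation_floor = saturation_floor, sem_floor = sem_floor, seed = seed
  ), class = "ng_design")
}

#' Generate a synthetic age series
#'
#' @param design An [age_series_design()].
#' @return An age-series tibble (columns `age`, `compartment`, `mean`,
#'   `sem`; see [as_age_series()]). Deterministic for a given design seed.
#' @examples
#' generate_age_series(age_series_design(cv = 0, seed = 1))
#' @export
generate_age_series <- function(design) {
  stopifnot(inherits(design, "ng_design"))
  truth_stem <- closed_form_c1(design$params, design$state[["c1"]], design$ages)
  if (!is.null(design$saturation_floor)) {
    truth_stem <- pmax(truth_stem, design$saturation_floor)
  }
  truth_prog <- closed_form_c2(design$params, design$state[["c1"]],
                               design$state[["c2"]], design$ages)
  gen <- function() {
    one <- function(truth, compartment) {
      purrr::map2(design$ages, truth, function(a, mu) {
        if (design$cv == 0) {
          return(tibble(age = a, compartment = compartment, mean = mu,
                        sem = design$sem_floor))
        }
        draws <- if (design$noise == "lognormal") {
          sdlog <- sqrt(log1p(design$cv^2))
          stats::rlnorm(design$replicates, log(mu) - sdlog^2 / 2, sdlog)
        } else {
          pmax(rnorm(design$replicates, mu, design$cv * mu), 0)
        }
        tibble(age = a, compartment = compartment, mean = mean(draws),
               sem = max(sd(draws) / sqrt(design$replicates), 1e-12))
      }) |> purrr::list_rbind()
    }
    dplyr::bind_rows(one(truth_stem, "stem"), one(truth_prog, "progenitor")) |>
      dplyr::arrange(.data$age, .data$compartment)
  }
  out <- if (is.null(design$seed)) gen() else withr::with_seed(design$seed, gen())
  as_age_series(out)
}

#' Generate a paired wild-type / knockout dataset
#'
#' Noisy paired observations of cell counts (and, when a protocol is given,
#' BrdU-labelled counts) under a baseline parameter set and under the same
#' set with one parameter shifted by `delta_p` — the structure of an
#' inducible-knockout readout.
#'
#' @inheritParams sensitivity
#' @param delta_p Parameter shift defining the knockout arm (the perturbed
#'   value must remain in the valid domain).
#' @param times Observation times after the knockout.
#' @param protocol Optional [labeling_protocol()]; when supplied, labelled
#'   counts `l1..l5` at the protocol's chase times are observed too.
#' @param cv Coefficient of variation of the lognormal observation noise.
#' @param replicates Animals per group and time point.
#' @param seed Optional integer seed.
#' @return A tibble with columns `group` (`"wild_type"` / `"knockout"`),
#'   `time`, `quantity` (`c1..c5`, `l1..l5`), `mean`, `sem`.
#' @examples
#' generate_ko_dataset(ng_params(), ng_state(), "a1", 0.05,
#'                     times = c(0, 1, 2), seed = 1)
#' @export
generate_ko_dataset <- function(params, state, param, delta_p, times,
                                protocol = NULL, cv = 0.05, replicates = 4,
                                seed = NULL) {
  params <- as_ng_params(params)
  check_param_name(param)
  pl <- unclass(params)
  pl[[param]] <- pl[[param]] + delta_p
  ko_params <- as_ng_params(pl)

  truth_for <- function(pp) {
    counts <- ng_solve(pp, state, times) |>
      tidyr::pivot_longer(dplyr::all_of(.ng_compartments),
                          names_to = "quantity", values_to = "truth")
    if (is.null(protocol)) return(counts)
    c_hat <- if (protocol$t_hat > 0) {
      as.matrix(ng_solve(pp, state, c(0, protocol$t_hat))[2, .ng_compartments])[1, ]
    } else {
      as.numeric(as_ng_state(state))
    }
    l0 <- drop(label_matrix(pp, protocol$delta) %*% c_hat)
    labs <- labeled_trajectory(pp, l0, protocol$tau) |>
      tidyr::pivot_longer(dplyr::all_of(.ng_labels),
                          names_to = "quantity", values_to = "truth")
    dplyr::bind_rows(counts, labs)
  }

  gen <- function() {
    sdlog <- sqrt(log1p(cv^2))
    purrr::map2(
      list("wild_type", "knockout"), list(params, ko_params),
      function(group, pp) {
        truth_for(pp) |>
          dplyr::rowwise() |>
          dplyr::mutate(draws = list(
            if (cv == 0) rep(.data$truth, replicates)
            else stats::rlnorm(replicates,
                               log(max(.data$truth, 1e-300)) - sdlog^2 / 2,
                               sdlog) * (.data$truth > 0)
          )) |>
          dplyr::ungroup() |>
          dplyr::mutate(
            group = group,
            mean = purrr::map_dbl(.data$draws, mean),
            sem = purrr::map_dbl(.data$draws, ~ sd(.x) / sqrt(replicates))
          ) |>
          dplyr::select(dplyr::all_of(c("group", "time", "quantity", "mean", "sem")))
      }
    ) |> purrr::list_rbind()
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
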