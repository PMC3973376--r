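ng_config_keys <- c("kind", "params", "init", "times", "protocol", "param",
                    "delta", "delta_p", "fit", "design", "data", "n_rep",
                    "seed", "solver", "out_prefix")

#' Load and validate a scenario configuration
#'
#' Reads a JSON or YAML file describing one reproducible analysis run.
#' Recognised top-level keys: `kind` (one of `counts`, `brdu`,
#' `sensitivity`, `table1`, `fit`, `oracle`, `synth`), `params` (kinetic
#' parameters; unspecified entries take the [ng_params()] defaults), `init`
#' (initial counts, [ng_state()] defaults), `times` (either a numeric
#' vector or `{from, to, n}`; default 3001 points on `[0, 30]`), `protocol`
#' (`t_hat`, `delta`, `tau`), `param`, `delta`, `delta_p`, `fit`
#' (`mode`, `n_starts`), `design` (passed to [age_series_design()]),
#' `data` (CSV path of an age series for `kind: fit`), `n_rep`, `seed`,
#' `solver` (`rtol`, `atol`), `out_prefix`. Unknown keys are rejected with
#' their names; invalid parameter values surface the offending field.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated list of class `ng_config` with defaults applied.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "ng_invalid_config")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_scenario_config(raw)
}

#' @rdname load_scenario_config
#' @param config A plain list with the same structure as the file contents.
#' @export
as_scenario_config <- function(config) {
  unknown <- setdiff(names(config), ng_config_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "ng_invalid_config")
  }
  kinds <- c("counts", "brdu", "sensitivity", "table1", "fit", "oracle", "synth")
  kind <- config$kind %||% "counts"
  if (!kind %in% kinds) {
    abort(sprintf("`kind` must be one of: %s", paste(kinds, collapse = ", ")),
          class = "ng_invalid_config")
  }
  params <- do.call(ng_params, as.list(config$params %||% list()))
  init <- do.call(ng_state, as.list(config$init %||% list()))
  grid <- function(x, default_from = 0, default_to = 30, default_n = 3001) {
    if (is.null(x)) return(seq(default_from, default_to, length.out = default_n))
    if (is.list(x)) {
      return(seq(x$from %||% default_from, x$to %||% default_to,
                 length.out = x$n %||% default_n))
    }
    as.numeric(x)
  }
  solver <- config$solver %||% list()
  rtol <- solver$rtol %||% 1e-10
  atol <- solver$atol %||% 1e-12
  if (rtol <= 0 || rtol > 1e-2 || atol <= 0 || atol > 1e-4) {
    abort("solver overrides out of range (need 0 < rtol <= 1e-2, 0 < atol <= 1e-4)",
          class = "ng_invalid_config")
  }
  protocol <- NULL
  if (!is.null(config$protocol) || kind %in% c("brdu", "oracle")) {
    pr <- config$protocol %||% list()
    protocol <- labeling_protocol(
      t_hat = pr$t_hat %||% 0,
      delta = pr$delta %||% 0.1,
      tau = grid(pr$tau)
    )
  }
  if (!is.null(config$data) && !file.exists(config$data)) {
    abort(sprintf("data file not found: %s", config$data),
          class = "ng_invalid_config")
  }
  structure(list(
    kind = kind, params = params, init = init,
    times = grid(config$times),
    protocol = protocol,
    param = config$param %||% "a1",
    delta = config$delta %||% 0.1,
    delta_p = config$delta_p %||% NULL,
    fit = list(mode = (config$fit %||% list())$mode %||% "c1_c2",
               n_starts = (config$fit %||% list())$n_starts %||% 100),
    design = config$design %||% list(),
    data = config$data %||% NULL,
    n_rep = config$n_rep %||% 200,
    seed = config$seed %||% 1,
    solver = list(rtol = rtol, atol = atol),
    out_prefix = config$out_prefix %||% "neurodyn"
  ), class = "ng_config")
}

#' Run a configured scenario and write its artifacts
#'
#' Executes one analysis stage from a validated configuration and writes its
#' outputs (CSV tables, JSON summaries) plus a JSON run log recording the
#' package version, seed and solver settings. Outputs are deterministic for
#' a given config and seed.
#'
#' @param config An `ng_config` from [load_scenario_config()] /
#'   [as_scenario_config()].
#' @param out_dir Directory for the written artifacts (created if missing).
#' @return Invisibly, a named list of written file paths.
#' @examples
#' cfg <- as_scenario_config(list(kind = "counts",
#'                                times = list(from = 0, to = 2, n = 21)))
#' run_scenario(cfg, out_dir = tempfile("ng"))
#' @export
run_scenario <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "ng_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(suffix) file.path(out_dir,
                                     paste0(config$out_prefix, "_", suffix))
  written <- list()
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("scenario stage `%s` failed: %s", stage, conditionMessage(e)),
            class = "ng_scenario_failure", parent = e)
    })
  }
  rtol <- config$solver$rtol; atol <- config$solver$atol

  if (config$kind == "counts") {
    traj <- with_stage("counts", ng_solve(config$params, config$init,
                                          config$times, rtol, atol))
    written$counts <- path("counts.csv")
    readr::write_csv(as_tibble(traj), written$counts)
  } else if (config$kind == "brdu") {
    pr <- config$protocol
    lab <- with_stage("brdu", {
      c_hat <- if (pr$t_hat > 0) {
        as.matrix(ng_solve(config$params, config$init, c(0, pr$t_hat),
                           rtol, atol)[2, .ng_compartments])[1, ]
      } else {
        as.numeric(config$init)
      }
      l0 <- initial_labels(config$params, c_hat, pr$delta)
      labeled_trajectory(config$params, l0, pr$tau, rtol, atol)
    })
    written$brdu <- path("brdu.csv")
    readr::write_csv(dplyr::rename(as_tibble(lab), tau = "time"), written$brdu)
  } else if (config$kind == "sensitivity") {
    s <- with_stage("sensitivity",
                    sensitivity(config$params, config$init, config$param,
                                config$times, rtol, atol))
    written$sensitivity <- path("sensitivity.csv")
    readr::write_csv(as_tibble(s), written$sensitivity)
    seqs <- purrr::map(.ng_compartments,
                       ~ format(sign_sequence(s$time, s[[.x]])))
    written$signs <- path("signs.json")
    jsonlite::write_json(setNames(seqs, .ng_compartments), written$signs,
                         auto_unbox = TRUE, pretty = TRUE)
  } else if (config$kind == "table1") {
    tab <- with_stage("table1",
                      ko_sign_table(config$params, config$init, config$times,
                                    config$delta, rtol = rtol, atol = atol))
    written$table <- path("sign_table.json")
    wide <- tab |>
      dplyr::select(dplyr::all_of(c("parameter", "quantity", "signs"))) |>
      tidyr::pivot_wider(names_from = "quantity", values_from = "signs")
    jsonlite::write_json(wide, written$table, pretty = TRUE)
  } else if (config$kind == "fit") {
    data <- with_stage("fit", {
      if (!is.null(config$data)) {
        as_age_series(readr::read_csv(config$data, show_col_types = FALSE))
      } else {
        generate_age_series(do.call(age_series_design, c(
          config$design, list(params = config$params, state = config$init,
                              seed = config$seed)
        )))
      }
    })
    fit <- with_stage("fit", fit_age_series(data, config$fit$mode,
                                            n_starts = config$fit$n_starts,
                                            seed = config$seed))
    written$fit <- path("fit.json")
    jsonlite::write_json(
      list(composites = as.list(fit$composites), ssr = fit$ssr,
           r_squared = fit$r_squared, mode = fit$mode),
      written$fit, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written$curves <- path("fit_curves.csv")
    readr::write_csv(fitted_curves(fit), written$curves)
  } else if (config$kind == "oracle") {
    pr <- config$protocol
    sim <- with_stage("oracle",
                      simulate_brdu(config$params, round(config$init), pr,
                                    n_rep = config$n_rep, seed = config$seed))
    written$replicates <- path("oracle_replicates.csv")
    readr::write_csv(sim, written$replicates)
    written$summary <- path("oracle_summary.json")
    jsonlite::write_json(ensemble_summary(sim), written$summary,
                         digits = NA, pretty = TRUE)
  } else if (config$kind == "synth") {
    design <- with_stage("synth", do.call(age_series_design, c(
      config$design, list(params = config$params, state = config$init,
                          seed = config$seed)
    )))
    series <- with_stage("synth", generate_age_series(design))
    written$series <- path("age_series.csv")
    readr::write_csv(series, written$series)
    written$provenance <- path("design.json")
    jsonlite::write_json(
      list(ages = design$ages, cv = design$cv, replicates = design$replicates,
           noise = design$noise, saturation_floor = design$saturation_floor,
           sem_floor = design$sem_floor, seed = design$seed,
           params = unclass(design$params), init = as.numeric(design$state)),
      written$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  written$log <- path("run_log.json")
  jsonlite::write_json(list(
    package = "neurodyn",
    version = as.character(utils::packageVersion("neurodyn")),
    kind = config$kind, seed = config$seed, solver = config$solver,
    params = unclass(config$params), init = as.numeric(config$init)
  ), written$log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}
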