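#' Assemble a run configuration
#'
#' Inputs may be given as in-memory objects (the usual route in scripts
#' and tests) or as file paths in the schemas documented under the
#' `read_*` helpers.  `scenario` is a built-in name (`"a"` to `"f"`), a
#' [scenario_spec()], or a path to a scenario YAML.
#'
#' @param scenario Scenario name, spec or YAML path.
#' @param year Calendar year for a single run.
#' @param years Vector of years for a projection (overrides `year`).
#' @param population A `population_table` or CSV path.
#' @param risk A `risk_profile` or CSV path.
#' @param timings A `timing_table` or CSV path.
#' @param capacities Capacities data frame, named vector or CSV path.
#' @param risk_trajectory Optional trajectory list (`start_year`,
#'   `start_rate`, `end_year`, `end_rate`, percent) applied when `risk`
#'   is a path or has no trajectory.
#' @param attendance_rate Fraction of children attending annually.
#' @param urgent_uplift Fraction of the population needing urgent care.
#' @param urgent_minutes Minutes per urgent visit.
#' @param rounding Reporting mode, `"nearest"` or `"ceil"`.
#' @param seed Optional seed for synthetic input generation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "a", year = 2023, years = NULL,
                       population = NULL, risk = NULL, timings = NULL,
                       capacities = NULL, risk_trajectory = NULL,
                       attendance_rate = 1, urgent_uplift = 0,
                       urgent_minutes = 0,
                       rounding = c("nearest", "ceil"), seed = NULL) {
  rounding <- match.arg(rounding)
  structure(list(scenario = scenario, year = year, years = years,
                 population = population, risk = risk, timings = timings,
                 capacities = capacities, risk_trajectory = risk_trajectory,
                 attendance_rate = attendance_rate,
                 urgent_uplift = urgent_uplift,
                 urgent_minutes = urgent_minutes,
                 rounding = rounding, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' A single YAML file mirroring the fields of [run_config()]; file-path
#' fields are resolved relative to the YAML's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rel <- function(p) {
    if (!is.character(p)) return(p)
    q <- file.path(dirname(path), p)
    if (file.exists(p)) p else if (file.exists(q)) q else p
  }
  run_config(scenario = rel(y$scenario %||% "a"),
             year = y$year %||% 2023,
             years = y$years,
             population = rel(y$population),
             risk = rel(y$risk),
             timings = rel(y$timings),
             capacities = rel(y$capacities),
             risk_trajectory = y$risk_trajectory,
             attendance_rate = y$attendance_rate %||% 1,
             urgent_uplift = y$urgent_uplift %||% 0,
             urgent_minutes = y$urgent_minutes %||% 0,
             rounding = y$rounding %||% "nearest",
             seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_inputs <- function(config) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  pop <- stage("population", {
    p <- config$population
    if (is.null(p)) stop("no population input supplied")
    if (is.character(p)) read_population_csv(p) else p
  })
  if (!inherits(pop, "population_table")) {
    stop("[population] not a population_table")
  }
  risk <- stage("risk", {
    r <- config$risk
    if (is.null(r)) stop("no risk input supplied")
    if (is.character(r)) read_risk_csv(r, trajectory = config$risk_trajectory)
    else r
  })
  if (!inherits(risk, "risk_profile")) stop("[risk] not a risk_profile")
  if (is.null(risk$trajectory) && !is.null(config$risk_trajectory)) {
    risk$trajectory <- config$risk_trajectory
  }
  timings <- stage("timings", {
    t <- config$timings
    if (is.null(t)) stop("no timing input supplied")
    if (is.character(t)) read_timing_csv(t) else as_timing_table(t)
  })
  caps <- stage("capacities", {
    cp <- config$capacities
    if (is.null(cp)) default_capacities()
    else if (is.character(cp)) read_capacities_csv(cp)
    else cp
  })
  scen <- stage("scenario", {
    s <- config$scenario
    if (inherits(s, "scenario_spec")) s
    else if (is.character(s) && s %in% names(builtin_scenarios())) {
      builtin_scenarios(care_plan_cells(timings))[[s]]
    } else if (is.character(s)) {
      read_scenario_yaml(s, cells = care_plan_cells(timings))
    } else stop("unrecognised scenario input")
  })
  list(population = pop, risk = risk, timings = timings,
       capacities = caps, scenario = scen)
}

#' Run the model for a single year
#'
#' Resolves the configured inputs, interpolates the population and risk
#' rate to `year`, computes per-cadre demand under the scenario, solves
#' the workforce linear programme and rounds for reporting.  Deterministic
#' for fixed inputs.
#'
#' @param config A [run_config()].
#' @param year Calendar year; defaults to `config$year`.
#' @return A list of class `single_run`: `result` (a
#'   `workforce_result`), `demand` (a `demand_vector`), `year`,
#'   `scenario`, `risk_rate_used`, `population_used`.
#' @export
run_single <- function(config, year = config$year) {
  if (!is.null(config$seed)) set.seed(config$seed)
  inp <- resolve_inputs(config)
  pop_cat <- population_at(inp$population, year)
  pop_band <- merge_to_care_bands(pop_cat)
  rate <- risk_rate_at(inp$risk, year)
  frac_cat <- risk_fractions_at(inp$risk, year)
  frac_band <- band_risk_fractions(frac_cat, pop_cat)
  demand <- demand_by_cadre(inp$scenario, pop_band, frac_band, inp$timings,
                            attendance_rate = config$attendance_rate,
                            urgent_uplift = config$urgent_uplift,
                            urgent_minutes = config$urgent_minutes)
  result <- solve_lp(demand, inp$capacities, rounding = config$rounding)
  structure(list(result = result, demand = demand, year = year,
                 scenario = inp$scenario$name,
                 risk_rate_used = rate,
                 population_used = sum(pop_band)),
            class = "single_run")
}

#' @export
print.single_run <- function(x, ...) {
  cat("year ", x$year, ", scenario ", x$scenario, ", risk rate ",
      sprintf("%.2f", x$risk_rate_used), "%, population ",
      format(round(x$population_used), big.mark = ","), "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Run the model over a range of years
#'
#' One [run_single()] per year, with the population interpolated between
#' anchors and the risk rate following the profile's trajectory.
#'
#' @param config A [run_config()].
#' @param years Years to run; defaults to `config$years`, else the
#'   2023-2050 anchor set `c(2023, 2030, 2040, 2050)` clipped to the
#'   population's anchor span.
#' @return A `projection_result` data frame with one row per
#'   (year, scenario, cadre).
#' @export
run_projection <- function(config, years = NULL) {
  years <- years %||% config$years %||% c(2023, 2030, 2040, 2050)
  rows <- list()
  for (y in years) {
    run <- run_single(config, year = y)
    res <- run$result
    for (cad in names(res$wte_continuous)) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, scenario = run$scenario, cadre = cad,
        wte_continuous = res$wte_continuous[[cad]],
        wte_reported = res$wte_reported[[cad]],
        combined_total = res$combined_total,
        risk_rate_used = run$risk_rate_used,
        population_used = run$population_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$scenario, out$cadre), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("projection_result", "data.frame")
  out
}

projection_rows <- function(x) {
  if (inherits(x, "single_run")) {
    run_rows <- data.frame(year = x$year, scenario = x$scenario,
                           cadre = names(x$result$wte_continuous),
                           wte_continuous = unname(x$result$wte_continuous),
                           wte_reported = unname(x$result$wte_reported),
                           combined_total = x$result$combined_total,
                           risk_rate_used = x$risk_rate_used,
                           population_used = x$population_used,
                           stringsAsFactors = FALSE)
    run_rows
  } else if (inherits(x, "projection_result") || is.data.frame(x)) {
    as.data.frame(x)
  } else {
    stop("cannot report an object of class ", paste(class(x), collapse = "/"))
  }
}

#' Write a workforce report
#'
#' Bit-stable for fixed inputs: rows are sorted by year, scenario and
#' cadre; continuous WTE and risk rates are written to two decimals;
#' reported WTE are integers and the combined total equals the sum of the
#' cadre rows.
#'
#' @param x A `single_run` or `projection_result`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- projection_rows(x)
  if (nrow(df) > 0) {
    df <- df[order(df$year, df$scenario, df$cadre), , drop = FALSE]
    df$wte_continuous <- round(df$wte_continuous, 2)
    df$risk_rate_used <- round(df$risk_rate_used, 2)
  }
  rownames(df) <- NULL
  if (format == "csv") {
    out <- df
    if (nrow(out) > 0) {
      out$wte_continuous <- sprintf("%.2f", out$wte_continuous)
      out$risk_rate_used <- sprintf("%.2f", out$risk_rate_used)
      out$population_used <- sprintf("%.1f", out$population_used)
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
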