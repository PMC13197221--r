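#' Read a population CSV
#'
#' Expected columns: `year`, `age_category` (e.g. `"0-4"`), `count`;
#' rows with category `"0-17"` (the `total_label`) are totals.  When the
#' listed categories are a strict subset of the total range the residual
#' band is derived automatically (e.g. 15-17 from a 0-17 total).
#'
#' @param path CSV file path.
#' @param total_label Label of total rows.
#' @param derive_residual Derive the missing band from the total row.
#' @return A `population_table`.
#' @export
read_population_csv <- function(path, total_label = "0-17",
                                derive_residual = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  pt <- load_population_table(tab, total_label = total_label)
  if (derive_residual) pt <- derive_residual_category(pt)
  pt
}

#' Read a caries-risk CSV
#'
#' Expected columns: `age_category`, `high_risk_fraction`.  The trajectory
#' (start/end year and rate, in percent) comes from the run configuration,
#' not the file.
#'
#' @param path CSV file path.
#' @param trajectory Optional trajectory list passed to [risk_profile()].
#' @param weights Optional population weights for the overall rate.
#' @param overall_rate Optional headline rate in percent.
#' @return A `risk_profile`.
#' @export
read_risk_csv <- function(path, trajectory = NULL, weights = NULL,
                          overall_rate = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_category", "high_risk_fraction")
  if (!all(need %in% names(tab))) {
    stop("risk CSV needs columns: ", paste(need, collapse = ", "))
  }
  risk_profile(stats::setNames(tab$high_risk_fraction, tab$age_category),
               overall_rate = overall_rate, trajectory = trajectory,
               weights = weights)
}

#' Read a per-child annual timing CSV
#'
#' Expected columns: `component`, `age_category`, `risk`, `cadre`,
#' `minutes_per_year` (already amortised; empty cells are treated as
#' missing).
#'
#' @param path CSV file path.
#' @return A `timing_table`.
#' @export
read_timing_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_timing_table(tab)
}

#' Read a cadre-capacity CSV
#'
#' Expected columns: `cadre`, `nhs_hours_per_week`, `leave_weeks`;
#' `annual_minutes` is recomputed.
#'
#' @param path CSV file path.
#' @return Capacities data frame as [default_capacities()].
#' @export
read_capacities_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cadre", "nhs_hours_per_week", "leave_weeks")
  if (!all(need %in% names(tab))) {
    stop("capacities CSV needs columns: ", paste(need, collapse = ", "))
  }
  tab$annual_minutes <- annual_available_minutes(tab$nhs_hours_per_week,
                                                 tab$leave_weeks)
  tab[, c(need, "annual_minutes")]
}

#' Read a scenario YAML file
#'
#' Layout: `name`, optional `label`, `rules` (map component -> cadre, or
#' component -> map cadre -> share), optional `population_split`
#' (`stratum`, `fraction`, `cadre`), optional `charge_confirmatory`.
#'
#' @param path YAML file path.
#' @param cells Care-plan cell grid over which rules are expanded.
#' @return A `scenario_spec`.
#' @export
read_scenario_yaml <- function(path, cells = care_plan_cells()) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$rules)) {
    stop("scenario YAML needs fields name and rules")
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    comp <- cells$component[i]
    rule <- y$rules[[comp]]
    if (is.null(rule)) stop("no rule for component ", comp)
    shares <- if (is.character(rule)) stats::setNames(1, rule)
              else unlist(rule)
    for (cad in names(shares)) {
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, age_category = cells$age_category[i],
        risk = cells$risk[i], cadre = cad,
        share = as.numeric(shares[[cad]]), stringsAsFactors = FALSE)
    }
  }
  scenario_spec(y$name, do.call(rbind, rows),
                population_split = y$population_split,
                charge_confirmatory = isTRUE(y$charge_confirmatory),
                label = y$label)
}
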