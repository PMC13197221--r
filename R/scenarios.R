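ALL_COMPONENTS <- c("exam", "confirmatory_exam", "radiographs",
                    "fluoride_varnish", "fissure_sealants", "oh_advice",
                    "diet_advice", "vba", "restorative")

EDDN_SCOPE <- c("fluoride_varnish", "oh_advice", "diet_advice", "vba",
                "confirmatory_exam")

#' Is a cadre permitted to deliver a care component?
#'
#' Dentists and DH/DThs may deliver every component.  EDDNs are restricted
#' to fluoride varnish, oral-health and dietary advice, very brief advice
#' and the confirmatory examination: no diagnosis/treatment planning, no
#' fissure sealants, no radiograph prescription and no restorations.
#'
#' @param cadre One of [cadres()].
#' @param component A component identifier.
#' @return Logical.
#' @export
scope_of_practice <- function(cadre, component) {
  if (!cadre %in% cadres()) stop("unknown cadre: ", cadre)
  if (!component %in% ALL_COMPONENTS) stop("unknown component: ", component)
  if (cadre == "eddn") return(component %in% EDDN_SCOPE)
  # the examination proper belongs to the examining clinician; the
  # confirmatory variant exists only for EDDN-delivered care
  if (component == "confirmatory_exam") return(cadre == "eddn")
  TRUE
}

#' Construct a delegation scenario
#'
#' @param name Scenario name.
#' @param shares Data frame with columns `component`, `age_category`,
#'   `risk`, `cadre`, `share`; for every in-scope cell the cadre shares
#'   must sum to 1.
#' @param population_split Optional list `list(stratum = "high",
#'   fraction = 0.1, cadre = "dentist")`: that fraction of the stratum's
#'   children receive their whole care plan from the named cadre, the
#'   remainder being delegated according to `shares`.
#' @param charge_confirmatory If `TRUE`, every child in a stratum where an
#'   EDDN delivers any shared care is additionally charged the EDDN
#'   confirmatory examination.  Off by default: in the built-in scenarios
#'   a dentist or DH/DTh of record performs the examination.
#' @param label Optional human-readable description.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, shares, population_split = NULL,
                          charge_confirmatory = FALSE, label = NULL) {
  need <- c("component", "age_category", "risk", "cadre", "share")
  if (!is.data.frame(shares) || !all(need %in% names(shares))) {
    stop("shares needs columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(population_split)) {
    ps <- population_split
    if (is.null(ps$stratum) || !ps$stratum %in% c("high", "low") ||
        is.null(ps$fraction) || ps$fraction < 0 || ps$fraction > 1 ||
        is.null(ps$cadre) || !ps$cadre %in% cadres()) {
      stop("population_split needs stratum (high/low), fraction in [0, 1] ",
           "and a valid cadre")
    }
  }
  structure(list(name = name, shares = shares[, need],
                 population_split = population_split,
                 charge_confirmatory = isTRUE(charge_confirmatory),
                 label = label),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name,
      if (!is.null(x$label)) paste0(" - ", x$label), "\n", sep = "")
  if (!is.null(x$population_split)) {
    ps <- x$population_split
    cat("  population split: ", ps$fraction * 100, "% of ", ps$stratum,
        "-risk children wholly to ", ps$cadre, "\n", sep = "")
  }
  invisible(x)
}

# expand a component -> cadre rule over the care-plan cell grid
shares_from_rules <- function(rules, cells) {
  cadre <- unname(rules[cells$component])
  if (any(is.na(cadre))) {
    stop("no delegation rule for component(s): ",
         paste(unique(cells$component[is.na(cadre)]), collapse = ", "))
  }
  data.frame(cells, cadre = cadre, share = 1, stringsAsFactors = FALSE)
}

#' The six built-in skill-mix scenarios
#'
#' * **a** No skill mix: dentists provide all preventive care.
#' * **b** No skill mix: DH/DThs provide all preventive care.
#' * **c** Moderate skill mix: DH/DThs provide the examination, fissure
#'   sealants, restorative treatment (and radiographs, which lie outside
#'   EDDN scope); everything else goes to EDDNs.
#' * **d** Intermediate skill mix: dentists examine and treatment-plan,
#'   EDDNs apply fluoride varnish, DH/DThs deliver everything else.
#' * **e** Combination skill mix: dentists provide the whole care plan for
#'   10% of high-risk children; the remainder are delegated as in (c).
#' * **f** Maximum skill mix: dentists perform the oral health assessment,
#'   DH/DThs the sealants, restorations and radiographs, EDDNs everything
#'   else within their scope.
#'
#' @param cells Care-plan cell grid; default [care_plan_cells()].
#' @return Named list of six [scenario_spec()] objects.
#' @export
builtin_scenarios <- function(cells = care_plan_cells()) {
  comps <- setdiff(unique(cells$component), "confirmatory_exam")
  all_to <- function(cadre) stats::setNames(rep(cadre, length(comps)), comps)
  rules_c <- all_to("eddn")
  rules_c[c("exam", "fissure_sealants", "restorative", "radiographs")] <-
    "dh_dth"
  rules_d <- all_to("dh_dth")
  rules_d["exam"] <- "dentist"
  rules_d["fluoride_varnish"] <- "eddn"
  rules_f <- rules_c
  rules_f["exam"] <- "dentist"
  list(
    a = scenario_spec("a", shares_from_rules(all_to("dentist"), cells),
                      label = "no skill mix: dentists only"),
    b = scenario_spec("b", shares_from_rules(all_to("dh_dth"), cells),
                      label = "no skill mix: DH/DThs only"),
    c = scenario_spec("c", shares_from_rules(rules_c, cells),
                      label = "moderate skill mix: DH/DThs + EDDNs"),
    d = scenario_spec("d", shares_from_rules(rules_d, cells),
                      label = "intermediate skill mix: all three cadres"),
    e = scenario_spec("e", shares_from_rules(rules_c, cells),
                      population_split = list(stratum = "high",
                                              fraction = 0.10,
                                              cadre = "dentist"),
                      label = "combination: 10% of high risk to dentists"),
    f = scenario_spec("f", shares_from_rules(rules_f, cells),
                      label = "maximum skill mix")
  )
}

#' Validate a scenario against the care-plan cell grid
#'
#' @param spec A `scenario_spec`.
#' @param cells Cell grid the scenario must cover; default
#'   [care_plan_cells()].
#' @return Character vector of violations; empty when the scenario is
#'   valid.  Violations are returned, not raised.
#' @export
validate_scenario <- function(spec, cells = care_plan_cells()) {
  stopifnot(inherits(spec, "scenario_spec"))
  sh <- spec$shares
  out <- character(0)
  if (any(sh$share < 0 | sh$share > 1)) {
    out <- c(out, "shares outside [0, 1]")
  }
  ok <- mapply(function(cad, comp) {
    cad %in% cadres() && comp %in% ALL_COMPONENTS &&
      scope_of_practice(cad, comp)
  }, sh$cadre, sh$component)
  if (!all(ok)) {
    bad <- unique(paste0(sh$component[!ok], " -> ", sh$cadre[!ok]))
    out <- c(out, paste0("scope violation: ", bad))
  }
  key <- function(d) paste(d$component, d$age_category, d$risk, sep = "|")
  sums <- tapply(sh$share, key(sh), sum)
  ck <- key(cells)
  missing <- setdiff(ck, names(sums))
  if (length(missing) > 0) {
    out <- c(out, paste0("cell not covered: ", missing))
  }
  covered <- intersect(ck, names(sums))
  bad_sum <- covered[abs(sums[covered] - 1) > 1e-9]
  if (length(bad_sum) > 0) {
    out <- c(out, paste0("shares do not sum to 1 for cell: ", bad_sum))
  }
  out
}

#' Annual demand minutes assigned to each cadre
#'
#' For each care-plan cell, the children of the stratum (band population
#' times high- or low-risk fraction, scaled by the attendance rate) are
#' multiplied by the scenario share and by the delivering cadre's per-year
#' minutes for that component.  A `population_split` carve-out routes the
#' full care plan of the split fraction to its designated cadre before the
#' shares apply.  An optional urgent-care uplift adds
#' `urgent_uplift x total population x urgent_minutes` to `urgent_cadre`.
#'
#' @param spec A validated `scenario_spec`.
#' @param population Named numeric vector of children by care band.
#' @param risk_fractions Named numeric vector of high-risk fractions by
#'   band.
#' @param timing_table A `timing_table` covering all cells with nonzero
#'   share.
#' @param attendance_rate Fraction of children attending; default 1.
#' @param urgent_uplift Fraction of the population requiring urgent care
#'   per year (e.g. 0.03); default 0 (off).
#' @param urgent_minutes Minutes per urgent visit; required when
#'   `urgent_uplift > 0`.
#' @param urgent_cadre Cadre absorbing urgent care; default `"dentist"`.
#' @return An object of class `demand_vector`: list with `minutes` (named
#'   totals by cadre) and `breakdown` (data frame by cadre, component,
#'   band, risk).
#' @export
demand_by_cadre <- function(spec, population, risk_fractions, timing_table,
                            attendance_rate = 1, urgent_uplift = 0,
                            urgent_minutes = 0, urgent_cadre = "dentist") {
  stopifnot(inherits(spec, "scenario_spec"))
  if (attendance_rate < 0 || attendance_rate > 1) {
    stop("attendance_rate must lie in [0, 1]")
  }
  if (urgent_uplift > 0 && urgent_minutes <= 0) {
    stop("urgent_uplift requires a positive urgent_minutes duration")
  }
  bands <- names(population)
  if (is.null(bands) || !setequal(bands, names(risk_fractions))) {
    stop("population and risk_fractions must be named by the same bands")
  }
  cells <- care_plan_cells(timing_table)
  viol <- validate_scenario(spec, cells)
  if (length(viol) > 0) {
    stop("invalid scenario ", spec$name, ": ",
         paste(viol, collapse = "; "))
  }

  tmins <- function(comp, band, risk, cad) {
    sel <- timing_table$component == comp &
      timing_table$age_category == band & timing_table$risk == risk &
      timing_table$cadre == cad
    v <- timing_table$minutes_per_year[sel]
    if (length(v) == 0 || any(is.na(v))) {
      stop("timing table does not cover component ", comp, " for (", band,
           ", ", risk, ", ", cad, ")")
    }
    sum(v)
  }

  ps <- spec$population_split
  rows <- list()
  add <- function(cad, comp, band, risk, mins) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cadre = cad, component = comp, age_category = band, risk = risk,
      minutes = mins, stringsAsFactors = FALSE)
  }

  for (band in bands) {
    if (population[[band]] == 0) next
    for (risk in c("high", "low")) {
      frac <- if (risk == "high") risk_fractions[[band]]
              else 1 - risk_fractions[[band]]
      attending <- population[[band]] * frac * attendance_rate
      if (attending == 0) next
      carve <- if (!is.null(ps) && ps$stratum == risk) ps$fraction else 0
      stratum_cells <- cells[cells$age_category == band & cells$risk == risk,
                             , drop = FALSE]
      # carved fraction: the full plan from the designated cadre
      if (carve > 0) {
        for (i in seq_len(nrow(stratum_cells))) {
          comp <- stratum_cells$component[i]
          add(ps$cadre, comp, band, risk,
              attending * carve * tmins(comp, band, risk, ps$cadre))
        }
      }
      # remainder: delegated according to the scenario shares
      rem <- attending * (1 - carve)
      sh <- spec$shares[spec$shares$age_category == band &
                          spec$shares$risk == risk &
                          spec$shares$share > 0, , drop = FALSE]
      for (i in seq_len(nrow(sh))) {
        add(sh$cadre[i], sh$component[i], band, risk,
            rem * sh$share[i] *
              tmins(sh$component[i], band, risk, sh$cadre[i]))
      }
      if (spec$charge_confirmatory && any(sh$cadre == "eddn")) {
        add("eddn", "confirmatory_exam", band, risk,
            rem * tmins("confirmatory_exam", band, risk, "eddn"))
      }
    }
  }
  if (urgent_uplift > 0) {
    add(urgent_cadre, "urgent_care", "0-17", "all",
        urgent_uplift * sum(population) * urgent_minutes)
  }
  breakdown <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cadre = character(0), component = character(0),
               age_category = character(0), risk = character(0),
               minutes = numeric(0))
  minutes <- vapply(cadres(), function(cad) {
    sum(breakdown$minutes[breakdown$cadre == cad])
  }, numeric(1))
  structure(list(minutes = minutes, breakdown = breakdown),
            class = "demand_vector")
}

#' @export
print.demand_vector <- function(x, ...) {
  cat("<demand_vector> annual minutes by cadre:\n")
  print(round(x$minutes, 1))
  invisible(x)
}
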