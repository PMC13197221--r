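#' Amortised chair time per year
#'
#' Fissure sealants are applied once per tooth per child, so the total
#' chair time for the sealants of an age band is spread evenly across the
#' years of the band: e.g. four sealants at 9.3 minutes over the five
#' years of the 5-9 band give 4 x 9.3 / 5 = 7.44 minutes per year.
#'
#' @param units_total Number of applications over the band (>= 0).
#' @param minutes_per_unit Minutes per application (>= 0).
#' @param span_years Years in the band (>= 1).
#' @return Minutes per year.
#' @export
amortised_minutes_per_year <- function(units_total, minutes_per_unit,
                                       span_years) {
  if (any(span_years < 1)) stop("span_years must be at least 1")
  if (any(units_total < 0) || any(minutes_per_unit < 0)) {
    stop("units_total and minutes_per_unit must be nonnegative")
  }
  units_total * minutes_per_unit / span_years
}

#' Fluoride-varnish schedule for an age band and risk level
#'
#' High-risk 5-17-year-olds receive three applications a year and low-risk
#' two.  In the 0-4 band, 0-year-olds have no dentition so high-risk
#' varnish covers ages 1-4 only, and low-risk varnish is restricted to
#' 3-4-year-olds; under a uniform single-year age distribution the eligible
#' fraction of the band is 4/5 (high) and 2/5 (low).
#'
#' @param category Age-band label (e.g. `"0-4"`).
#' @param risk `"high"` or `"low"`.
#' @return List with `applications` (per year) and `eligible_fraction`.
#' @export
varnish_schedule <- function(category, risk = c("high", "low")) {
  risk <- match.arg(risk)
  rng <- parse_age_label(category)
  apps <- if (risk == "high") 3 else 2
  ages <- seq(rng$min_age, rng$max_age)
  eligible <- if (risk == "high") ages >= 1 else ages >= 3
  # bands at 5+ are fully eligible at either risk level
  if (rng$min_age >= 5) eligible[] <- TRUE
  list(applications = apps, eligible_fraction = mean(eligible))
}

#' Define a care-plan component
#'
#' @param id Component identifier (e.g. `"exam"`, `"fluoride_varnish"`).
#' @param bands Age bands eligible for the component.
#' @param risks Risk levels eligible (`"high"`, `"low"` or both).
#' @param frequency Applications per year (ignored for schedule- or
#'   amortisation-driven components).
#' @param unit_minutes Named numeric vector of minutes per application by
#'   cadre (`dentist`, `dh_dth`, `eddn`).  `NA` marks a value not yet
#'   supplied; such entries survive into the timing table as missing.
#' @param amortisation Optional list `list(units = c("5-9" = 4, ...))`
#'   giving applications per band, spread across the band's years.
#' @param schedule `TRUE` for fluoride varnish: frequency and eligible
#'   fraction come from [varnish_schedule()].
#' @return An object of class `care_component`.
#' @export
care_component <- function(id, bands, risks = c("high", "low"),
                           frequency = 1, unit_minutes,
                           amortisation = NULL, schedule = FALSE) {
  stopifnot(is.character(id), length(id) == 1)
  if (!all(risks %in% c("high", "low"))) stop("risks must be high/low")
  if (is.null(names(unit_minutes)) ||
      !all(names(unit_minutes) %in% cadres())) {
    stop("unit_minutes must be named by cadre")
  }
  if (any(unit_minutes < 0, na.rm = TRUE)) {
    stop("unit_minutes must be nonnegative")
  }
  if (frequency < 0) stop("frequency must be nonnegative")
  if (!is.null(amortisation)) {
    if (is.null(amortisation$units) || is.null(names(amortisation$units))) {
      stop("amortisation$units must be named by band")
    }
  }
  structure(list(id = id, bands = bands, risks = risks,
                 frequency = frequency, unit_minutes = unit_minutes,
                 amortisation = amortisation, schedule = isTRUE(schedule)),
            class = "care_component")
}

#' The evidence-based preventive care-plan components
#'
#' Returns the component set used throughout: an annual clinical
#' examination/treatment plan, radiographs (5-17 only), fluoride varnish
#' on the age/risk schedule, fissure sealants amortised over the band
#' (high risk only: 4 applications for 5-9, 12 for 10-17, 9.3 minutes
#' each), oral-health and dietary advice, very brief advice on tobacco and
#' vaping for 10-17-year-olds (0.3 minutes), restorative treatment for
#' high-risk children (30 minutes a year, any age), and the two-minute
#' confirmatory examination an EDDN performs when delivering care under
#' prescription.
#'
#' Durations marked `NA` are sourced from a per-team timing table rather
#' than fixed here; supply them through `unit_minutes` (or load a complete
#' timing table from file) before computing demand.
#'
#' @param unit_minutes Named list of cadre-named numeric vectors overriding
#'   or completing component durations, e.g.
#'   `list(exam = c(dentist = 10, dh_dth = 10))`.
#' @return Named list of [care_component()] objects.
#' @export
dboh_components <- function(unit_minutes = list()) {
  um <- function(id, default) {
    o <- unit_minutes[[id]]
    if (is.null(o)) return(default)
    default[names(o)] <- o
    default
  }
  comps <- list(
    exam = care_component("exam", care_bands(),
      unit_minutes = um("exam", c(dentist = NA_real_, dh_dth = NA_real_))),
    confirmatory_exam = care_component("confirmatory_exam", care_bands(),
      unit_minutes = um("confirmatory_exam", c(eddn = 2))),
    radiographs = care_component("radiographs", c("5-9", "10-17"),
      unit_minutes = um("radiographs",
                        c(dentist = NA_real_, dh_dth = NA_real_))),
    fluoride_varnish = care_component("fluoride_varnish", care_bands(),
      schedule = TRUE,
      unit_minutes = um("fluoride_varnish",
                        c(dentist = NA_real_, dh_dth = NA_real_))),
    fissure_sealants = care_component("fissure_sealants", c("5-9", "10-17"),
      risks = "high",
      amortisation = list(units = c("5-9" = 4, "10-17" = 12)),
      unit_minutes = um("fissure_sealants", c(dentist = 9.3, dh_dth = 9.3))),
    oh_advice = care_component("oh_advice", care_bands(),
      unit_minutes = um("oh_advice",
                        c(dentist = NA_real_, dh_dth = NA_real_))),
    diet_advice = care_component("diet_advice", care_bands(),
      unit_minutes = um("diet_advice",
                        c(dentist = NA_real_, dh_dth = NA_real_))),
    vba = care_component("vba", "10-17",
      unit_minutes = um("vba", c(dentist = 0.3, dh_dth = 0.3))),
    restorative = care_component("restorative", care_bands(), risks = "high",
      unit_minutes = um("restorative", c(dentist = 30, dh_dth = 30)))
  )
  comps
}

#' Build a per-child annual timing table from component definitions
#'
#' Expands each component over its eligible (band, risk) cells and the
#' cadres permitted to deliver it, computing minutes per child per year:
#' `frequency x eligible_fraction x unit_minutes`, or the amortised value
#' for sealants.  EDDN timings equal DH/DTh timings componentwise, except
#' that the EDDN examination is the two-minute confirmatory examination
#' (a separate component); EDDN entries are only created for components
#' within EDDN scope of practice.
#'
#' @param components Named list of [care_component()] objects.
#' @return A `timing_table` data frame with columns `component`,
#'   `age_category`, `risk`, `cadre`, `minutes_per_year` (possibly `NA`
#'   where a duration was not supplied).
#' @export
build_timing_table <- function(components = dboh_components()) {
  rows <- list()
  for (comp in components) {
    for (cad in cadres()) {
      if (!scope_of_practice(cad, comp$id)) {
        if (cad %in% names(comp$unit_minutes) &&
            !is.na(comp$unit_minutes[[cad]])) {
          stop("component ", comp$id, " assigned a duration for cadre ",
               cad, ", which is outside its scope of practice")
        }
        next
      }
      unit <- if (cad %in% names(comp$unit_minutes)) {
        comp$unit_minutes[[cad]]
      } else if (cad == "eddn" && "dh_dth" %in% names(comp$unit_minutes)) {
        comp$unit_minutes[["dh_dth"]]  # EDDN timings mirror DH/DTh
      } else {
        next
      }
      for (band in comp$bands) {
        for (risk in comp$risks) {
          mins <- if (!is.null(comp$amortisation)) {
            units <- comp$amortisation$units[[band]]
            if (is.null(units)) next
            amortised_minutes_per_year(units, unit,
                                       parse_age_label(band)$span)
          } else if (comp$schedule) {
            sch <- varnish_schedule(band, risk)
            sch$applications * sch$eligible_fraction * unit
          } else {
            comp$frequency * unit
          }
          rows[[length(rows) + 1L]] <- data.frame(
            component = comp$id, age_category = band, risk = risk,
            cadre = cad, minutes_per_year = mins, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  as_timing_table(tab)
}

#' Coerce and validate a timing table
#'
#' @param tab Data frame with columns `component`, `age_category`, `risk`,
#'   `cadre`, `minutes_per_year`.
#' @return A validated `timing_table`.
#' @export
as_timing_table <- function(tab) {
  need <- c("component", "age_category", "risk", "cadre", "minutes_per_year")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop("timing table needs columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  if (any(tab$minutes_per_year < 0, na.rm = TRUE)) {
    stop("timing entries must be nonnegative")
  }
  if (!all(tab$risk %in% c("high", "low"))) stop("risk must be high/low")
  if (!all(tab$cadre %in% cadres())) {
    stop("unknown cadre(s): ",
         paste(setdiff(unique(tab$cadre), cadres()), collapse = ", "))
  }
  ok <- mapply(scope_of_practice, tab$cadre, tab$component)
  if (!all(ok)) {
    bad <- unique(paste(tab$cadre[!ok], tab$component[!ok], sep = ":"))
    stop("timing entries outside scope of practice: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tab[, c("component", "age_category", "risk", "cadre")])) {
    stop("duplicate timing-table cells")
  }
  rownames(tab) <- NULL
  class(tab) <- c("timing_table", "data.frame")
  tab
}

#' Total annual care minutes for one (band, risk, cadre) cell
#'
#' @param table A `timing_table`.
#' @param category Age-band label.
#' @param risk `"high"` or `"low"`.
#' @param cadre Cadre identifier.
#' @return Minutes per child per year (0 for an empty table).
#' @export
annual_care_minutes <- function(table, category, risk, cadre) {
  if (is.null(table) || nrow(table) == 0) return(0)
  sel <- table$age_category == category & table$risk == risk &
    table$cadre == cadre
  sub <- table[sel, , drop = FALSE]
  if (any(is.na(sub$minutes_per_year))) {
    stop("timing table does not cover (", category, ", ", risk, ", ", cadre,
         "): missing minutes for component(s) ",
         paste(sub$component[is.na(sub$minutes_per_year)], collapse = ", "))
  }
  sum(sub$minutes_per_year)
}

#' The (component, band, risk) cells of a care plan
#'
#' The confirmatory examination is excluded: it is charged through the
#' `charge_confirmatory` toggle of [demand_by_cadre()], not via scenario
#' shares.
#'
#' @param table A `timing_table`.
#' @return Data frame of unique `component`, `age_category`, `risk` cells.
#' @export
care_plan_cells <- function(table = build_timing_table()) {
  cells <- unique(table[table$component != "confirmatory_exam",
                        c("component", "age_category", "risk")])
  rownames(cells) <- NULL
  cells
}
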