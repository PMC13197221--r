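#' Annual NHS clinical minutes available per whole-time equivalent
#'
#' A working year is 52 weeks minus annual leave; bank holidays and
#' sickness are not modelled.
#'
#' @param hours_per_week NHS clinical hours per week (>= 0).
#' @param leave_weeks Weeks of annual leave (0-52).
#' @return Minutes per year: `hours_per_week * 60 * (52 - leave_weeks)`.
#' @export
annual_available_minutes <- function(hours_per_week, leave_weeks) {
  if (any(hours_per_week < 0)) stop("hours_per_week must be nonnegative")
  if (any(leave_weeks < 0 | leave_weeks > 52)) {
    stop("leave_weeks must lie in [0, 52]")
  }
  hours_per_week * 60 * (52 - leave_weeks)
}

#' Default cadre working patterns
#'
#' Dentists dedicate on average 26.7 NHS clinical hours a week with 4.4
#' weeks of annual leave; dental nurses (hence EDDNs) work comparable
#' hours.  DH/DThs work about `dh_weekly_hours` hours a week of which
#' `dh_nhs_share` is NHS care (defaults collapse to 11.8 NHS hours a
#' week), also with 4.4 weeks of leave.  All cadres are assumed to dedicate
#' 100% of NHS clinical time to children.
#'
#' @param dh_weekly_hours Total weekly clinical hours for DH/DThs.
#' @param dh_nhs_share Fraction of DH/DTh clinical time under NHS contract.
#' @param leave_weeks Annual leave in weeks, applied to every cadre.
#' @return Data frame with columns `cadre`, `nhs_hours_per_week`,
#'   `leave_weeks`, `annual_minutes`.
#' @export
default_capacities <- function(dh_weekly_hours = 25, dh_nhs_share = 0.472,
                               leave_weeks = 4.4) {
  hours <- c(dentist = 26.7, dh_dth = dh_weekly_hours * dh_nhs_share,
             eddn = 26.7)
  data.frame(cadre = names(hours),
             nhs_hours_per_week = unname(hours),
             leave_weeks = leave_weeks,
             annual_minutes = annual_available_minutes(unname(hours),
                                                       leave_weeks),
             stringsAsFactors = FALSE)
}

# accept either a capacities data frame or a named vector of annual minutes
capacity_minutes <- function(capacities) {
  if (is.data.frame(capacities)) {
    if (!all(c("cadre", "annual_minutes") %in% names(capacities))) {
      stop("capacities data frame needs columns cadre and annual_minutes")
    }
    stats::setNames(capacities$annual_minutes, capacities$cadre)
  } else if (is.numeric(capacities) && !is.null(names(capacities))) {
    capacities
  } else {
    stop("capacities must be a data frame or a named numeric vector")
  }
}
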