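#' Population-weighted average high-caries-risk rate
#'
#' @param fractions Named numeric vector of high-risk fractions in `[0, 1]`
#'   by age category.
#' @param weights Named numeric vector of population counts by the same
#'   categories; nonnegative, not all zero.
#' @return The weighted mean fraction expressed as a percentage.
#' @export
average_risk_rate <- function(fractions, weights) {
  if (!is.null(names(fractions)) && !is.null(names(weights))) {
    if (!setequal(names(fractions), names(weights))) {
      stop("fractions and weights cover different age categories")
    }
    weights <- weights[names(fractions)]
  }
  if (length(fractions) != length(weights)) {
    stop("fractions and weights must have the same length")
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("risk fractions must lie in [0, 1]")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  100 * sum(fractions * weights) / sum(weights)
}

#' Construct a caries-risk profile
#'
#' Holds per-age-category high-risk fractions, the headline overall risk
#' rate (percent) and an optional linear trajectory of that rate over
#' calendar time (e.g. 31.02% in 2023 declining to 16.56% by 2050).
#'
#' @param fractions Named numeric vector of high-risk fractions in `[0, 1]`
#'   by age-category label.
#' @param overall_rate Overall risk rate in percent.  If `NULL` and
#'   `weights` are supplied it is computed with [average_risk_rate()];
#'   otherwise it defaults to the unweighted mean of `fractions`.
#' @param trajectory Optional list with `start_year`, `start_rate`,
#'   `end_year`, `end_rate` (rates in percent); linear in calendar year.
#' @param weights Optional population weights used to compute
#'   `overall_rate`.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(fractions, overall_rate = NULL, trajectory = NULL,
                         weights = NULL) {
  if (is.null(names(fractions))) stop("fractions must be named by category")
  if (any(fractions < 0 | fractions > 1)) {
    stop("risk fractions must lie in [0, 1]")
  }
  if (is.null(overall_rate)) {
    overall_rate <- if (is.null(weights)) 100 * mean(fractions)
                    else average_risk_rate(fractions, weights)
  }
  if (overall_rate < 0 || overall_rate > 100) {
    stop("overall_rate must lie in [0, 100]")
  }
  if (!is.null(trajectory)) {
    need <- c("start_year", "start_rate", "end_year", "end_rate")
    if (!all(need %in% names(trajectory))) {
      stop("trajectory needs fields: ", paste(need, collapse = ", "))
    }
    if (trajectory$start_year >= trajectory$end_year) {
      stop("trajectory start_year must precede end_year")
    }
  }
  structure(list(fractions = fractions, overall_rate = overall_rate,
                 trajectory = trajectory),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile> overall rate ", sprintf("%.2f", x$overall_rate), "%, ",
      length(x$fractions), " age categories", sep = "")
  if (!is.null(x$trajectory)) {
    cat("; trajectory ", x$trajectory$start_rate, "% (",
        x$trajectory$start_year, ") -> ", x$trajectory$end_rate, "% (",
        x$trajectory$end_year, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Overall risk rate at a calendar year
#'
#' Linear interpolation between the trajectory endpoints.  Without a
#' trajectory the profile's overall rate is returned for any year.
#'
#' @param profile A `risk_profile`.
#' @param year Calendar year within the trajectory span.
#' @return Risk rate in percent.
#' @export
risk_rate_at <- function(profile, year) {
  stopifnot(inherits(profile, "risk_profile"), length(year) == 1)
  tr <- profile$trajectory
  if (is.null(tr)) return(profile$overall_rate)
  if (year < tr$start_year || year > tr$end_year) {
    stop("year ", year, " outside the risk trajectory span [",
         tr$start_year, ", ", tr$end_year, "]")
  }
  w <- (year - tr$start_year) / (tr$end_year - tr$start_year)
  (1 - w) * tr$start_rate + w * tr$end_rate
}

#' Per-category risk fractions at a calendar year
#'
#' Under a changing overall rate, category-level fractions are scaled
#' proportionally (every category multiplied by the ratio of the year's
#' rate to the profile's baseline rate) and clipped to `[0, 1]`.
#'
#' @param profile A `risk_profile`.
#' @param year Calendar year.
#' @return Named numeric vector of fractions by category.
#' @export
risk_fractions_at <- function(profile, year) {
  rate <- risk_rate_at(profile, year)
  if (profile$overall_rate == 0) return(profile$fractions * 0)
  pmin(pmax(profile$fractions * rate / profile$overall_rate, 0), 1)
}

#' Aggregate category risk fractions onto care-plan age bands
#'
#' @param fractions Named fractions by population age category.
#' @param population Named population counts by the same categories.
#' @param bands Band labels; default [care_bands()].
#' @return Named numeric vector of high-risk fractions by band.
#' @export
band_risk_fractions <- function(fractions, population, bands = care_bands()) {
  if (!setequal(names(fractions), names(population))) {
    stop("fractions and population cover different age categories")
  }
  population <- population[names(fractions)]
  grp <- band_for_category(names(fractions), bands)
  out <- vapply(bands, function(b) {
    w <- population[grp == b]
    f <- fractions[grp == b]
    if (length(f) == 0) 0
    else if (sum(w) == 0) mean(f)
    else sum(f * w) / sum(w)
  }, numeric(1))
  names(out) <- bands
  out
}
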