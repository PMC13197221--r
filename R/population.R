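#' Build a validated population table
#'
#' Takes long-format records of child population counts by calendar year and
#' age category and returns a `population_table`.  A record whose category
#' label equals `total_label` is treated as the all-children total for that
#' year (anchor years of a projection are usually supplied as totals only).
#'
#' Validation: counts must be nonnegative; categories within a year must be
#' disjoint; when the listed categories cover the whole of `total_label`'s
#' age range, their sum must agree with any provided total to within one
#' person.  Categories may be a strict subset of the total range (e.g. 0-4,
#' 5-9, 10-14 against a 0-17 total); the missing band is recovered with
#' [derive_residual_category()].
#'
#' @param records Data frame with columns `year`, `age_category`, `count`.
#' @param total_label Label of total rows; default `"0-17"`.
#' @return An object of class `population_table`.
#' @export
load_population_table <- function(records, total_label = "0-17") {
  stopifnot(is.data.frame(records))
  need <- c("year", "age_category", "count")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  records$year <- as.numeric(records$year)
  records$count <- as.numeric(records$count)
  records$age_category <- as.character(records$age_category)
  if (any(!is.finite(records$count)) || any(records$count < 0)) {
    stop("population counts must be finite and nonnegative")
  }
  total_range <- parse_age_label(total_label)

  is_total <- records$age_category == total_label
  cat_rows <- records[!is_total, , drop = FALSE]
  tot_rows <- records[is_total, , drop = FALSE]

  totals <- data.frame(year = numeric(0), total = numeric(0))
  for (y in sort(unique(records$year))) {
    cy <- cat_rows[cat_rows$year == y, , drop = FALSE]
    ty <- tot_rows[tot_rows$year == y, , drop = FALSE]
    if (nrow(ty) > 1) stop("multiple total rows for year ", y)
    if (nrow(cy) > 0) {
      cats <- age_categories(cy$age_category)  # disjointness check
      if (any(cats$min_age < total_range$min_age) ||
          any(cats$max_age > total_range$max_age)) {
        stop("age categories in year ", y, " exceed the range of ", total_label)
      }
      covers <- sum(cats$span) == total_range$span
      s <- sum(cy$count)
      if (nrow(ty) == 1) {
        if (covers && abs(s - ty$count) > 1) {
          stop("year ", y, ": category counts sum to ", s,
               " but the total row gives ", ty$count)
        }
        if (!covers && s > ty$count + 1) {
          stop("year ", y, ": partial category counts (", s,
               ") exceed the total row (", ty$count, ")")
        }
        totals <- rbind(totals, data.frame(year = y, total = ty$count))
      } else {
        if (!covers) {
          stop("year ", y, ": categories do not cover ", total_label,
               " and no total row is given")
        }
        totals <- rbind(totals, data.frame(year = y, total = s))
      }
    } else if (nrow(ty) == 1) {
      totals <- rbind(totals, data.frame(year = y, total = ty$count))
    }
  }

  structure(list(counts = cat_rows[order(cat_rows$year), , drop = FALSE],
                 totals = totals[order(totals$year), , drop = FALSE],
                 total_label = total_label),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  yrs <- x$totals$year
  cat("<population_table> ", length(yrs), " anchor year(s), ",
      min(yrs), "-", max(yrs), "; total label ", x$total_label, "\n", sep = "")
  invisible(x)
}

#' Derive the residual age category from a total row
#'
#' Table-style sources often list bands 0-4, 5-9 and 10-14 but print only a
#' 0-17 total; the 15-17 band is then the total minus the listed bands.
#' The residual is added to every anchor year that has category detail.
#'
#' @param table A `population_table`.
#' @param total_label Label of the total range; defaults to the table's.
#' @return The table with the residual category appended.
#' @export
derive_residual_category <- function(table, total_label = table$total_label) {
  stopifnot(inherits(table, "population_table"))
  total_range <- parse_age_label(total_label)
  counts <- table$counts
  for (y in unique(counts$year)) {
    cy <- counts[counts$year == y, , drop = FALSE]
    cats <- age_categories(cy$age_category)
    if (sum(cats$span) == total_range$span) next  # already complete
    tot <- table$totals$total[table$totals$year == y]
    if (length(tot) != 1) stop("no total available for year ", y)
    resid <- tot - sum(cy$count)
    if (resid < 0) {
      stop("year ", y, ": listed categories exceed the total (residual ",
           resid, ")")
    }
    lab <- paste0(max(cats$max_age) + 1L, "-", total_range$max_age)
    counts <- rbind(counts,
                    data.frame(year = y, age_category = lab, count = resid,
                               stringsAsFactors = FALSE))
  }
  table$counts <- counts[order(counts$year), , drop = FALSE]
  table
}

#' Population by age category at a calendar year
#'
#' Exact at anchor years; the total is interpolated linearly between
#' adjacent anchors, and category shares are held fixed at the most recent
#' anchor that carries category detail (projection anchors usually give
#' totals only).  No extrapolation outside the anchor span.
#'
#' @param table A `population_table`.
#' @param year Calendar year within the anchor span.
#' @return Named numeric vector of counts by category, with attribute
#'   `total`.
#' @export
population_at <- function(table, year) {
  stopifnot(inherits(table, "population_table"), length(year) == 1)
  yrs <- table$totals$year
  if (year < min(yrs) || year > max(yrs)) {
    stop("year ", year, " outside the anchor span [", min(yrs), ", ",
         max(yrs), "]; no extrapolation")
  }
  total <- stats::approx(yrs, table$totals$total, xout = year)$y

  detail_years <- unique(table$counts$year)
  if (length(detail_years) == 0) stop("table has no category detail")
  ref <- if (any(detail_years <= year)) max(detail_years[detail_years <= year])
         else min(detail_years)
  cy <- table$counts[table$counts$year == ref, , drop = FALSE]
  shares <- cy$count / sum(cy$count)
  out <- shares * total
  names(out) <- cy$age_category
  attr(out, "total") <- total
  out
}
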