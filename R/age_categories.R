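#' Clinician cadres recognised by the model
#'
#' The model distinguishes three registrant groups: dentists, dental
#' hygienists/dental therapists combined (`"dh_dth"`), and extended duties
#' dental nurses (`"eddn"`).
#'
#' @return Character vector of cadre identifiers.
#' @export
cadres <- function() c("dentist", "dh_dth", "eddn")

#' Care-plan age bands
#'
#' Preventive care plans are defined over three age bands: 0-4, 5-9 and
#' 10-17 years.  Finer population categories (e.g. 10-14 plus a derived
#' 15-17) are merged into these bands for demand purposes.
#'
#' @return Character vector of band labels.
#' @export
care_bands <- function() c("0-4", "5-9", "10-17")

#' Parse an age-range label such as "0-4" or "10-17"
#'
#' @param label Character vector of labels of the form "min-max".
#' @return Data frame with columns `label`, `min_age`, `max_age`, `span`.
#' @export
parse_age_label <- function(label) {
  label <- as.character(label)
  m <- regmatches(label, regexec("^\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse age category label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  min_age <- vapply(m, function(x) as.integer(x[2]), integer(1))
  max_age <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (any(max_age < min_age)) {
    stop("age category with max_age < min_age: ",
         paste(label[max_age < min_age], collapse = ", "))
  }
  data.frame(label = label, min_age = min_age, max_age = max_age,
             span = max_age - min_age + 1L, stringsAsFactors = FALSE)
}

#' Validate a set of age categories
#'
#' Categories within one table must be pairwise disjoint; the result is
#' ordered by `min_age`.
#'
#' @param labels Character vector of "min-max" labels.
#' @return Data frame as [parse_age_label()], sorted by `min_age`.
#' @export
age_categories <- function(labels) {
  cats <- parse_age_label(unique(labels))
  cats <- cats[order(cats$min_age), , drop = FALSE]
  if (nrow(cats) > 1) {
    overlap <- cats$min_age[-1] <= cats$max_age[-nrow(cats)]
    if (any(overlap)) {
      stop("overlapping age categories: ",
           paste(cats$label[c(FALSE, overlap) | c(overlap, FALSE)],
                 collapse = ", "))
    }
  }
  rownames(cats) <- NULL
  cats
}

# map each category label onto the unique care band containing its range
band_for_category <- function(labels, bands = care_bands()) {
  cats <- parse_age_label(labels)
  bnd <- parse_age_label(bands)
  out <- character(nrow(cats))
  for (i in seq_len(nrow(cats))) {
    hit <- which(bnd$min_age <= cats$min_age[i] & bnd$max_age >= cats$max_age[i])
    if (length(hit) != 1L) {
      stop("age category ", cats$label[i],
           " does not fall within a single care band")
    }
    out[i] <- bnd$label[hit]
  }
  out
}

#' Merge per-category population counts into care-plan age bands
#'
#' @param population Named numeric vector of counts, names are age-category
#'   labels (e.g. `c("0-4" = 3237500, "10-14" = ..., "15-17" = ...)`).
#' @param bands Band labels; default [care_bands()].
#' @return Named numeric vector of counts by band.
#' @export
merge_to_care_bands <- function(population, bands = care_bands()) {
  if (is.null(names(population))) stop("population must be a named vector")
  grp <- band_for_category(names(population), bands)
  out <- vapply(bands, function(b) sum(population[grp == b]), numeric(1))
  names(out) <- bands
  out
}
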