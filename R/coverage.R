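#' Service rate per 1000 denominator persons
#'
#' @param raw_count number of service events.
#' @param denominator_count persons in the denominator class.
#' @param digits decimal places for the reported rate (reports use 1);
#'   `NA` for the unrounded value.
#' @return `1000 * raw_count / denominator_count`.
#' @export
#' @examples
#' rate_per_1000(14829910, 13066000)  # 1135
rate_per_1000 <- function(raw_count, denominator_count, digits = 1) {
  if (any(denominator_count <= 0)) {
    stop("denominator_count must be positive")
  }
  if (any(raw_count < 0, na.rm = TRUE)) stop("raw_count must be non-negative")
  r <- 1000 * raw_count / denominator_count
  if (is.na(digits)) r else round_half_up(r, digits)
}

# resolve the denominator count for each record; over5 falls back to
# total - under5 when not supplied directly
denominator_lookup <- function(denominators, fiscal_year, class, context = "") {
  row <- denominators[denominators$fiscal_year == fiscal_year, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("no denominators for fiscal year '", fiscal_year, "'", context)
  }
  if (!class %in% denominator_classes()) {
    stop("unknown denominator class '", class, "'", context)
  }
  if (class %in% names(row) && !is.na(row[[class]][1])) {
    return(row[[class]][1])
  }
  if (class == "over5" && all(c("total", "under5") %in% names(row))) {
    return(row$total[1] - row$under5[1])
  }
  stop("denominator class '", class, "' not available for fiscal year '",
       fiscal_year, "'", context)
}

#' Provision rates per intervention for one fiscal year
#'
#' Converts raw HMIS counts into rates per 1000 of each record's
#' denominator class.  Records that already carry a `rate_per_1000`
#' column (the form in which published provision tables are transcribed)
#' are passed through unchanged.  Interventions reported in other years
#' but not in `year` appear with a missing rate — absence of a report is
#' not a zero.
#'
#' @param records data frame with columns `intervention`, `fiscal_year`,
#'   `denominator_class`, and either `raw_count` or `rate_per_1000`.
#' @param denominators data frame with column `fiscal_year` and one
#'   column per denominator class (see [denominator_classes()]); only
#'   needed when records carry raw counts.
#' @param year fiscal-year label, e.g. `"2007/08"`.
#' @param digits decimal places for reported rates.
#' @return Tibble `intervention`, `fiscal_year`, `denominator_class`,
#'   `rate_per_1000` (NA where that intervention-year was not reported).
#' @export
build_provision_table <- function(records, denominators = NULL, year,
                                  digits = 1) {
  stopifnot(all(c("intervention", "fiscal_year", "denominator_class")
                %in% names(records)))
  bad <- !records$denominator_class %in% denominator_classes()
  if (any(bad)) {
    stop("unknown denominator class '",
         records$denominator_class[which(bad)[1]], "' for intervention '",
         records$intervention[which(bad)[1]], "'")
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(intervention = character(),
                          fiscal_year = character(),
                          denominator_class = character(),
                          rate_per_1000 = numeric()))
  }

  all_interventions <- unique(records[, c("intervention", "denominator_class")])
  this_year <- records[records$fiscal_year == year, , drop = FALSE]

  if ("rate_per_1000" %in% names(this_year)) {
    rates <- this_year$rate_per_1000
  } else {
    if (is.null(denominators)) {
      stop("records carry raw counts; 'denominators' is required")
    }
    denom <- vapply(seq_len(nrow(this_year)), function(i) {
      denominator_lookup(denominators, year, this_year$denominator_class[i],
                         context = paste0(" (intervention '",
                                          this_year$intervention[i], "')"))
    }, numeric(1))
    rates <- rate_per_1000(this_year$raw_count, denom, digits = digits)
  }

  out <- tibble::tibble(
    intervention      = all_interventions$intervention,
    fiscal_year       = year,
    denominator_class = all_interventions$denominator_class,
    rate_per_1000     = rates[match(all_interventions$intervention,
                                    this_year$intervention)]
  )
  out
}

#' Multi-year rate series for one intervention
#'
#' Orders the intervention's reported rates by fiscal year and summarises
#' the change between the first and last non-missing values.
#'
#' @param records data frame with columns `intervention`, `fiscal_year`
#'   and `rate_per_1000` (or `raw_count` plus `denominator_class` with
#'   `denominators` supplied, as in [build_provision_table()]).
#' @param intervention name to extract (matched after normalization).
#' @param denominators optional denominator table for raw-count records.
#' @param aliases optional alias map passed to [normalize_intervention()].
#' @return Object of class `ehp_trend`: a list with the year-ordered
#'   `series` tibble and `first`, `last`, `abs_change`, `rel_change`
#'   (relative change as a fraction of the first value).
#' @export
trend_series <- function(records, intervention, denominators = NULL,
                         aliases = NULL) {
  key <- normalize_intervention(records$intervention, aliases)
  want <- normalize_intervention(intervention, aliases)
  sel <- records[key == want, , drop = FALSE]
  if (nrow(sel) == 0) stop("no records for intervention '", intervention, "'")

  if (!"rate_per_1000" %in% names(sel)) {
    denom <- vapply(seq_len(nrow(sel)), function(i) {
      denominator_lookup(denominators, sel$fiscal_year[i],
                         sel$denominator_class[i])
    }, numeric(1))
    sel$rate_per_1000 <- rate_per_1000(sel$raw_count, denom)
  }
  sel <- sel[order(fy_start(sel$fiscal_year)), , drop = FALSE]
  series <- tibble::tibble(fiscal_year = sel$fiscal_year,
                           rate_per_1000 = sel$rate_per_1000)
  obs <- series$rate_per_1000[!is.na(series$rate_per_1000)]
  if (length(obs) == 0) stop("all rates missing for '", intervention, "'")
  first <- obs[1]
  last <- obs[length(obs)]
  structure(
    list(intervention = intervention, series = series,
         first = first, last = last,
         abs_change = last - first,
         rel_change = if (first > 0) (last - first) / first else NA_real_),
    class = "ehp_trend"
  )
}

#' @export
print.ehp_trend <- function(x, ...) {
  cat("Provision trend:", x$intervention, "\n")
  print(x$series)
  cat(sprintf("first %s, last %s; change %+g (%+.1f%%)\n",
              format(x$first), format(x$last), x$abs_change,
              100 * x$rel_change))
  invisible(x)
}
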