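#' Funding coverage: expenditure as a fraction of required cost
#'
#' Both arguments are per-capita dollar amounts for the same year and the
#' same accounting scope; the result is dimensionless, so any common
#' currency rescaling cancels.
#'
#' @param expenditure_pc per-capita expenditure (USD/person/year).
#' @param required_pc per-capita required cost; must be positive.
#' @return `expenditure_pc / required_pc`.
#' @export
#' @examples
#' coverage_fraction(13.5, 28.6)  # 0.472
coverage_fraction <- function(expenditure_pc, required_pc) {
  if (any(required_pc <= 0)) stop("required_pc must be positive")
  if (any(expenditure_pc < 0, na.rm = TRUE)) {
    stop("expenditure_pc must be non-negative")
  }
  expenditure_pc / required_pc
}

#' Percent change between two per-capita amounts
#'
#' @param first_pc value in the first year; must be positive.
#' @param last_pc value in the last year.
#' @return `100 * (last_pc - first_pc) / first_pc`.
#' @export
#' @examples
#' percent_change(7.9, 13.5)  # 70.9
percent_change <- function(first_pc, last_pc) {
  if (any(first_pc <= 0)) stop("first_pc must be positive")
  100 * (last_pc - first_pc) / first_pc
}

#' Mean yearly funding coverage over a series
#'
#' Averages the yearly expenditure/required fractions of a funding
#' series.  The series must come from a single accounting scope: a
#' sector-wide-approach (SWAp) EHP series excludes households, NGOs and
#' non-SWAp donors and is not comparable with a national-total series.
#' Years without both amounts are dropped.
#'
#' @param series data frame with columns `fiscal_year`, `expenditure_pc`,
#'   `required_pc` and optionally `scope`.
#' @return Mean of the yearly coverage fractions.
#' @export
mean_coverage <- function(series) {
  if (nrow(series) == 0) stop("'series' must be non-empty")
  if ("scope" %in% names(series) && length(unique(series$scope)) > 1) {
    stop("mixed funding scopes: ",
         paste(unique(series$scope), collapse = ", "),
         "; SWAp-EHP and national-total series are not comparable")
  }
  ok <- !is.na(series$expenditure_pc) & !is.na(series$required_pc)
  if (!any(ok)) stop("no complete (expenditure, required) pairs in series")
  mean(coverage_fraction(series$expenditure_pc[ok], series$required_pc[ok]))
}

#' Summarise a funding series per scope
#'
#' For each accounting scope: yearly coverage fractions, the mean
#' coverage, and the percent change in expenditure between the first and
#' last years with data.
#'
#' @param series data frame with columns `fiscal_year`, `expenditure_pc`,
#'   `required_pc`, `scope`.
#' @return Tibble with one row per scope: `scope`, `first_year`,
#'   `last_year`, `first_expenditure_pc`, `last_expenditure_pc`,
#'   `pct_change`, `mean_coverage`.
#' @export
funding_summary <- function(series) {
  stopifnot(all(c("fiscal_year", "expenditure_pc", "required_pc", "scope")
                %in% names(series)))
  scopes <- unique(series$scope)
  rows <- lapply(scopes, function(s) {
    sub <- series[series$scope == s & !is.na(series$expenditure_pc), , drop = FALSE]
    sub <- sub[order(fy_start(sub$fiscal_year)), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    tibble::tibble(
      scope = s,
      first_year = sub$fiscal_year[1],
      last_year = sub$fiscal_year[nrow(sub)],
      first_expenditure_pc = sub$expenditure_pc[1],
      last_expenditure_pc = sub$expenditure_pc[nrow(sub)],
      pct_change = if (nrow(sub) > 1) {
        percent_change(sub$expenditure_pc[1], sub$expenditure_pc[nrow(sub)])
      } else NA_real_,
      mean_coverage = mean_coverage(series[series$scope == s, , drop = FALSE])
    )
  })
  dplyr::bind_rows(rows)
}
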