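#' Packaged Malawi 2008 EHP assessment tables
#'
#' Plain-CSV transcriptions of the published Malawi essential-health-
#' package assessment inputs, shipped with the package so the whole
#' pipeline runs without any download:
#'
#' * `"gap"` — the 49-intervention gap table: national incidence (NA
#'   where not published), need per 1000 (column a), provision in
#'   2007/08 per 1000 (column b) and the printed ratio; a `source`
#'   column (`incidence_derived` / `costing_default`) and the implied
#'   required coverage are added via [build_need_table()] using
#'   [malawi_population_2008].
#' * `"burden"` — the top-20 disease ranking for 2008 by stratum
#'   (persons / males / females) with percent of total DALYs.
#' * `"burden_totals"` — stratum DALY totals: 7.5M total, 2.1M under-15,
#'   5.4M adults, with the percentages as published (the published 29%
#'   for under-15s and 2.1/7.5 = 28% are both retained, unreconciled).
#' * `"provision"` — HMIS service provision rates per 1000 denominator
#'   persons, 2002/03–2007/08, long format.  Blank cells in the source
#'   table (series not yet collected) are NA; published zeros are 0.
#' * `"funding"` — the published per-capita funding values by scope:
#'   SWAp-EHP expenditure ($7.9 then $13.5) against EHP cost estimates
#'   ($17.3 then $28.6), and national totals ($25 in 2005/06 against the
#'   $34 target, rising to $38 by 2015).
#' * `"population"` — the working national population (13,066,000 for
#'   2007/08).
#' * `"ce"` — the individually published $/DALY values with EHP and
#'   top-20 flags (the full per-intervention table lives only in the
#'   original supplementary file; these are the values quoted in text).
#'
#' @param name which fixture to load.
#' @return A tibble (see above for columns).
#' @export
#' @examples
#' gap <- ehp_fixture("gap")
#' sum(gap$need_a)  # 1931.6
ehp_fixture <- function(name = c("gap", "burden", "burden_totals",
                                 "provision", "funding", "population", "ce")) {
  name <- match.arg(name)
  file <- c(
    gap           = "malawi_gap_2008.csv",
    burden        = "malawi_burden_2008.csv",
    burden_totals = "malawi_burden_totals_2008.csv",
    provision     = "malawi_provision_2002_2008.csv",
    funding       = "malawi_funding.csv",
    population    = "malawi_population.csv",
    ce            = "malawi_ce_quotes.csv"
  )[[name]]
  path <- system.file("extdata", file, package = "ehpgap", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture '", file, "' is missing; reinstall ehpgap")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (name == "gap") {
    src <- build_need_table(
      data.frame(intervention = d$intervention, incidence = d$incidence,
                 need_per_1000 = d$need_a),
      population = malawi_population_2008
    )
    d$source <- src$source
    d$implied_coverage <- src$implied_coverage
  }
  if (name == "provision") {
    d <- tidyr::pivot_longer(d, dplyr::starts_with("y"),
                             names_to = "fiscal_year",
                             values_to = "rate_per_1000")
    start <- as.integer(substr(d$fiscal_year, 2, 5))
    d$fiscal_year <- fy_label(start)
    d <- d[, c("intervention", "fiscal_year", "denominator_class",
               "rate_per_1000")]
  }
  d
}
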