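#' Rank diseases by DALY burden within a population stratum
#'
#' Sorts descending by DALYs (ties broken alphabetically by disease name),
#' assigns ranks 1..n, and expresses each disease's share of the stratum
#' total.  When the input lists only the leading causes, supply the known
#' stratum total via `total_dalys` so that shares are of the full burden
#' rather than of the listed subset.
#'
#' @param entries data frame with columns `disease`, `dalys` and
#'   optionally `stratum`.
#' @param stratum if given and `entries` has a `stratum` column, restrict
#'   to this stratum (one of `"persons"`, `"males"`, `"females"`,
#'   `"under15"`, `"adults"`).
#' @param total_dalys stratum total DALYs; defaults to the sum of the
#'   listed entries.
#' @return Tibble with columns `rank`, `disease`, `dalys`, `pct_total`,
#'   sorted by rank.
#' @export
rank_diseases <- function(entries, stratum = NULL, total_dalys = NULL) {
  if (!is.data.frame(entries) || nrow(entries) == 0) {
    stop("'entries' must be a non-empty data frame")
  }
  if (!all(c("disease", "dalys") %in% names(entries))) {
    stop("'entries' needs columns 'disease' and 'dalys'")
  }
  if (!is.null(stratum) && "stratum" %in% names(entries)) {
    entries <- entries[entries$stratum == stratum, , drop = FALSE]
    if (nrow(entries) == 0) stop("no entries for stratum '", stratum, "'")
  }
  if (any(entries$dalys < 0)) stop("DALYs must be non-negative")
  total <- total_dalys %||% sum(entries$dalys)
  out <- entries[order(-entries$dalys, entries$disease), , drop = FALSE]
  tibble::tibble(
    rank      = seq_len(nrow(out)),
    disease   = out$disease,
    dalys     = out$dalys,
    pct_total = 100 * out$dalys / total
  )
}

#' Names of the top-n diseases of a ranked burden table
#'
#' @param ranked output of [rank_diseases()] (or any data frame with
#'   `rank` and `disease` columns).
#' @param n how many leading diseases to return.
#' @return Character vector of disease names in rank order.  If `n`
#'   exceeds the table size, all diseases are returned with a warning.
#' @export
top_diseases <- function(ranked, n = 20) {
  if (n < 1) stop("'n' must be at least 1")
  if (n > nrow(ranked)) {
    warning("requested top ", n, " of only ", nrow(ranked),
            " ranked diseases; returning all")
    n <- nrow(ranked)
  }
  ranked$disease[order(ranked$rank)][seq_len(n)]
}

#' Convert national incidence into required cases per 1000 population
#'
#' The need an intervention must meet, expressed per 1000 population:
#' `1000 * incidence * required_coverage / population`.
#'
#' @param incidence national incident cases per year.
#' @param population total population.
#' @param required_coverage fraction of incident cases the package aims to
#'   serve, in (0, 1]; defaults to full coverage.
#' @param digits decimal places for the reported rate (reports use 1);
#'   `NA` for the unrounded value.
#' @return Need per 1000 population per year.
#' @export
#' @examples
#' incidence_to_need(1829077, 13066000)  # 140
incidence_to_need <- function(incidence, population, required_coverage = 1,
                              digits = 1) {
  if (any(population <= 0)) stop("population must be positive")
  if (any(required_coverage <= 0) || any(required_coverage > 1)) {
    stop("required_coverage must lie in (0, 1]")
  }
  if (any(incidence < 0, na.rm = TRUE)) stop("incidence must be non-negative")
  need <- 1000 * incidence * required_coverage / population
  if (is.na(digits)) need else round_half_up(need, digits)
}

#' Build an intervention need table with provenance
#'
#' Classifies each intervention's need rate as `incidence_derived` when it
#' is reproduced (within `tol` per 1000) by
#' `1000 * incidence / population`, and as `costing_default` otherwise —
#' rows without incidence, or whose published need reflects a required-
#' coverage default from a costing exercise rather than full incidence.
#' For costing-default rows with an incidence the implied coverage is
#' back-solved and reported.
#'
#' @param needs data frame with columns `intervention`, `incidence`
#'   (NA allowed) and `need_per_1000`.
#' @param population total population the rates refer to.
#' @param tol agreement tolerance in cases per 1000 (default 0.5, i.e.
#'   within rounding of a rate printed to one decimal or to an integer).
#' @return Tibble `intervention`, `incidence`, `need_per_1000`, `source`,
#'   `implied_coverage` (NA where not derivable).
#' @export
build_need_table <- function(needs, population, tol = 0.5) {
  stopifnot(all(c("intervention", "need_per_1000") %in% names(needs)))
  if (!"incidence" %in% names(needs)) needs$incidence <- NA_real_
  derived <- incidence_to_need(needs$incidence, population, digits = NA)
  ok <- !is.na(derived) & abs(derived - needs$need_per_1000) <= tol
  source <- ifelse(ok, "incidence_derived", "costing_default")
  implied <- ifelse(ok, 1,
                    needs$need_per_1000 * population / (1000 * needs$incidence))
  tibble::tibble(
    intervention     = needs$intervention,
    incidence        = needs$incidence,
    need_per_1000    = needs$need_per_1000,
    source           = source,
    implied_coverage = implied
  )
}
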